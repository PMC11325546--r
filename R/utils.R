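# Small shared utilities: stable string hashing, structured logging, seeded
# RNG scoping. No external dependencies so every module can use them.

#' Stable 31-bit string hash
#'
#' Polynomial rolling hash (base 131, modulus 2^31 - 1) over the UTF-8 code
#' points of `x`. Platform-independent and stable across sessions, unlike
#' R's internal hashing; used to derive deterministic seeds from canonical
#' SMILES strings.
#'
#' @param x Character scalar.
#' @return Integer in [0, 2^31 - 2].
#' @export
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647  # 2^31 - 1, fits exactly in a double
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 131 + cp) %% m
  as.integer(h)
}

#' Evaluate an expression with a local RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never perturbs
#' user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Structured log lines: "LEVEL [stage] (mol id) message" on stderr.
# Controlled by option micropka.verbose (default TRUE for warn, FALSE info).
mp_log <- function(level = c("info", "warn", "error"), stage, msg, id = NULL) {
  level <- match.arg(level)
  verbose <- getOption("micropka.verbose", FALSE)
  if (level == "info" && !verbose) return(invisible(NULL))
  tag <- if (is.null(id)) "" else sprintf(" (%s)", id)
  message(sprintf("%s [%s]%s %s", toupper(level), stage, tag, msg))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
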