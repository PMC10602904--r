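#' Run code with a local RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, restoring the
#' previous RNG state afterwards so callers never perturb each other.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a top-level seed and a stage label
#'
#' Every stochastic stage draws its stream from the run's single top-level
#' seed plus its own label, so stages can be rerun independently yet
#' reproducibly. Result is always a valid 32-bit integer seed.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label (e.g. `"eeg/p03/direct"`).
#' @return integer sub-seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
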