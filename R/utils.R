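#' @importFrom stats plogis qlogis quantile rbeta rbinom rlnorm rnorm runif
#'   sd weighted.mean cor predict
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a base seed and a string key
#'
#' Simulation and data generation key their random-number streams by
#' (hospital, purpose) so that per-hospital results are independent of how
#' many hospitals are run and in which order, and so that scenario runs can
#' share patient-level noise by reusing the hospital's stream.
#'
#' @param seed integer base seed.
#' @param key character key, e.g. `"H007/patients"`.
#' @return an integer seed in `[1, 2^31 - 20]`.
#' @keywords internal
substream_seed <- function(seed, key) {
  stopifnot(length(seed) == 1, is.finite(seed))
  m <- 2147483629 # large prime below 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% m
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% m) + 1L
}

assert_proportion <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_range <- function(x, name) {
  if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2]) {
    stop(sprintf("`%s` must be a non-empty (min, max) range with min <= max",
                 name), call. = FALSE)
  }
  invisible(x)
}
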