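# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

clamp_pos <- function(x) pmax(0, x)

stop_invalid <- function(...) stop(..., call. = FALSE)

check_finite_temperature <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop_invalid("temperature must be finite and numeric")
  }
  invisible(t)
}

#' Derive a child seed from a parent seed
#'
#' Deterministically maps a parent seed plus an integer stream index to a
#' new seed in `[1, 2^31 - 2]`, so that one global seed reproducibly drives
#' every replicate and pipeline stage.
#'
#' @param seed parent seed (integer-like scalar).
#' @param ... one or more integer-like stream indices.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647            # 2^31 - 1, Mersenne prime modulus
  s <- as.numeric(seed) %% m
  for (k in idx) {
    s <- (s * 48271 + as.numeric(k) * 16807 + 1) %% m
  }
  as.integer(if (s == 0) 1 else s)
}

# Standard error of a vector; NA for n < 2.
std_err <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
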