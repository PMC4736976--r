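#' Round half away from zero
#'
#' Symmetric two-sided rounding used by the chain codec: 0.005 -> 0.01 and
#' -0.005 -> -0.01, unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @keywords internal
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-operator seed derived from a master seed and integer
# tags (iteration, electrode, template, role). Kept strictly below 2^31.
derive_seed <- function(master, ...) {
  tags <- c(...)
  h <- as.double(master) %% 2147483647
  for (t in tags) {
    h <- (h * 48271 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
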