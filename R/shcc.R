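#' SHCC chains
#'
#' The Slope Horizontal Chain Code represents a curve as a sequence of S
#' slope symbols, one per straight-line segment of the resampled,
#' unit-square-normalized curve. Each symbol is the segment's inclination
#' relative to the horizontal, expressed as a fraction of 90 degrees and
#' quantized to two decimals, so symbols live strictly inside (-1, 1).
#'
#' @param symbols numeric vector of two-decimal symbols in (-1, 1).
#' @return An object of class `shcc_chain` (a numeric vector).
#' @examples
#' shcc_chain(c(0.05, -0.02, 0.1))
#' @export
shcc_chain <- function(symbols) {
  symbols <- as.numeric(symbols)
  if (length(symbols) < 1) abort("a chain needs at least one symbol.")
  if (any(abs(symbols) >= 1)) abort("chain symbols must lie strictly inside (-1, 1).")
  if (any(abs(symbols - round_away(symbols, 2)) > 1e-9)) {
    abort("chain symbols must be quantized to two decimals.")
  }
  structure(round_away(symbols, 2), class = "shcc_chain")
}

#' @export
format.shcc_chain <- function(x, ...) {
  paste(sub("^0\\.00$", "0", sprintf("%.2f", unclass(x) + 0)), collapse = " ")
}

#' @export
print.shcc_chain <- function(x, ...) {
  cat(sprintf("<shcc_chain S=%d> (%s)\n", length(x), format(x)))
  invisible(x)
}

#' Rediscretize a curve into S segments
#'
#' Selects S+1 of the curve's own sample points at nominal spacing
#' Delta = T/(S+1), snapping each nominal position to the nearest existing
#' sample — no interpolation, exploiting the uniform sampling of the
#' acquisition. The first point is always sample 1; indices are
#' `round(1 + m * Delta)` for m = 0..S, clipped to `[1, T]`.
#'
#' @param curve an `erp_curve` with T points.
#' @param S desired number of segments; must satisfy `S < T`. At
#'   `S = T - 1` every sample is retained.
#' @return An `erp_curve` with S+1 points.
#' @export
resample_curve <- function(curve, S) {
  stopifnot(inherits(curve, "erp_curve"))
  T <- nrow(curve)
  S <- as.integer(S)
  if (S < 1 || S >= T) abort(sprintf("S must satisfy 1 <= S < T (got S=%d, T=%d).", S, T))
  delta <- T / (S + 1)
  idx <- pmin(pmax(as.integer(round_away(1 + (0:S) * delta, 0)), 1L), T)
  if (any(diff(idx) <= 0)) abort("resampled indices are not strictly increasing.")
  erp_curve(curve$x[idx], curve$y[idx])
}

#' Min-max normalize a curve to the unit square
#'
#' Scales `x` and `y` independently to `[0, 1]`. A flat axis (max equals
#' min) maps to all zeros rather than dividing by zero, so a
#' zero-amplitude epoch encodes to the all-zero chain.
#'
#' @param curve an `erp_curve`.
#' @return A tibble of class `shcc_normalized_curve` with columns `x`, `y`
#'   in `[0, 1]`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 2)
  mm <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  tibble::new_tibble(list(x = mm(curve$x), y = mm(curve$y)),
                     class = "shcc_normalized_curve")
}

#' Encode a curve as an SHCC chain
#'
#' Composition of [resample_curve()] and [normalize_curve()] followed by
#' per-segment symbol computation. In the default `"angle"` mode the symbol
#' for segment s is its inclination `atan(dy/dx)` expressed in degrees,
#' divided by 90 and rounded half-away-from-zero to two decimals; the
#' `"rise"` mode instead codes the normalized rise `dy` per segment
#' (treating the segment width as one unit). Both are translation-invariant
#' in amplitude.
#'
#' @param curve an `erp_curve`.
#' @param S number of segments.
#' @param mode symbol convention, `"angle"` (default) or `"rise"`.
#' @return An `shcc_chain` of length exactly `S`.
#' @export
encode_chain <- function(curve, S, mode = c("angle", "rise")) {
  mode <- match.arg(mode)
  nc <- normalize_curve(resample_curve(curve, S))
  b <- chain_symbols(nc, mode)
  shcc_chain(b)
}

# Symbols from an already resampled+normalized curve.
chain_symbols <- function(nc, mode = c("angle", "rise")) {
  mode <- match.arg(mode)
  dx <- diff(nc$x)
  dy <- diff(nc$y)
  raw <- if (mode == "angle") atan2(dy, dx) * 180 / pi / 90 else dy
  b <- round_away(raw, 2)
  # two-decimal rounding can hit +/-1.00 for near-vertical segments at
  # large S; the alphabet is open at +/-1, so saturate at the extreme symbol
  pmin(pmax(b, -0.99), 0.99)
}

#' l1 distance between two chains
#'
#' The Manhattan distance between equal-length chains: the sum over
#' segments of the absolute symbol differences. Small distances mean
#' similar waveforms; a subject's P300 trials sit closer to their P300
#' template chain than background-EEG trials do.
#'
#' @param a,b `shcc_chain`s (or plain numeric symbol vectors) of equal
#'   length.
#' @return A nonnegative real.
#' @examples
#' chain_distance(shcc_chain(c(0.1, -0.2)), shcc_chain(c(0, 0)))
#' @export
chain_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("chain lengths differ (%d vs %d).", length(a), length(b)))
  }
  sum(abs(as.numeric(a) - as.numeric(b)))
}

#' Tortuosity of a chain
#'
#' The sum of the absolute values of all S symbols: zero for a curve of
#' purely horizontal segments and increasing with curvature, measuring how
#' twisted the encoded waveform is.
#'
#' @param chain an `shcc_chain` (or plain numeric symbol vector).
#' @return A nonnegative real.
#' @export
tortuosity <- function(chain) {
  sum(abs(as.numeric(chain)))
}

#' Read and write chain files
#'
#' Chains serialize one per line as space-separated two-decimal tokens
#' (e.g. `0.05 -0.02 ... 0.04`); lines starting with `#` are comments.
#'
#' @param path file path.
#' @param chains a list of `shcc_chain`s (or a single chain) to write.
#' @return `read_chains()` returns a list of `shcc_chain`s; `write_chains()`
#'   returns `path` invisibly.
#' @export
read_chains <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    toks <- strsplit(lines[i], "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      abort(sprintf("parse failure in chain %d: non-numeric token '%s'.",
                    i, toks[which(is.na(vals))[1]]))
    }
    shcc_chain(vals)
  })
}

#' @rdname read_chains
#' @export
write_chains <- function(chains, path) {
  if (inherits(chains, "shcc_chain")) chains <- list(chains)
  writeLines(vapply(chains, format, character(1)), path)
  invisible(path)
}
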