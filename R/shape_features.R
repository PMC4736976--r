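#' Trapezoid-rule segment areas
#'
#' Areas under the first S points of a normalized curve, one trapezoid per
#' consecutive point pair: `0.5 * (y_i + y_{i+1}) * (x_{i+1} - x_i)` for
#' i = 1..S-1. These S-1 areas are the per-segment quadrature used to
#' compare a candidate waveform against a template.
#'
#' @param curve an `shcc_normalized_curve` (or any data frame with `x`, `y`)
#'   with at least 3 points.
#' @return A numeric vector of S-1 areas, where the curve has S+1 points.
#' @export
segment_areas <- function(curve) {
  n <- nrow(curve)
  if (is.null(n) || n < 3) abort("need at least 3 points for segment areas.")
  s <- n - 1                               # points 1..s are the "first S"
  i <- seq_len(s - 1)
  0.5 * (curve$y[i] + curve$y[i + 1]) * (curve$x[i + 1] - curve$x[i])
}

#' Area-difference features between template and candidate
#'
#' Signed per-segment differences `a_i = template_area_i - candidate_area_i`
#' and their absolute sum, the area-dissimilarity total. Template and
#' candidate are each integrated on their own min-max normalization.
#'
#' @param template,candidate normalized curves with the same number of
#'   points (same S).
#' @return A list with `area_diffs` (length S-1, signed) and
#'   `area_diff_sum` (sum of `abs(area_diffs)`).
#' @export
area_difference_features <- function(template, candidate) {
  if (nrow(template) != nrow(candidate)) {
    abort(sprintf("segment counts differ (%d vs %d points).",
                  nrow(template), nrow(candidate)))
  }
  a <- segment_areas(template) - segment_areas(candidate)
  list(area_diffs = a, area_diff_sum = sum(abs(a)))
}

#' Assemble the shape-feature vector
#'
#' Packs the shape descriptors into the fixed layout
#' `[a_1..a_{S-1}, Tsum, d, tort, b_1..b_S]` of length 2S+2 (34 when
#' S = 16). Position S+1 always holds the chain distance `d`, which the
#' calibration stage extracts for AUROC scoring.
#'
#' @param area_diffs S-1 signed per-segment area differences.
#' @param area_diff_sum their absolute sum.
#' @param distance l1 chain distance between template and candidate chains.
#' @param tort tortuosity of the candidate chain.
#' @param chain the candidate `shcc_chain` (length S).
#' @return A named numeric vector of class `shape_features` and length
#'   2S+2, names `a1..a{S-1}, Tsum, d, tort, b1..bS`.
#' @export
assemble_vector <- function(area_diffs, area_diff_sum, distance, tort, chain) {
  S <- length(chain)
  if (length(area_diffs) != S - 1) {
    abort(sprintf("expected %d area differences for a length-%d chain, got %d.",
                  S - 1, S, length(area_diffs)))
  }
  stopifnot(length(area_diff_sum) == 1, length(distance) == 1, length(tort) == 1)
  v <- c(area_diffs, area_diff_sum, distance, tort, as.numeric(chain))
  names(v) <- c(paste0("a", seq_len(S - 1)), "Tsum", "d", "tort",
                paste0("b", seq_len(S)))
  structure(v, S = S, class = "shape_features")
}

#' Unpack a shape-feature vector into its components
#'
#' Inverse of [assemble_vector()]: recovers the named components from the
#' flat layout.
#'
#' @param v a `shape_features` vector (length 2S+2).
#' @return A list with `area_diffs`, `area_diff_sum`, `distance`, `tort`
#'   and `chain`.
#' @export
unpack_vector <- function(v) {
  S <- attr(v, "S") %||% ((length(v) - 2) / 2)
  if (length(v) != 2 * S + 2) abort("not a valid shape-feature layout.")
  v <- as.numeric(v)
  list(area_diffs = v[seq_len(S - 1)],
       area_diff_sum = v[S],
       distance = v[S + 1],
       tort = v[S + 2],
       chain = shcc_chain(v[(S + 3):(2 * S + 2)]))
}

#' @export
print.shape_features <- function(x, ...) {
  S <- attr(x, "S")
  cat(sprintf("<shape_features> S=%d, V=%d | Tsum=%.4f d=%.2f tort=%.2f\n",
              S, length(x), x[["Tsum"]], x[["d"]], x[["tort"]]))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.shape_features <- function(x, ...) {
  as_tibble(as.list(unclass(x)))
}

#' Write / read a shape-feature matrix as delimited text
#'
#' One row per feature vector, a header naming each component
#' (`a1..a{S-1}, Tsum, d, tort, b1..bS`) plus a `label` column when labels
#' are supplied.
#'
#' @param X matrix (rows = vectors) or list of `shape_features`.
#' @param path file path.
#' @param labels optional per-row class labels.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a list with `X` (matrix) and `labels` (or `NULL`).
#' @export
write_features <- function(X, path, labels = NULL) {
  if (is.list(X) && !is.data.frame(X)) {
    X <- do.call(rbind, lapply(X, function(v) {
      nm <- names(v)
      v <- as.numeric(v)
      names(v) <- nm
      v
    }))
  }
  X <- as.matrix(X)
  df <- as_tibble(X)
  if (!is.null(labels)) df <- dplyr::bind_cols(tibble(label = labels), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  list(X = as.matrix(df), labels = labels)
}
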