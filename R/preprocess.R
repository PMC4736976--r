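#' ERP curves
#'
#' A curve is the ordered-pair representation of one (possibly averaged)
#' ERP trace: a tibble with integer sample numbers `x` (strictly
#' increasing) and real amplitudes `y` in microvolts. Curves are what the
#' chain codec consumes.
#'
#' @param x nonnegative integer sample numbers, strictly increasing.
#' @param y real amplitudes, same length as `x`.
#' @return A tibble of class `erp_curve` with columns `x` and `y`.
#' @export
erp_curve <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("a curve needs at least 2 points.")
  if (any(diff(x) <= 0)) abort("`x` must be strictly increasing.")
  tibble::new_tibble(list(x = x, y = y), class = "erp_curve")
}

#' Zero-phase Butterworth band-pass
#'
#' Applies a Butterworth band-pass of the given order to every
#' (trial, electrode) series, forward and backward (zero-phase), so the
#' P300 latency is not shifted by filter delay. The default band is the
#' conventional ERP extraction band.
#'
#' @param epochs an `epoch_set`.
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth design order (default 4).
#' @return An `epoch_set` with identical axes and filtered amplitudes.
#' @export
bandpass <- function(epochs, low_hz = 0.1, high_hz = 12, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sampling_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort(sprintf("band (%g, %g) Hz must satisfy 0 < low < high < Nyquist (%g Hz).",
                  low_hz, high_hz, nyq))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- epochs
  d <- dim(epochs$data)
  for (c in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      out$data[i, c, ] <- signal::filtfilt(bf, epochs$data[i, c, ])
    }
  }
  out
}

#' Remove DC offset and linear trend
#'
#' Subtracts from each (trial, electrode) series its mean and its
#' least-squares straight-line fit, leaving every series with zero mean and
#' zero fitted slope.
#'
#' @param epochs an `epoch_set`.
#' @return An `epoch_set` with detrended amplitudes.
#' @export
remove_dc_and_detrend <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  t <- seq_len(d[3])
  tc <- t - mean(t)
  den <- sum(tc^2)
  out <- epochs
  for (c in seq_len(d[2])) {
    m <- epochs$data[, c, , drop = TRUE]
    if (d[1] == 1) m <- matrix(m, nrow = 1)
    mu <- rowMeans(m)
    slope <- (m %*% tc) / den
    out$data[, c, ] <- m - mu - slope %*% rbind(tc)
  }
  out
}

#' Coherent average of time-locked trials
#'
#' Pointwise arithmetic mean of the selected trials at one electrode. Since
#' the P300 is time-locked to the stimulus while background EEG is not,
#' averaging K trials raises the signal-to-noise ratio roughly by sqrt(K).
#'
#' @param epochs an `epoch_set`.
#' @param electrode electrode name or index.
#' @param trials trial indices to average; defaults to all trials.
#' @return An `erp_curve` with `x = 1..T` and the averaged amplitudes.
#' @export
coherent_average <- function(epochs, electrode = 1, trials = NULL) {
  m <- electrode_series(epochs, electrode)
  if (is.null(trials)) trials <- seq_len(nrow(m))
  if (length(trials) == 0) abort("cannot average an empty trial selection.")
  m <- m[trials, , drop = FALSE]
  erp_curve(seq_len(ncol(m)), colMeans(m))
}

#' Standard offline conditioning pipeline
#'
#' Band-pass, DC removal, then linear detrend, in that order.
#'
#' @inheritParams bandpass
#' @return A conditioned `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, low_hz = 0.1, high_hz = 12, order = 4) {
  epochs |>
    bandpass(low_hz, high_hz, order) |>
    remove_dc_and_detrend()
}

#' @exportS3Method ggplot2::autoplot
autoplot.erp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "sample", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}
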