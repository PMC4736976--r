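#' Simulation configuration for the oddball-paradigm ERP generator
#'
#' Describes a synthetic subject in the reference acquisition regime: 10
#' electrodes at 256 Hz, 800 ms epochs, a training collection of 480 P300
#' and 2,400 non-P300 trials and a validation collection of 150 + 750.
#' P300 epochs carry a positive raised-Gaussian deflection at a jittered
#' latency, scaled per electrode by an amplitude profile that mimics how
#' the P300 attenuates with distance from its cortical sources (by default
#' 3 electrodes at full amplitude, 4 at half, 3 at zero). Background EEG is
#' Gaussian noise band-limited to the post-filter ERP band.
#'
#' @param n_electrodes number of electrodes (default 10).
#' @param electrodes electrode names (default the 10-electrode 10-20
#'   montage Fz, C4, Cz, C3, P4, Pz, P3, PO8, Oz, PO7).
#' @param sampling_rate_hz sampling rate (default 256).
#' @param epoch_ms epoch duration (default 800).
#' @param n_p300_train,n_nonp300_train training trial counts
#'   (defaults 480 / 2400).
#' @param n_p300_valid,n_nonp300_valid validation trial counts
#'   (defaults 150 / 750).
#' @param p300_amplitude_uV peak deflection amplitude in microvolts,
#'   recycled to one value per electrode. The default is 8 uV scaled by
#'   the profile `c(1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0, 0, 0)`.
#' @param p300_latency_ms nominal peak latency (default 350 ms).
#' @param jitter_sd_ms trial-to-trial latency jitter SD (default 20 ms;
#'   set 0 for exact-recovery tests).
#' @param p300_width_ms Gaussian width (SD) of the deflection (default 45).
#' @param n_bumps 1 (default) or 2; with 2 a second deflection follows at
#'   one interstimulus interval (125 ms), mimicking overlapping responses.
#' @param noise_sd_uV background EEG standard deviation (default 2,
#'   making the full-amplitude electrodes a high-SNR reference subject;
#'   raise toward 10 for realistic single-trial SNR stress tests).
#' @param noise_band band limits of the background noise in Hz
#'   (default `c(0.1, 12)`, the post-filter ERP band).
#' @param seed master seed for the generator.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_electrodes = 10,
                       electrodes = c("Fz", "C4", "Cz", "C3", "P4",
                                      "Pz", "P3", "PO8", "Oz", "PO7"),
                       sampling_rate_hz = 256, epoch_ms = 800,
                       n_p300_train = 480, n_nonp300_train = 2400,
                       n_p300_valid = 150, n_nonp300_valid = 750,
                       p300_amplitude_uV = 8 * c(1, 1, 1, 0.5, 0.5, 0.5,
                                                 0.5, 0, 0, 0),
                       p300_latency_ms = 350, jitter_sd_ms = 20,
                       p300_width_ms = 45, n_bumps = 1,
                       noise_sd_uV = 2, noise_band = c(0.1, 12),
                       seed = 1) {
  n_electrodes <- as.integer(n_electrodes)
  if (length(electrodes) != n_electrodes) {
    electrodes <- if (length(electrodes) > n_electrodes) electrodes[seq_len(n_electrodes)]
                  else paste0("E", seq_len(n_electrodes))
  }
  amp <- rep_len(p300_amplitude_uV, n_electrodes)
  counts <- c(n_p300_train, n_nonp300_train, n_p300_valid, n_nonp300_valid)
  if (any(counts < 0)) abort("trial counts must be nonnegative.")
  if (epoch_ms < p300_latency_ms + 3 * p300_width_ms) {
    abort("epoch must be long enough to contain latency + 3 x width.")
  }
  if (any(amp < 0) || noise_sd_uV < 0) abort("amplitudes must be nonnegative.")
  stopifnot(n_bumps %in% c(1, 2))
  structure(list(n_electrodes = n_electrodes, electrodes = electrodes,
                 sampling_rate_hz = sampling_rate_hz, epoch_ms = epoch_ms,
                 n_p300_train = n_p300_train, n_nonp300_train = n_nonp300_train,
                 n_p300_valid = n_p300_valid, n_nonp300_valid = n_nonp300_valid,
                 p300_amplitude_uV = amp, p300_latency_ms = p300_latency_ms,
                 jitter_sd_ms = jitter_sd_ms, p300_width_ms = p300_width_ms,
                 n_bumps = as.integer(n_bumps), noise_sd_uV = noise_sd_uV,
                 noise_band = noise_band, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a labeled oddball ERP dataset
#'
#' Generates training and validation epoch sets under a [sim_config()]:
#' non-P300 epochs are band-limited background noise; P300 epochs add a
#' positive Gaussian deflection at a per-trial jittered latency, scaled by
#' the per-electrode amplitude. Background noise is synthesized as one
#' continuous band-limited stream per electrode and sliced into epochs.
#' Fully deterministic for a fixed config seed.
#'
#' @param config a [sim_config()].
#' @return A list with `train` and `valid` (`epoch_set`s), `truth` (a
#'   tibble recording each trial's set, label, injected latency and
#'   per-electrode peak amplitudes), `bump` (the unit-amplitude deflection
#'   waveform at nominal latency, length T), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_hz
  Tn <- floor(config$epoch_ms / 1000 * fs)
  t_ms <- (seq_len(Tn) - 1) / fs * 1000
  bump_at <- function(lat) {
    b <- exp(-(t_ms - lat)^2 / (2 * config$p300_width_ms^2))
    if (config$n_bumps == 2) {
      b <- b + exp(-(t_ms - lat - 125)^2 / (2 * config$p300_width_ms^2))
    }
    b
  }
  gen_set <- function(nP, nN, seed) {
    n <- nP + nN
    labels <- c(rep("P300", nP), rep("NONP300", nN))
    arr <- array(0, c(n, config$n_electrodes, Tn))
    lat <- rep(NA_real_, n)
    withr::with_seed(seed, {
      if (n > 0) {
        bf <- signal::butter(4, config$noise_band / (fs / 2), type = "pass")
        pad <- 4 * fs
        for (c in seq_len(config$n_electrodes)) {
          w <- rnorm(n * Tn + 2 * pad)
          f <- signal::filtfilt(bf, w)
          f <- f[(pad + 1):(pad + n * Tn)]
          f <- f / sd(f) * config$noise_sd_uV
          arr[, c, ] <- matrix(f, nrow = n, ncol = Tn, byrow = TRUE)
        }
      }
      if (nP > 0) {
        lat[seq_len(nP)] <- config$p300_latency_ms +
          rnorm(nP, 0, config$jitter_sd_ms)
        for (i in seq_len(nP)) {
          b <- bump_at(lat[i])
          for (c in seq_len(config$n_electrodes)) {
            arr[i, c, ] <- arr[i, c, ] + config$p300_amplitude_uV[c] * b
          }
        }
      }
    })
    list(ep = epoch_set(arr, labels, config$electrodes, fs, config$epoch_ms),
         lat = lat, labels = labels)
  }
  tr <- gen_set(config$n_p300_train, config$n_nonp300_train,
                derive_seed(config$seed, 11))
  va <- gen_set(config$n_p300_valid, config$n_nonp300_valid,
                derive_seed(config$seed, 13))
  truth <- dplyr::bind_rows(
    tibble(set = "train", trial = seq_along(tr$labels), label = tr$labels,
           latency_ms = tr$lat),
    tibble(set = "valid", trial = seq_along(va$labels), label = va$labels,
           latency_ms = va$lat))
  truth$amplitudes <- list(stats::setNames(config$p300_amplitude_uV,
                                           config$electrodes))
  list(train = tr$ep, valid = va$ep, truth = truth,
       bump = bump_at(config$p300_latency_ms), config = config)
}

#' Chains of the printed worked examples
#'
#' Returns the four 16-symbol chains shipped with the package as a
#' plain-text fixture: the subject template, the P300 and non-P300
#' candidate chains of the distance worked example, and the discretized
#' ERP chain of the tortuosity worked example. Useful as golden inputs for
#' the chain operations.
#'
#' @return A named list of `shcc_chain`s: `template`, `p300`, `nonp300`,
#'   `fig1`.
#' @examples
#' ch <- make_fixture_chains()
#' chain_distance(ch$template, ch$p300)
#' @export
make_fixture_chains <- function() {
  path <- system.file("extdata", "printed_chains.txt", package = "erpshape",
                      mustWork = TRUE)
  chains <- read_chains(path)
  stats::setNames(chains, c("template", "p300", "nonp300", "fig1"))
}
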