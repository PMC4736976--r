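#' Labeled ERP epoch sets
#'
#' An `epoch_set` holds epoched EEG trials as a 3-axis numeric array
#' (trial x electrode x sample, amplitudes in microvolts) together with a
#' per-trial class label (`"P300"` or `"NONP300"`), ordered electrode
#' names, the sampling rate and the epoch duration. It is the container
#' for the training and validation collections that the calibration and
#' validation stages consume.
#'
#' @param data numeric array with dimensions trial x electrode x sample.
#' @param labels character vector, one of `"P300"`/`"NONP300"` per trial.
#' @param electrodes unique electrode names, one per electrode axis entry
#'   (10-20 system names such as `"Fz"`, `"Cz"`, `"PO8"`).
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @param epoch_ms positive epoch duration in milliseconds.
#' @return An object of class `epoch_set`.
#' @examples
#' x <- epoch_set(array(rnorm(2 * 1 * 8), c(2, 1, 8)),
#'                labels = c("P300", "NONP300"), electrodes = "Cz",
#'                sampling_rate_hz = 10, epoch_ms = 800)
#' n_trials(x)
#' @export
epoch_set <- function(data, labels, electrodes, sampling_rate_hz, epoch_ms) {
  if (!is.array(data) || length(dim(data)) != 3 || !is.numeric(data)) {
    abort("`data` must be a numeric 3-axis array (trial x electrode x sample).")
  }
  d <- dim(data)
  if (d[3] < 2) abort("every trial must have at least 2 samples.")
  labels <- as.character(labels)
  if (length(labels) != d[1]) {
    abort(sprintf("label count (%d) does not match trial count (%d).",
                  length(labels), d[1]))
  }
  bad <- setdiff(unique(labels), c("P300", "NONP300"))
  if (length(bad) > 0) {
    abort(sprintf("unknown label token(s): %s (expected P300/NONP300).",
                  paste(bad, collapse = ", ")))
  }
  electrodes <- as.character(electrodes)
  if (length(electrodes) != d[2]) {
    abort(sprintf("electrode name count (%d) does not match electrode axis (%d).",
                  length(electrodes), d[2]))
  }
  if (anyDuplicated(electrodes)) abort("electrode names must be unique.")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("`sampling_rate_hz` must be a positive number.")
  }
  if (!is.numeric(epoch_ms) || epoch_ms <= 0) {
    abort("`epoch_ms` must be a positive number.")
  }
  structure(
    list(data = data, labels = labels, electrodes = electrodes,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         epoch_ms = as.numeric(epoch_ms)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d electrodes x %d samples @ %g Hz (%g ms)\n",
              d[1], d[2], d[3], x$sampling_rate_hz, x$epoch_ms))
  cat(sprintf("  labels: %d P300, %d NONP300\n",
              sum(x$labels == "P300"), sum(x$labels == "NONP300")))
  cat(sprintf("  electrodes: %s\n", paste(x$electrodes, collapse = ", ")))
  invisible(x)
}

#' @rdname epoch_set
#' @param x an `epoch_set`.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname epoch_set
#' @export
n_electrodes <- function(x) dim(x$data)[2]

#' @rdname epoch_set
#' @export
n_samples <- function(x) dim(x$data)[3]

#' Long tabular view of an epoch set
#'
#' @param x an `epoch_set`.
#' @param ... unused.
#' @return A tibble with columns `trial`, `electrode`, `label`, `sample`,
#'   `time_ms` and `amplitude`, one row per data point.
#' @exportS3Method tibble::as_tibble
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    electrode = rep(rep(x$electrodes, each = d[1]), times = d[3]),
    label = rep(x$labels, times = d[2] * d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    amplitude = as.vector(x$data)
  ) |>
    dplyr::mutate(time_ms = (.data$sample - 1) / x$sampling_rate_hz * 1000,
                  .before = "amplitude") |>
    dplyr::arrange(.data$trial, .data$electrode, .data$sample)
}

#' Subset an epoch set by trial index
#'
#' @param x an `epoch_set`.
#' @param trials integer vector of trial indices to keep (in the given order).
#' @return An `epoch_set` containing only those trials.
#' @export
epochs_subset <- function(x, trials) {
  trials <- as.integer(trials)
  if (length(trials) > 0 && (min(trials) < 1 || max(trials) > n_trials(x))) {
    abort("trial indices out of range.")
  }
  epoch_set(x$data[trials, , , drop = FALSE], x$labels[trials],
            x$electrodes, x$sampling_rate_hz, x$epoch_ms)
}

#' Extract one electrode's trials as a matrix
#'
#' @param x an `epoch_set`.
#' @param electrode electrode name (preferred) or axis index.
#' @return A trials x samples numeric matrix.
#' @export
electrode_series <- function(x, electrode) {
  if (is.character(electrode)) {
    idx <- match(electrode, x$electrodes)
    if (is.na(idx)) abort(sprintf("unknown electrode '%s'.", electrode))
  } else {
    idx <- as.integer(electrode)
    if (idx < 1 || idx > n_electrodes(x)) abort("electrode index out of range.")
  }
  m <- x$data[, idx, , drop = FALSE]
  dim(m) <- c(dim(x$data)[1], dim(x$data)[3])
  m
}

#' Read and write epoch sets
#'
#' Two on-disk representations are supported. The `"delimited"` format is
#' plain UTF-8 text: `#`-prefixed header lines record the sampling rate and
#' epoch duration, then a CSV table with header
#' `trial,electrode,label,s1..sT` holds one row per (trial, electrode) with
#' amplitudes as decimal text. The `"archive"` format is a single-file RDS
#' container serializing the full object (array, labels, electrode names,
#' rates) losslessly.
#'
#' @param path file path to read from / write to.
#' @param format `"delimited"` or `"archive"`.
#' @param epochs an `epoch_set` to write.
#' @return `load_epochs()` returns an `epoch_set`; `save_epochs()` returns
#'   `path` invisibly.
#' @examples
#' x <- epoch_set(array(rnorm(16), c(2, 1, 8)), c("P300", "NONP300"),
#'                "Cz", 10, 800)
#' f <- tempfile(fileext = ".csv")
#' save_epochs(x, f)
#' y <- load_epochs(f)
#' all.equal(x$data, y$data)
#' @export
load_epochs <- function(path, format = c("delimited", "archive")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "archive") {
    obj <- readRDS(path)
    if (!inherits(obj, "epoch_set")) abort("archive does not contain an epoch_set.")
    return(epoch_set(obj$data, obj$labels, obj$electrodes,
                     obj$sampling_rate_hz, obj$epoch_ms))
  }
  hdr <- readr::read_lines(path, n_max = 20)
  hdr <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) abort(sprintf("malformed header: missing '%s' line.", key))
    val <- suppressWarnings(as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1])))
    if (is.na(val)) abort(sprintf("malformed header: non-numeric '%s'.", key))
    val
  }
  fs <- get_meta("sampling_rate_hz")
  ms <- get_meta("epoch_ms")
  df <- suppressWarnings(readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          trial = readr::col_integer(),
                          electrode = readr::col_character(),
                          label = readr::col_character(),
                          .default = readr::col_double())))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("parse failure at line %d, column %d: expected %s, got '%s'.",
                  probs$row[1] + 1, probs$col[1], probs$expected[1],
                  probs$actual[1]))
  }
  need <- c("trial", "electrode", "label")
  if (!all(need %in% names(df))) {
    abort(sprintf("malformed header: expected columns %s.",
                  paste(need, collapse = ", ")))
  }
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  if (length(scols) < 2) abort("malformed header: need sample columns s1..sT (T >= 2).")
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  if (anyNA(df[scols])) {
    bad <- which(rowSums(is.na(df[scols])) > 0)[1]
    abort(sprintf("inconsistent row length: row %d (trial %s, electrode %s) has missing samples.",
                  bad, df$trial[bad], df$electrode[bad]))
  }

  trials <- sort(unique(df$trial))
  electrodes <- unique(df$electrode)
  ntr <- length(trials); nel <- length(electrodes); nsm <- length(scols)
  if (ntr == 0) {
    return(epoch_set(array(numeric(0), c(0, max(nel, 1), nsm)),
                     character(0), if (nel == 0) "none" else electrodes, fs, ms))
  }
  if (nrow(df) != ntr * nel) {
    abort(sprintf("incomplete table: %d rows but %d trials x %d electrodes.",
                  nrow(df), ntr, nel))
  }
  labels <- character(ntr)
  arr <- array(NA_real_, c(ntr, nel, nsm))
  ti <- match(df$trial, trials)
  ei <- match(df$electrode, electrodes)
  amp <- as.matrix(df[scols])
  for (r in seq_len(nrow(df))) arr[ti[r], ei[r], ] <- amp[r, ]
  lab_by_trial <- tapply(df$label, ti, unique)
  if (any(lengths(lab_by_trial) > 1)) {
    bad <- which(lengths(lab_by_trial) > 1)[1]
    abort(sprintf("conflicting labels for trial %s.", trials[bad]))
  }
  labels <- vapply(lab_by_trial, `[[`, character(1), 1)
  epoch_set(arr, labels, electrodes, fs, ms)
}

#' @rdname load_epochs
#' @export
save_epochs <- function(epochs, path, format = c("delimited", "archive")) {
  format <- match.arg(format)
  stopifnot(inherits(epochs, "epoch_set"))
  if (format == "archive") {
    saveRDS(epochs, path)
    return(invisible(path))
  }
  d <- dim(epochs$data)
  writeLines(c("# erpshape epoch set v1",
               sprintf("# sampling_rate_hz: %.10g", epochs$sampling_rate_hz),
               sprintf("# epoch_ms: %.10g", epochs$epoch_ms)), path)
  amp <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  df <- tibble(
    trial = rep(seq_len(d[1]), each = d[2]),
    electrode = rep(epochs$electrodes, times = d[1]),
    label = rep(epochs$labels, each = d[2])
  )
  colnames(amp) <- paste0("s", seq_len(d[3]))
  df <- dplyr::bind_cols(df, as_tibble(amp))
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Deterministic random subset of one class
#'
#' Draws `count` trials of the requested class uniformly without
#' replacement, excluding any trial index in `exclude`. This is the random
#' selection primitive used by the calibration wrapper to build templates
#' and cross-validation folds; a fixed `seed` makes the draw reproducible.
#'
#' @param epochs an `epoch_set`.
#' @param label class to draw from (`"P300"` or `"NONP300"`).
#' @param count number of trials to draw (may be 0).
#' @param seed integer seed controlling the draw.
#' @param exclude integer trial indices ineligible for selection.
#' @return A list with `epochs` (the selected trials as an `epoch_set`) and
#'   `indices` (their trial indices in the parent set, disjoint from
#'   `exclude`).
#' @export
random_subset <- function(epochs, label, count, seed, exclude = integer(0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  count <- as.integer(count)
  if (count < 0) abort("`count` must be nonnegative.")
  pool <- setdiff(which(epochs$labels == label), exclude)
  if (count > length(pool)) {
    abort(sprintf("requested %d %s trials but only %d are eligible.",
                  count, label, length(pool)))
  }
  idx <- withr::with_seed(as.integer(seed), {
    if (count == 0) integer(0) else pool[sample.int(length(pool), count)]
  })
  list(epochs = epochs_subset(epochs, idx), indices = idx)
}
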