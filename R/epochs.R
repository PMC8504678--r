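#' Epoch container
#'
#' Bundles a trial x channel x time voltage array (in microvolts) with its
#' time axis, sampling rate, montage and per-trial metadata.
#'
#' @param data Numeric array, dim = (trial, channel, time).
#' @param times Numeric vector of sample times in ms relative to stimulus
#'   onset; length must match `dim(data)[3]`.
#' @param channels Channel labels, length `dim(data)[2]`.
#' @param fs Sampling rate in Hz.
#' @param trial_meta Tibble with one row per trial (any columns; a `retained`
#'   logical column is added if absent).
#' @param montage Optional `ow_montage`.
#' @return An object of class `ow_epochs`.
#' @export
epoch_set <- function(data, times, channels, fs, trial_meta = NULL,
                      montage = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[3] != length(times)) abort("time axis length mismatch")
  if (dim(data)[2] != length(channels)) abort("channel count mismatch")
  if (is.null(trial_meta)) trial_meta <- tibble(trial = seq_len(dim(data)[1]))
  if (nrow(trial_meta) != dim(data)[1]) abort("trial_meta row count mismatch")
  if (!"retained" %in% names(trial_meta)) trial_meta$retained <- TRUE
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, times = times, channels = channels, fs = fs,
         trial_meta = as_tibble(trial_meta), montage = montage),
    class = "ow_epochs")
}

#' @export
print.ow_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ow_epochs> %d trials x %d channels x %d samples @ %g Hz, %g..%g ms\n",
              d[1], d[2], d[3], x$fs, min(x$times), max(x$times)))
  cat(sprintf("  retained: %d / %d\n", sum(x$trial_meta$retained), d[1]))
  invisible(x)
}

#' @export
dim.ow_epochs <- function(x) dim(x$data)

# number of samples for a window at rate fs; times inclusive of both ends
epoch_times <- function(window_ms, fs) {
  seq(window_ms[1], window_ms[2], by = 1000 / fs)
}

#' Subset epochs by trial
#'
#' @param epochs An `ow_epochs`.
#' @param idx Logical or integer trial index.
#' @return An `ow_epochs` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$channels,
            epochs$fs, epochs$trial_meta[idx, ], epochs$montage)
}

#' Persist and reload an epoch set as plain text
#'
#' `write_epochs()` writes a directory holding `meta.json` (time axis,
#' channels, sampling rate, trial table, montage) and `data.tsv` (one row per
#' trial-channel, samples as columns, trials varying slowest).
#'
#' @param epochs An `ow_epochs`.
#' @param dir Directory to create/write.
#' @return `read_epochs()` returns the reconstructed `ow_epochs`.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    fs = epochs$fs,
    times_ms = epochs$times,
    channels = epochs$channels,
    trial_meta = epochs$trial_meta,
    montage = if (!is.null(epochs$montage)) {
      list(circumference_cm = attr(epochs$montage, "circumference_cm"),
           channels = epochs$montage$label)
    }
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  write.table(format(flat, digits = 8, trim = TRUE, scientific = TRUE),
              file.path(dir, "data.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(read.table(file.path(dir, "data.tsv"), sep = "\t"))
  n_ch <- length(meta$channels)
  n_t <- length(meta$times_ms)
  n_trial <- nrow(flat) / n_ch
  data <- aperm(array(t(flat), dim = c(n_t, n_ch, n_trial)), c(3, 2, 1))
  montage <- NULL
  if (!is.null(meta$montage) && length(meta$montage) > 0) {
    montage <- build_montage(meta$montage$channels, meta$montage$circumference_cm)
  }
  epoch_set(data, meta$times_ms, meta$channels, meta$fs,
            as_tibble(meta$trial_meta), montage)
}

#' Export epochs as a BrainVision recording
#'
#' Concatenates the epochs into a continuous multiplexed IEEE float32 binary
#' (`.eeg`) with a text header (`.vhdr`) and a marker file (`.vmrk`) holding
#' one stimulus marker per epoch at its onset sample.
#'
#' @param epochs An `ow_epochs`.
#' @param basename Output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(epochs, basename) {
  d <- dim(epochs$data)
  n_trial <- d[1]; n_ch <- d[2]; n_t <- d[3]
  stem <- basename(basename)
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  # multiplexed: channels fastest, samples next, epochs concatenated
  flat <- aperm(epochs$data, c(2, 3, 1))
  writeBin(as.numeric(flat), eeg, size = 4, endian = "little")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    sprintf("SamplingInterval=%g", 1e6 / epochs$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), epochs$channels)
  )
  writeLines(hdr, vhdr)
  onset_sample <- (seq_len(n_trial) - 1L) * n_t +
    which.min(abs(epochs$times)) # sample index of t = 0 within each epoch
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    "[Marker Infos]",
    sprintf("Mk%d=Stimulus,S%3d,%d,1,0", seq_len(n_trial),
            rep(1L, n_trial), onset_sample)
  )
  writeLines(mrk, vmrk)
  invisible(vhdr)
}
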