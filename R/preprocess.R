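#' Artifact-rejection rule set
#'
#' @param abs_limit_uv Absolute voltage limit per sample (default 100 uV in
#'   either direction).
#' @param range_limit_uv Maximum within-trial peak-to-peak range per channel
#'   (default 100 uV).
#' @param dist_sd_limit A channel in a trial is "extreme distribution" when
#'   its trial variance lies more than this many SDs from that channel's
#'   across-trial variance distribution (default 5).
#' @param max_bad_channels Trials with more bad channels than this are
#'   rejected; otherwise bad channels are interpolated (default 3).
#' @param baseline_window Pre-stimulus window in ms used by
#'   [baseline_correct()] (default `c(-300, 0)`).
#' @param lowpass_hz Low-pass cutoff applied before rejection (default 30).
#' @return A list of class `ow_rules`.
#' @export
rejection_rules <- function(abs_limit_uv = 100, range_limit_uv = 100,
                            dist_sd_limit = 5, max_bad_channels = 3,
                            baseline_window = c(-300, 0), lowpass_hz = 30) {
  stopifnot(abs_limit_uv > 0, range_limit_uv > 0, dist_sd_limit > 0,
            max_bad_channels >= 0)
  structure(list(abs_limit_uv = abs_limit_uv, range_limit_uv = range_limit_uv,
                 dist_sd_limit = dist_sd_limit,
                 max_bad_channels = max_bad_channels,
                 baseline_window = baseline_window, lowpass_hz = lowpass_hz),
            class = "ow_rules")
}

#' Re-reference epochs
#'
#' Subtracts the per-sample mean of the reference channels from every
#' channel (the reference channels themselves included, so their re-referenced
#' mean is identically zero).
#'
#' @param epochs An `ow_epochs`.
#' @param ref_channels Labels of the reference channels (default both
#'   mastoids).
#' @return The re-referenced `ow_epochs`.
#' @export
rereference <- function(epochs, ref_channels = c("M1", "M2")) {
  ci <- match(ref_channels, epochs$channels)
  if (anyNA(ci)) {
    abort(sprintf("reference channel(s) missing: %s",
                  paste(ref_channels[is.na(ci)], collapse = ", ")))
  }
  refmean <- epochs$data[, ci[1], ]
  for (k in ci[-1]) refmean <- refmean + epochs$data[, k, ]
  refmean <- refmean / length(ci) # trial x time
  for (c in seq_along(epochs$channels)) {
    epochs$data[, c, ] <- epochs$data[, c, ] - refmean
  }
  epochs
}

# squared magnitude response of an order-`order` Butterworth low-pass at
# frequencies f (the response of forward-backward filtering)
butter_mag2 <- function(f, cutoff, order = 4) 1 / (1 + (f / cutoff)^(2 * order))

# zero-phase low-pass of a time x series matrix via frequency-domain
# application of the squared Butterworth magnitude, with even (reflection)
# extension to suppress edge wrap-around
fft_lowpass_mat <- function(M, fs, cutoff, order = 4) {
  n <- nrow(M)
  X <- rbind(M, M[n:1, , drop = FALSE])
  N <- 2L * n
  f <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1)) * fs / N
  H2 <- butter_mag2(abs(f), cutoff, order)
  out <- Re(mvfft(mvfft(X) * H2, inverse = TRUE)) / N
  out[seq_len(n), , drop = FALSE]
}

#' Zero-phase low-pass filter
#'
#' Applies a 4th-order Butterworth low-pass forward and backward
#' (zero phase). The default realization runs the compiled
#' forward-backward recursion with odd-reflection padding over all
#' channel-trial series at once; `method = "fft"` instead multiplies the
#' spectrum by the identical squared Butterworth magnitude (with even
#' reflection padding). DC gain is 1 and the two-pass response at twice the
#' cutoff is about -48 dB.
#'
#' @param epochs An `ow_epochs`.
#' @param cutoff_hz Cutoff frequency (must be below Nyquist).
#' @param method `"filtfilt"` (default) or `"fft"`.
#' @param order Filter order of the underlying one-pass design (default 4).
#' @return Filtered `ow_epochs`.
#' @export
lowpass_filter <- function(epochs, cutoff_hz = 30,
                           method = c("filtfilt", "fft"), order = 4) {
  method <- match.arg(method)
  if (cutoff_hz >= epochs$fs / 2) {
    abort(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                  cutoff_hz, epochs$fs / 2))
  }
  d <- dim(epochs$data)
  M <- t(matrix(epochs$data, nrow = d[1] * d[2], ncol = d[3])) # time x series
  filt <- if (method == "fft") {
    fft_lowpass_mat(M, epochs$fs, cutoff_hz, order)
  } else {
    bf <- signal::butter(order, cutoff_hz / (epochs$fs / 2), "low")
    .filtfilt_mat(M, bf$b / bf$a[1], bf$a / bf$a[1])
  }
  epochs$data <- array(t(filt), dim = d,
                       dimnames = list(NULL, epochs$channels, NULL))
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window so
#' that the corrected baseline mean is zero.
#'
#' @param epochs An `ow_epochs`.
#' @param window Baseline window in ms (default `c(-300, 0)`).
#' @return Corrected `ow_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-300, 0)) {
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) abort("baseline window lies outside the epoch span")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base) # time dim recycles last
  epochs
}

# per-(trial, channel) max / min / variance via the compiled row scanner
trialchan_stats <- function(data) {
  d <- dim(data)
  S <- .row_stats(matrix(data, nrow = d[1] * d[2], ncol = d[3]))
  list(mx = matrix(S[, 1], d[1], d[2]),
       mn = matrix(S[, 2], d[1], d[2]),
       v = matrix(S[, 3], d[1], d[2]))
}

#' Mark, interpolate, and reject artifact trials
#'
#' A channel within a trial is *bad* when any of three rules fires: absolute
#' voltage beyond `abs_limit_uv`, within-trial range beyond `range_limit_uv`,
#' or trial variance more than `dist_sd_limit` SDs away from that channel's
#' across-trial variance distribution. Trials with more than
#' `max_bad_channels` bad channels are rejected; otherwise each bad channel
#' is replaced by an inverse-distance-weighted average of its good
#' adjacency-graph neighbours (all good channels when no neighbour is good).
#' Non-scalp channels (e.g. mastoids) are ignored by the rules.
#'
#' @param epochs A baseline-corrected `ow_epochs`.
#' @param rules An `ow_rules` from [rejection_rules()].
#' @param adjacency An `ow_adjacency` for neighbour interpolation (built from
#'   the epochs' montage when `NULL`).
#' @return A list with elements `epochs` (bad channels interpolated,
#'   `trial_meta$retained` updated) and `report` (an `ow_preprocess_report`:
#'   `$trials` has one row per trial with the decision and the rules fired,
#'   `$rejection_fraction`, `$n_interpolated_trials`).
#' @export
reject_and_interpolate <- function(epochs, rules = rejection_rules(),
                                   adjacency = NULL) {
  scalp <- if (!is.null(epochs$montage)) epochs$montage$label else epochs$channels
  si <- match(scalp, epochs$channels)
  if (is.null(adjacency) && !is.null(epochs$montage)) {
    adjacency <- build_adjacency(epochs$montage)
  }
  sub <- epochs$data[, si, , drop = FALSE]
  n_trial <- dim(sub)[1]
  st <- trialchan_stats(sub)
  mx <- st$mx
  mn <- st$mn
  v <- st$v
  bad_abs <- pmax(mx, -mn) > rules$abs_limit_uv
  bad_range <- (mx - mn) > rules$range_limit_uv
  mu_v <- colMeans(v)
  sd_v <- apply(v, 2, sd)
  z <- sweep(sweep(v, 2, mu_v), 2, pmax(sd_v, 1e-12), "/")
  bad_dist <- abs(z) > rules$dist_sd_limit
  bad <- bad_abs | bad_range | bad_dist

  n_bad <- rowSums(bad)
  rejected <- n_bad > rules$max_bad_channels
  interp_needed <- !rejected & n_bad > 0

  D <- if (!is.null(epochs$montage)) {
    electrode_distances(epochs$montage)
  }
  for (i in which(interp_needed)) {
    bad_ch <- which(bad[i, ])
    good_ch <- which(!bad[i, ])
    for (b in bad_ch) {
      nbrs <- if (!is.null(adjacency)) {
        intersect(match(adjacency[[scalp[b]]], scalp), good_ch)
      } else {
        integer(0)
      }
      if (length(nbrs) == 0) nbrs <- good_ch
      wgt <- if (!is.null(D)) 1 / pmax(D[b, nbrs], 1e-9) else rep(1, length(nbrs))
      wgt <- wgt / sum(wgt)
      vals <- matrix(epochs$data[i, si[nbrs], , drop = FALSE],
                     nrow = length(nbrs))
      epochs$data[i, si[b], ] <- colSums(vals * wgt)
    }
  }
  epochs$trial_meta$retained <- epochs$trial_meta$retained & !rejected

  rules_fired <- lapply(seq_len(n_trial), function(i) {
    out <- character(0)
    if (any(bad_abs[i, ])) out <- c(out, "abs")
    if (any(bad_range[i, ] & !bad_abs[i, ])) out <- c(out, "range")
    if (any(bad_dist[i, ] & !bad_abs[i, ] & !bad_range[i, ])) out <- c(out, "dist")
    out
  })
  trials <- tibble(
    trial = seq_len(n_trial),
    decision = dplyr::case_when(rejected ~ "rejected",
                                interp_needed ~ "interpolated",
                                TRUE ~ "retained"),
    n_bad = n_bad,
    bad_channels = lapply(seq_len(n_trial), function(i) scalp[bad[i, ]]),
    bad_abs_channels = lapply(seq_len(n_trial), function(i) scalp[bad_abs[i, ]]),
    rules_fired = rules_fired
  )
  epochs$trial_meta$interpolated_channels <- ifelse(
    interp_needed, trials$bad_channels, list(character(0)))
  report <- structure(list(
    trials = trials,
    rejection_fraction = mean(rejected),
    n_interpolated_trials = sum(interp_needed)
  ), class = "ow_preprocess_report")
  list(epochs = epochs, report = report)
}

#' @export
print.ow_preprocess_report <- function(x, ...) {
  cat(sprintf("<ow_preprocess_report> %d trials: %d retained clean, %d interpolated, %d rejected (%.2f%%)\n",
              nrow(x$trials), sum(x$trials$decision == "retained"),
              x$n_interpolated_trials,
              sum(x$trials$decision == "rejected"),
              100 * x$rejection_fraction))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Re-references to the mastoids (when present), low-pass filters, baseline
#' corrects, and applies [reject_and_interpolate()].
#'
#' @param epochs An `ow_epochs`.
#' @param rules An `ow_rules`.
#' @param adjacency Optional `ow_adjacency`.
#' @return As [reject_and_interpolate()].
#' @export
preprocess_epochs <- function(epochs, rules = rejection_rules(),
                              adjacency = NULL) {
  if (all(c("M1", "M2") %in% epochs$channels)) {
    epochs <- rereference(epochs, c("M1", "M2"))
  }
  epochs <- lowpass_filter(epochs, rules$lowpass_hz)
  epochs <- baseline_correct(epochs, rules$baseline_window)
  reject_and_interpolate(epochs, rules, adjacency)
}
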