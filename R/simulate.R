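#' Configuration of the synthetic epoch generator
#'
#' Collects every tunable of the forward model. The defaults are the study
#' conditions the package was designed around: 29 analyzed participants,
#' 1 kHz sampling, epochs from -300 to 1200 ms around a 820 ms disyllabic
#' stimulus, habituated standards and a slow within-sub-block amplitude ramp
#' (the split-half growth effect).
#'
#' @param n_participants Number of simulated participants (default 29).
#' @param components Component table, see [default_components()].
#' @param habituation_factor Multiplier applied to every component on
#'   standards (default 0.6): identity difference waves retain a residual
#'   `1 - habituation_factor` of components shared by both roles.
#' @param ramp_gain Linear per-trial amplitude growth: trial `i` of `n` is
#'   scaled by `1 + ramp_gain * i / n` (default 0.3, planting a second-half >
#'   first-half effect).
#' @param noise_sd Total additive noise SD per channel and sample, in uV
#'   (default 8).
#' @param one_over_f_weight Fraction of noise variance carried by the
#'   1/f-shaped process, remainder white (default 0.5).
#' @param spatial_smoothing Smooth noise across neighbouring channels via the
#'   montage adjacency graph (default `TRUE`).
#' @param artifact_rate Per-trial probability of an injected artifact
#'   (default 0.02); see [inject_artifacts()].
#' @param participant_amp_sd SD of the per-participant lognormal amplitude
#'   gain (default 0.2; 0 disables between-participant amplitude
#'   variability).
#' @param participant_lat_sd SD in ms of the per-participant latency shift
#'   applied to all components (default 8).
#' @param sampling_rate Hz (default 1000).
#' @param epoch_window Epoch span in ms relative to stimulus onset
#'   (default `c(-300, 1200)`).
#' @param include_mastoids Simulate M1/M2 reference channels as
#'   near-zero-signal channels carrying only `mastoid_noise_sd` white noise
#'   (default `TRUE`), so the re-referencing stage is exercised.
#' @param mastoid_noise_sd uV (default 2).
#' @param seed Base integer seed; all per-participant / per-sub-block streams
#'   are derived from it deterministically.
#' @return A list of class `ow_generator_config`.
#' @export
generator_config <- function(n_participants = 29,
                             components = default_components(),
                             habituation_factor = 0.6,
                             ramp_gain = 0.3,
                             noise_sd = 8,
                             one_over_f_weight = 0.5,
                             spatial_smoothing = TRUE,
                             artifact_rate = 0.02,
                             participant_amp_sd = 0.2,
                             participant_lat_sd = 8,
                             sampling_rate = 1000,
                             epoch_window = c(-300, 1200),
                             include_mastoids = TRUE,
                             mastoid_noise_sd = 2,
                             seed = 1L) {
  stopifnot_scalar_number(habituation_factor, "habituation_factor", 0, 1)
  stopifnot_scalar_number(artifact_rate, "artifact_rate", 0, 1)
  stopifnot_scalar_number(one_over_f_weight, "one_over_f_weight", 0, 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", 1)
  stopifnot(length(epoch_window) == 2, epoch_window[1] < epoch_window[2])
  structure(list(
    n_participants = as.integer(n_participants),
    components = components,
    habituation_factor = habituation_factor,
    ramp_gain = ramp_gain,
    noise_sd = noise_sd,
    one_over_f_weight = one_over_f_weight,
    spatial_smoothing = spatial_smoothing,
    artifact_rate = artifact_rate,
    participant_amp_sd = participant_amp_sd,
    participant_lat_sd = participant_lat_sd,
    sampling_rate = sampling_rate,
    epoch_window = epoch_window,
    include_mastoids = include_mastoids,
    mastoid_noise_sd = mastoid_noise_sd,
    seed = as.integer(seed)
  ), class = "ow_generator_config")
}

# channel x time signal matrix for one (condition, role) cell;
# mastoid rows (if any) stay zero.
component_signal <- function(cfg, montage, times, condition_id, role, sandhi,
                             amp_gain = 1, lat_shift = 0) {
  n_scalp <- nrow(montage)
  S <- matrix(0, n_scalp, length(times))
  P <- montage_xyz(montage)
  for (k in seq_len(nrow(cfg$components))) {
    comp <- cfg$components[k, ]
    if (!component_applies(comp, condition_id, role, sandhi)) next
    ci <- match(comp$spatial_center, montage$label)
    if (is.na(ci)) {
      abort(sprintf("component spatial_center %s not in montage", comp$spatial_center))
    }
    d <- sqrt(colSums((t(P) - P[ci, ])^2))
    w <- exp(-0.5 * (d / comp$spatial_sd_cm)^2)
    g <- exp(-0.5 * ((times - comp$peak_latency_ms - lat_shift) /
                       comp$temporal_sd_ms)^2)
    S <- S + (comp$amplitude * amp_gain) * outer(w, g)
  }
  S
}

# white + 1/f Gaussian noise for m series of n samples: unit marginal
# variance, the 1/f part synthesized by the compiled stationary pink filter
shaped_noise <- function(n, m, w_pink) {
  stopifnot(w_pink >= 0, w_pink <= 1)
  .shaped_noise_cpp(as.integer(n), as.integer(m), w_pink)
}

# spatial smoothing kernel over scalp channels: identity + half-weighted
# neighbours, rows scaled to unit L2 norm so marginal noise SD is preserved
smoothing_kernel <- function(adjacency) {
  A <- adjacency_matrix(adjacency)
  K <- diag(nrow(A)) + 0.5 * A
  K / sqrt(rowSums(K^2))
}

#' Forward-simulate the epochs of one oddball sub-block
#'
#' Every trial is the sum of the applicable components (each a unit-peak
#' Gaussian in time times a unit-peak Gaussian spatial falloff around its
#' centre electrode, so `amplitude` is the literal peak voltage), scaled by
#' `habituation_factor` on standards and by the per-trial ramp
#' `1 + ramp_gain * i / n`, plus white + 1/f channel noise (optionally
#' smoothed over neighbouring channels), plus injected artifacts at
#' `artifact_rate`. Deterministic given `cfg$seed`, `participant` and the
#' sub-block.
#'
#' @param spec One row of [condition_catalog()].
#' @param seq The matching `ow_sequence` from [generate_sequence()].
#' @param cfg An `ow_generator_config`.
#' @param montage An `ow_montage` of scalp channels.
#' @param participant Participant id (integer); drives the per-participant
#'   amplitude gain and latency shift streams.
#' @return An `ow_epochs` whose `trial_meta` records participant, block,
#'   direction, condition, role, token, experiment half, and the artifact
#'   injection log.
#' @export
simulate_subblock <- function(spec, seq, cfg, montage, participant = 1L) {
  spec <- as.list(spec)
  n_trial <- nrow(seq)
  times <- epoch_times(cfg$epoch_window, cfg$sampling_rate)
  n_t <- length(times)
  scalp <- montage$label
  channels <- c(scalp, if (cfg$include_mastoids) c("M1", "M2"))
  n_ch <- length(channels)
  inv <- stimulus_inventory()
  sandhi_lex <- unique(inv$lexeme[inv$sandhi])

  sb_index <- match(spec$block, c("A", "B", "C", "D")) +
    4L * (spec$direction == "Reversed")
  seed_pp <- derive_seed(cfg$seed, 7L + as.integer(participant))
  seed_sb <- derive_seed(cfg$seed, as.integer(participant) * 64L + sb_index)

  # participant-level amplitude gain / latency shift (own stream so the
  # same participant gets the same physiology in every sub-block)
  pp <- with_seed(seed_pp, {
    list(gain = if (cfg$participant_amp_sd > 0)
      exp(rnorm(1, 0, cfg$participant_amp_sd)) else 1,
      shift = if (cfg$participant_lat_sd > 0)
        rnorm(1, 0, cfg$participant_lat_sd) else 0)
  })

  with_seed(seed_sb, {
    data <- array(0, dim = c(n_trial, n_ch, n_t))
    for (r in c("standard", "deviant")) {
      idx <- which(seq$role == r)
      if (length(idx) == 0) next
      sandhi <- seq$lexeme[idx[1]] %in% sandhi_lex
      S <- component_signal(cfg, montage, times, spec$condition_id, r, sandhi,
                            amp_gain = pp$gain, lat_shift = pp$shift)
      gains <- (1 + cfg$ramp_gain * idx / n_trial) *
        (if (r == "standard") cfg$habituation_factor else 1)
      sig <- outer(gains, S) # trial x channel x time
      data[idx, seq_along(scalp), ] <- data[idx, seq_along(scalp), , drop = FALSE] + sig
    }
    if (cfg$noise_sd > 0) {
      K <- if (cfg$spatial_smoothing) {
        smoothing_kernel(build_adjacency(montage))
      }
      n_sc <- length(scalp)
      chunk <- max(1L, floor(4e6 / (n_t * n_sc)))
      for (i0 in seq(1L, n_trial, by = chunk)) {
        ii <- i0:min(n_trial, i0 + chunk - 1L)
        ns <- shaped_noise(n_t, length(ii) * n_sc, cfg$one_over_f_weight)
        # columns are (channel, trial) series; mix channels at fixed
        # (time, trial) with one kernel matmul
        nz <- array(ns, dim = c(n_t, n_sc, length(ii)))
        if (!is.null(K)) {
          nz <- aperm(nz, c(2, 1, 3))
          dim(nz) <- c(n_sc, n_t * length(ii))
          nz <- K %*% nz
          dim(nz) <- c(n_sc, n_t, length(ii))
          nz <- aperm(nz, c(2, 1, 3))
        }
        data[ii, seq_len(n_sc), ] <- data[ii, seq_len(n_sc), , drop = FALSE] +
          cfg$noise_sd * aperm(nz, c(3, 2, 1))
      }
      if (cfg$include_mastoids && cfg$mastoid_noise_sd > 0) {
        data[, n_ch - 1:0, ] <- data[, n_ch - 1:0, ] +
          rnorm(n_trial * 2 * n_t, 0, cfg$mastoid_noise_sd)
      }
    }
    meta <- tibble(
      participant = as.integer(participant),
      block = spec$block,
      direction = spec$direction,
      sub_block = paste0(spec$direction, "-", spec$block),
      condition_id = spec$condition_id,
      position = seq$position,
      role = seq$role,
      lexeme = seq$lexeme,
      rendition = seq$rendition,
      token = seq$token,
      half = ifelse(seq$position <= n_trial / 2, "first", "second"),
      retained = TRUE
    )
    ep <- epoch_set(data, times, channels, cfg$sampling_rate, meta, montage)
    if (cfg$artifact_rate > 0) {
      ep <- inject_artifacts(ep, cfg, seed = derive_seed(seed_sb, 999L))
    } else {
      ep$trial_meta$artifact_type <- NA_character_
      ep$trial_meta$artifact_channels <- vector("list", n_trial)
    }
    ep
  })
}

#' Inject synthetic artifacts into epochs
#'
#' Each trial independently receives, with probability `cfg$artifact_rate`,
#' one of three artifact classes chosen uniformly:
#'
#' * `"blink"` - a >100 uV Gaussian-shaped frontal deflection on 1-3 frontal
#'   channels (interpolable under the default rules);
#' * `"multi"` - the same deflection on 4-8 random scalp channels (forces
#'   trial rejection under the more-than-three-bad-channels rule);
#' * `"noisy"` - one channel gets additional white noise (SD 20 uV) across
#'   the whole trial (caught by the 5-SD trial-variance rule).
#'
#' Deflections are centred in 150-900 ms so the pre-stimulus baseline stays
#' clean. The injection log is recorded in `trial_meta` columns
#' `artifact_type` and `artifact_channels`.
#'
#' @param epochs An `ow_epochs`.
#' @param cfg An `ow_generator_config` (only `artifact_rate` is used).
#' @param seed Seed for the injection stream (default derived from
#'   `cfg$seed`).
#' @return The modified `ow_epochs`.
#' @export
inject_artifacts <- function(epochs, cfg, seed = derive_seed(cfg$seed, 999L)) {
  n_trial <- dim(epochs$data)[1]
  epochs$trial_meta$artifact_type <- NA_character_
  epochs$trial_meta$artifact_channels <- vector("list", n_trial)
  if (cfg$artifact_rate <= 0) return(epochs)
  scalp <- if (!is.null(epochs$montage)) epochs$montage$label else epochs$channels
  frontal <- intersect(c("FP1", "FP2", "FPz", "F7", "F8"), scalp)
  with_seed(seed, {
    hit <- which(runif(n_trial) < cfg$artifact_rate)
    for (i in hit) {
      type <- sample(c("blink", "multi", "noisy"), 1)
      if (type == "blink") {
        chs <- sample(frontal, sample(1:3, 1))
      } else if (type == "multi") {
        chs <- sample(scalp, min(sample(4:8, 1), length(scalp)))
      } else {
        chs <- sample(scalp, 1)
      }
      ci <- match(chs, epochs$channels)
      if (type == "noisy") {
        epochs$data[i, ci, ] <- epochs$data[i, ci, ] +
          rnorm(length(epochs$times), 0, 20)
      } else {
        centre <- runif(1, 150, 900)
        amp <- runif(1, 130, 160)
        kern <- amp * exp(-0.5 * ((epochs$times - centre) / 50)^2)
        epochs$data[i, ci, ] <- epochs$data[i, ci, , drop = FALSE] +
          rep(kern, each = length(ci))
      }
      epochs$trial_meta$artifact_type[i] <- type
      epochs$trial_meta$artifact_channels[[i]] <- chs
    }
    epochs
  })
}
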