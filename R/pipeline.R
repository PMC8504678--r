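#' Simulate and preprocess a whole oddball study
#'
#' Runs the full generator for every participant and sub-block: sequence
#' generation, forward simulation, preprocessing (mastoid re-reference,
#' low-pass, baseline, rejection/interpolation), and per-role averaging.
#' Only the condition averages and the preprocessing reports are kept, so
#' memory stays flat in the number of participants.
#'
#' @param cfg An `ow_generator_config`.
#' @param montage An `ow_montage` (default the 31-channel cap).
#' @param catalog Sub-block catalogue (default [condition_catalog()]).
#' @param participants Integer vector of participant ids (default
#'   `1:cfg$n_participants`).
#' @param rules An `ow_rules` for preprocessing, or `NULL` to skip
#'   preprocessing (averages are taken over raw simulated trials).
#' @param by_half Also compute averages per experiment half (for split-half
#'   analyses).
#' @return A list of class `ow_study`: `$erps` (tibble: `participant`,
#'   `block`, `direction`, `sub_block`, `condition_id`, `role`, `half`
#'   (`"all"`, `"first"`, `"second"`), `n_trials`, `wave` list-column of
#'   `ow_erp`), `$reports` (tibble of per-sub-block rejection summaries),
#'   `$montage`, `$cfg`.
#' @export
simulate_study <- function(cfg, montage = build_montage(),
                           catalog = condition_catalog(),
                           participants = seq_len(cfg$n_participants),
                           rules = rejection_rules(), by_half = FALSE) {
  adjacency <- build_adjacency(montage)
  erp_rows <- list()
  rep_rows <- list()
  for (pp in participants) {
    for (b in seq_len(nrow(catalog))) {
      spec <- catalog[b, ]
      sb_index <- match(spec$block, c("A", "B", "C", "D")) +
        4L * (spec$direction == "Reversed")
      seq <- generate_sequence(spec, seed = derive_seed(cfg$seed,
                                                        pp * 64L + sb_index))
      ep <- simulate_subblock(spec, seq, cfg, montage, participant = pp)
      if (!is.null(rules)) {
        pre <- preprocess_epochs(ep, rules, adjacency)
        ep <- pre$epochs
        rep_rows[[length(rep_rows) + 1]] <- tibble(
          participant = pp, sub_block = spec$sub_block,
          rejection_fraction = pre$report$rejection_fraction,
          n_interpolated = pre$report$n_interpolated_trials)
      }
      halves <- if (by_half) c("all", "first", "second") else "all"
      for (role in c("standard", "deviant")) {
        for (h in halves) {
          sel <- if (h == "all") NULL else ep$trial_meta$half == h
          erp <- average_condition(ep, role, which = sel)
          erp_rows[[length(erp_rows) + 1]] <- tibble(
            participant = pp, block = spec$block, direction = spec$direction,
            sub_block = spec$sub_block, condition_id = spec$condition_id,
            role = role, half = h, n_trials = erp$n_trials, wave = list(erp))
        }
      }
    }
  }
  structure(list(erps = dplyr::bind_rows(erp_rows),
                 reports = if (length(rep_rows)) dplyr::bind_rows(rep_rows)
                 else NULL,
                 montage = montage, cfg = cfg),
            class = "ow_study")
}

#' @export
print.ow_study <- function(x, ...) {
  cat(sprintf("<ow_study> %d participants x %d sub-block ERPs\n",
              length(unique(x$erps$participant)),
              length(unique(x$erps$sub_block))))
  invisible(x)
}

#' Per-participant difference waves of a simulated study
#'
#' Builds the identity waves #1-#4 and the derived effect waves #5-#9 for
#' every participant of an [simulate_study()] result.
#'
#' @param study An `ow_study`.
#' @param half `"all"` (default), `"first"`, or `"second"`.
#' @return Tibble with `participant`, `index` (1-9), `identity`, `wave`
#'   (list of `ow_wave`).
#' @export
study_waves <- function(study, half = "all") {
  erps <- study$erps[study$erps$half == half, ]
  rows <- purrr::map(sort(unique(erps$participant)), function(pp) {
    w14 <- identity_waves(erps, pp)
    for (k in names(w14)) w14[[k]]$participant <- pp
    w59 <- derive_waves(w14)
    for (k in names(w59)) w59[[k]]$participant <- pp
    all_w <- c(w14, w59)
    tibble(participant = pp,
           index = vapply(all_w, `[[`, NA_integer_, "index"),
           identity = vapply(all_w, `[[`, NA, "identity"),
           wave = unname(all_w))
  })
  dplyr::bind_rows(rows)
}

#' Point measures for all participants and conditions
#'
#' Applies [measure_wave()] to the identity difference waves #1-#4 of every
#' participant.
#'
#' @param waves Tibble from [study_waves()].
#' @param cfg An `ow_measure_config`.
#' @param electrodes Electrode subset (default all).
#' @return Tidy tibble: one row per participant x condition x electrode.
#' @export
study_measures <- function(waves, cfg = measure_config(), electrodes = NULL) {
  sel <- waves[waves$index %in% 1:4, ]
  purrr::map(seq_len(nrow(sel)), function(i) {
    measure_wave(sel$wave[[i]], cfg, electrodes)
  }) |> dplyr::bind_rows()
}

#' Grand-average a set of waves
#'
#' @param waves Tibble from [study_waves()] (or list of `ow_wave`).
#' @param index Difference-wave index to average (when `waves` is a tibble).
#' @return An `ow_wave` holding the unweighted participant mean.
#' @export
grand_average <- function(waves, index = NULL) {
  if (is.data.frame(waves)) {
    if (!is.null(index)) waves <- waves[waves$index == index, ]
    waves <- waves$wave
  }
  out <- collapse_waves(waves, index = waves[[1]]$index)
  out$participant <- NA_integer_
  out$formula <- sprintf("grand average of %d participants", length(waves))
  out
}
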