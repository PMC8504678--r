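#' Point-measure configuration
#'
#' @param window Measurement window in ms. The transitional positivity is
#'   conventionally measured over 250-400 ms, the S2 negativity over
#'   550-700 ms.
#' @param polarity `"positive"` or `"negative"`: the polarity whose peak and
#'   area are measured; samples of the other polarity contribute zero to the
#'   signed area.
#' @param upsample_factor Integer up-sampling factor by linear interpolation
#'   before measurement (default 2, damping high-frequency noise influence
#'   on latency estimates).
#' @param fraction Fraction for the fractional latency measures (default
#'   0.5).
#' @return A list of class `ow_measure_config`.
#' @export
measure_config <- function(window = c(250, 400),
                           polarity = c("positive", "negative"),
                           upsample_factor = 2, fraction = 0.5) {
  polarity <- match.arg(polarity)
  stopifnot_scalar_number(fraction, "fraction", 1e-9, 1 - 1e-9)
  stopifnot(upsample_factor >= 1, upsample_factor == round(upsample_factor))
  structure(list(window = window, polarity = polarity,
                 upsample_factor = as.integer(upsample_factor),
                 fraction = fraction),
            class = "ow_measure_config")
}

# trapezoid cumulative integral; returns vector same length as x with cum[1]=0
cum_trapz <- function(t, x) {
  c(0, cumsum(diff(t) * (head(x, -1) + tail(x, -1)) / 2))
}

# measure a single waveform (numeric vector over `times`)
measure_series <- function(v, times, cfg) {
  sel <- times >= cfg$window[1] & times <= cfg$window[2]
  if (sum(sel) < 2) abort("measurement window contains fewer than 2 samples")
  dt <- times[2] - times[1]
  tt <- seq(min(times[sel]), max(times[sel]), by = dt / cfg$upsample_factor)
  vv <- approx(times, v, xout = tt)$y
  sgn <- if (cfg$polarity == "positive") 1 else -1
  u <- sgn * vv # work in the polarity's frame: peaks are maxima

  mean_amplitude <- mean(vv)
  gated <- pmax(u, 0)
  area <- cum_trapz(tt, gated)
  signed_area <- sgn * area[length(area)]

  out <- tibble(mean_amplitude = mean_amplitude,
                signed_area = signed_area,
                peak_time = NA_real_, peak_amplitude = NA_real_,
                frac_prepeak_latency = NA_real_,
                frac_area_latency = NA_real_,
                prepeak_flagged = FALSE, polarity_missing = FALSE)
  if (all(u <= 0)) { # no sample of the required polarity
    out$polarity_missing <- TRUE
    return(out)
  }
  pk <- which.max(u)
  out$peak_time <- tt[pk]
  out$peak_amplitude <- sgn * u[pk]
  target <- cfg$fraction * u[pk]
  # walk backward from the peak to the latest crossing of fraction * peak
  j <- pk
  while (j > 1 && u[j - 1] >= target) j <- j - 1
  if (j == 1) {
    out$frac_prepeak_latency <- tt[1] # no crossing inside the window
    out$prepeak_flagged <- TRUE
  } else {
    out$frac_prepeak_latency <- tt[j - 1] +
      (target - u[j - 1]) / (u[j] - u[j - 1]) * (tt[j] - tt[j - 1])
  }
  tot <- area[length(area)]
  half <- cfg$fraction * tot
  k <- which(area >= half)[1]
  out$frac_area_latency <- if (k == 1) tt[1] else {
    tt[k - 1] + (half - area[k - 1]) / (area[k] - area[k - 1]) *
      (tt[k] - tt[k - 1])
  }
  out
}

#' Point measures of a difference wave
#'
#' Computes, per electrode, the four standard point measures after
#' up-sampling: mean amplitude over the window (uV), signed area amplitude
#' (uV.ms; only samples of the configured polarity contribute, and the
#' result carries the polarity's sign), the fractional pre-peak latency (the
#' latest pre-peak time at which the waveform crosses `fraction` times the
#' peak amplitude, linearly interpolated), and the fractional area latency
#' (the time at which the cumulative polarity-gated area reaches `fraction`
#' of its total). When the window holds no sample of the required polarity
#' the latency measures are returned as `NA` and flagged, not raised as
#' errors.
#'
#' @param wave An `ow_wave` (or `ow_erp`).
#' @param cfg An `ow_measure_config`.
#' @param electrodes Electrode subset (default all channels).
#' @return A tibble with one row per electrode, carrying `participant` and
#'   `index` when the wave has them.
#' @export
measure_wave <- function(wave, cfg = measure_config(), electrodes = NULL) {
  chans <- electrodes %||% wave$channels
  ci <- match(chans, wave$channels)
  if (anyNA(ci)) abort(sprintf("electrode(s) not in wave: %s",
                               paste(chans[is.na(ci)], collapse = ", ")))
  rows <- purrr::map(seq_along(ci), function(k) {
    res <- measure_series(wave$wave[ci[k], ], wave$times, cfg)
    res$electrode <- chans[k]
    res
  })
  out <- dplyr::bind_rows(rows)
  out$participant <- wave$participant %||% NA_integer_
  out$index <- wave$index %||% NA_integer_
  dplyr::select(out, "participant", "index", "electrode",
                dplyr::everything())
}

# condition factors of the 2x2 design from the difference-wave index (1-4)
condition_factors <- function(condition_id) {
  tibble(
    condition_id = as.integer(condition_id),
    ur_relation = factor(ifelse(condition_id %in% c(1, 2), "match", "mismatch"),
                         levels = c("match", "mismatch")),
    deviant_sandhi = factor(ifelse(condition_id %in% c(2, 4), "sandhi",
                                   "nonsandhi"),
                            levels = c("nonsandhi", "sandhi"))
  )
}

#' Within-subject 2x2 inference on point measures
#'
#' Tests the main effects of *UR relation* (match vs mismatch) and *deviant
#' sandhi status* (non-sandhi vs sandhi) and their interaction on a point
#' measure taken from the four identity difference waves.
#'
#' Two methods are offered. `"lmm"` (default) fits a linear mixed model with
#' participant random effects (random slopes for both factors; automatically
#' reduced to a random intercept on convergence failure or singular fit),
#' F-tests via Satterthwaite degrees of freedom, and Bonferroni-adjusted
#' pairwise post-hoc contrasts between the four conditions. `"cell_means"`
#' first averages to participant x condition cell means and then runs exact
#' paired contrasts (one-sample t-tests on the within-participant effect
#' scores); on balanced noiseless data its estimates are the contrast
#' algebra, e.g. the interaction estimate is `(m4 - m3) - (m2 - m1)`.
#'
#' Effect estimates are reported on the data scale: `mismatch - match`,
#' `sandhi - nonsandhi`, and the difference-of-differences interaction.
#'
#' @param measures Tibble with columns `participant`, `index` (or
#'   `condition_id`), `electrode`, and the measured value.
#' @param value Name of the value column (string), e.g.
#'   `"frac_area_latency"`.
#' @param method `"lmm"` or `"cell_means"`.
#' @return An `ow_inference` object with `$effects` (term, estimate,
#'   statistic, df, p.value), `$posthoc` (Bonferroni-adjusted pairwise
#'   condition contrasts), `$method`, `$model`. Supports `tidy()` and
#'   `glance()`.
#' @export
two_by_two_inference <- function(measures, value,
                                 method = c("lmm", "cell_means")) {
  method <- match.arg(method)
  df <- as_tibble(measures)
  if (!"condition_id" %in% names(df)) df$condition_id <- df$index
  if (!all(c("participant", "condition_id") %in% names(df))) {
    abort("measures need `participant` and `index`/`condition_id` columns")
  }
  df$value <- df[[value]]
  df <- df[!is.na(df$value), ]
  have <- tidyr::expand_grid(participant = unique(df$participant),
                             condition_id = 1:4)
  missing_cells <- dplyr::anti_join(have, df,
                                    by = c("participant", "condition_id"))
  if (nrow(missing_cells) > 0) {
    abort(sprintf("missing condition cells: %s",
                  paste(sprintf("p%s/c%s", missing_cells$participant,
                                missing_cells$condition_id), collapse = ", ")))
  }
  df <- dplyr::left_join(df, condition_factors(1:4), by = "condition_id")

  # participant x condition cell means (electrodes averaged)
  cells <- df |>
    dplyr::group_by(participant, condition_id, ur_relation, deviant_sandhi) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  wide <- tidyr::pivot_wider(cells[, c("participant", "condition_id", "value")],
                             names_from = "condition_id", names_prefix = "c",
                             values_from = "value")

  est <- c(
    ur_relation = mean((wide$c3 + wide$c4) / 2 - (wide$c1 + wide$c2) / 2),
    deviant_sandhi = mean((wide$c2 + wide$c4) / 2 - (wide$c1 + wide$c3) / 2),
    interaction = mean((wide$c4 - wide$c3) - (wide$c2 - wide$c1))
  )

  if (method == "cell_means") {
    scores <- list(
      ur_relation = (wide$c3 + wide$c4) / 2 - (wide$c1 + wide$c2) / 2,
      deviant_sandhi = (wide$c2 + wide$c4) / 2 - (wide$c1 + wide$c3) / 2,
      interaction = (wide$c4 - wide$c3) - (wide$c2 - wide$c1)
    )
    effects <- purrr::imap(scores, function(s, nm) {
      if (sd(s) < 1e-12) {
        tibble(term = nm, estimate = mean(s), statistic = NA_real_,
               df = length(s) - 1, p.value = if (abs(mean(s)) < 1e-12) 1 else 0)
      } else {
        tt <- stats::t.test(s)
        tibble(term = nm, estimate = mean(s),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p.value = tt$p.value)
      }
    }) |> dplyr::bind_rows()
    pairs <- utils::combn(1:4, 2, simplify = FALSE)
    posthoc <- purrr::map(pairs, function(pr) {
      d <- wide[[paste0("c", pr[2])]] - wide[[paste0("c", pr[1])]]
      if (sd(d) < 1e-12) {
        tibble(contrast = sprintf("c%d - c%d", pr[2], pr[1]),
               estimate = mean(d), statistic = NA_real_,
               p.value = if (abs(mean(d)) < 1e-12) 1 else 0)
      } else {
        tt <- stats::t.test(d)
        tibble(contrast = sprintf("c%d - c%d", pr[2], pr[1]),
               estimate = mean(d), statistic = unname(tt$statistic),
               p.value = tt$p.value)
      }
    }) |> dplyr::bind_rows()
    posthoc$p.value <- pmin(1, posthoc$p.value * nrow(posthoc))
    model <- NULL
    converged <- TRUE
    singular <- FALSE
  } else {
    ctr <- list(ur_relation = stats::contr.sum,
                deviant_sandhi = stats::contr.sum)
    fit_formula <- value ~ ur_relation * deviant_sandhi +
      (1 + ur_relation + deviant_sandhi | participant)
    model <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(fit_formula, data = df, contrasts = ctr, REML = TRUE))),
      error = function(e) NULL)
    singular <- !is.null(model) && lme4::isSingular(model, tol = 1e-4)
    if (is.null(model) || singular) {
      model <- suppressWarnings(suppressMessages(
        lmerTest::lmer(value ~ ur_relation * deviant_sandhi +
                         (1 | participant),
                       data = df, contrasts = ctr, REML = TRUE)))
    }
    an <- stats::anova(model, type = 3)
    term_map <- c("ur_relation" = "ur_relation",
                  "deviant_sandhi" = "deviant_sandhi",
                  "ur_relation:deviant_sandhi" = "interaction")
    effects <- tibble(
      term = unname(term_map[rownames(an)]),
      estimate = unname(est[term_map[rownames(an)]]),
      statistic = an$`F value`,
      df = an$DenDF,
      p.value = an$`Pr(>F)`
    )
    emm <- emmeans::emmeans(model, ~ ur_relation * deviant_sandhi)
    ph <- summary(emmeans::contrast(emm, method = "pairwise",
                                    adjust = "bonferroni"))
    posthoc <- tibble(contrast = as.character(ph$contrast),
                      estimate = ph$estimate, statistic = ph$t.ratio,
                      p.value = ph$p.value)
    converged <- TRUE
  }
  structure(list(effects = effects, posthoc = posthoc, method = method,
                 model = model, value = value,
                 n_participants = nrow(wide),
                 converged = converged, singular = singular),
            class = "ow_inference")
}

#' @export
print.ow_inference <- function(x, ...) {
  cat(sprintf("<ow_inference> %s on %s (%d participants)\n", x$method,
              x$value, x$n_participants))
  print(x$effects)
  invisible(x)
}

#' @export
#' @method tidy ow_inference
tidy.ow_inference <- function(x, ...) x$effects

#' @export
#' @method glance ow_inference
glance.ow_inference <- function(x, ...) {
  tibble(method = x$method, value = x$value,
         n_participants = x$n_participants,
         converged = x$converged, singular = x$singular)
}

#' Split-half comparison of a point measure
#'
#' Compares measures computed from the first and the second half of each
#' sub-block's trials: reports the second-minus-first difference with a
#' paired t-test across participants, overall and per condition.
#'
#' @param measures Tibble with `participant`, `index` (or `condition_id`),
#'   `electrode`, `half` (`"first"`/`"second"`), and the value column.
#' @param value Name of the value column.
#' @return Tibble with rows for `"all"` and each condition: `condition`,
#'   `estimate` (second - first), `statistic`, `df`, `p.value`, `n`.
#' @export
split_half <- function(measures, value) {
  df <- as_tibble(measures)
  if (!"condition_id" %in% names(df)) df$condition_id <- df$index
  df$value <- df[[value]]
  df <- df[!is.na(df$value), ]
  per <- df |>
    dplyr::group_by(participant, condition_id, half) |>
    dplyr::summarise(value = mean(value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "half", values_from = "value")
  if (!all(c("first", "second") %in% names(per))) {
    abort("need both `first` and `second` half measures")
  }
  per$diff <- per$second - per$first
  one <- function(d, label) {
    d <- d[!is.na(d)]
    if (length(d) < 2 || sd(d) < 1e-12) {
      return(tibble(condition = label, estimate = mean(d),
                    statistic = NA_real_, df = length(d) - 1,
                    p.value = NA_real_, n = length(d)))
    }
    tt <- stats::t.test(d)
    tibble(condition = label, estimate = mean(d),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value, n = length(d))
  }
  overall <- per |>
    dplyr::group_by(participant) |>
    dplyr::summarise(diff = mean(diff), .groups = "drop")
  dplyr::bind_rows(
    one(overall$diff, "all"),
    purrr::map(sort(unique(per$condition_id)), function(cid) {
      one(per$diff[per$condition_id == cid], as.character(cid))
    }) |> dplyr::bind_rows()
  )
}
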