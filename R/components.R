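#' Default ERP component set of the forward model
#'
#' The simulator builds every trial as a sum of Gaussian-in-time,
#' Gaussian-on-scalp components. The default set realizes a three-component
#' summation account of the S1-S2 transitional positivity plus the remaining
#' deviant-locked responses of the design:
#'
#' * **base_positivity** - on all deviants, fronto-central, the latest peak of
#'   the three transitional components (372 ms), peak amplitude `A = 2` uV;
#' * **ur_mismatch_positivity** - deviants of the UR-mismatch conditions (3,
#'   4), earlier peak (345 ms), amplitude approximately `A`;
#' * **mapping_positivity** - every underlyingly-T3+T3 (sandhi) stimulus,
#'   standard or deviant, the earliest peak (315 ms) and the smallest
#'   amplitude (1 uV). Because standards are habituated, a residual scaled by
#'   `1 - habituation_factor` survives the identity subtraction;
#' * **segmental_mmn** - condition-1 deviants, S1, negative, peak 269 ms;
#' * **early_negativity** - condition-2 deviants, negative, peak 120 ms
#'   (onset near 53 ms);
#' * **s2_negativity** - all deviants, peak inside 550-700 ms, earlier for
#'   sandhi-deviant conditions (625 vs 645 ms) and shallower for UR-mismatch
#'   conditions (-1.1 vs -2.2 uV peak).
#'
#' Peak-latency orderings, the 269/120 ms peaks and the amplitude relations
#' are the anchored facts; the absolute amplitudes and spatial extents are a
#' plausible preset calibrated once so that noise-free all-electrode window
#' means land near the magnitudes such studies report, not canonical values.
#'
#' @return Tibble with one row per component rule: `name`, `amplitude` (uV,
#'   signed peak), `peak_latency_ms`, `temporal_sd_ms`, `spatial_center`,
#'   `spatial_sd_cm`, `conditions` (list-column of condition ids, `NULL` =
#'   all), `role` (`"deviant"`, `"standard"`, or `"any"`), `sandhi`
#'   (`"sandhi"`, `"nonsandhi"`, or `"any"` - matched against the stimulus
#'   token's underlying tones).
#' @examples
#' default_components()
#' @export
default_components <- function() {
  comp <- function(name, amplitude, peak, tsd, conditions = NULL,
                   role = "deviant", sandhi = "any",
                   center = "FCz", ssd = 4) {
    tibble(name = name, amplitude = amplitude, peak_latency_ms = peak,
           temporal_sd_ms = tsd, spatial_center = center, spatial_sd_cm = ssd,
           conditions = list(conditions), role = role, sandhi = sandhi)
  }
  dplyr::bind_rows(
    comp("mapping_positivity", 1.0, 315, 35, role = "any", sandhi = "sandhi",
         ssd = 6),
    comp("ur_mismatch_positivity", 2.0, 345, 40, conditions = c(3L, 4L),
         ssd = 6),
    comp("base_positivity", 2.0, 372, 45, ssd = 6),
    comp("segmental_mmn", -1.5, 269, 35, conditions = 1L, ssd = 5),
    comp("early_negativity", -1.0, 120, 30, conditions = 2L, ssd = 5),
    comp("s2_negativity", -2.2, 645, 40, conditions = 1L, ssd = 8),
    comp("s2_negativity", -2.2, 625, 40, conditions = 2L, ssd = 8),
    comp("s2_negativity", -1.1, 645, 40, conditions = 3L, ssd = 8),
    comp("s2_negativity", -1.1, 625, 40, conditions = 4L, ssd = 8)
  )
}

# Does a component row apply to a trial of the given condition/role/sandhi?
component_applies <- function(comp_row, condition_id, role, sandhi) {
  conds <- comp_row$conditions[[1]]
  ok_cond <- is.null(conds) || condition_id %in% conds
  ok_role <- comp_row$role == "any" || comp_row$role == role
  ok_sandhi <- comp_row$sandhi == "any" ||
    comp_row$sandhi == (if (sandhi) "sandhi" else "nonsandhi")
  ok_cond && ok_role && ok_sandhi
}
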