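#' Condition ERP and difference-wave containers
#'
#' `ow_erp` holds a channel x time average with its retained-trial count and
#' identifying metadata; `ow_wave` holds a difference wave tagged with its
#' index (1-9), derivation formula, and whether it is an *identity*
#' difference wave (built from physically identical stimuli).
#'
#' @name wave_objects
NULL

new_erp <- function(wave, times, channels, n_trials, meta = list()) {
  dimnames(wave) <- list(channels, NULL)
  structure(list(wave = wave, times = times, channels = channels,
                 n_trials = n_trials, meta = meta),
            class = "ow_erp")
}

new_wave <- function(wave, times, channels, index = NA_integer_,
                     formula = "", identity = NA, participant = NA_integer_) {
  dimnames(wave) <- list(channels, NULL)
  structure(list(wave = wave, times = times, channels = channels,
                 index = index, formula = formula, identity = identity,
                 participant = participant),
            class = "ow_wave")
}

#' @export
print.ow_erp <- function(x, ...) {
  cat(sprintf("<ow_erp> %d channels x %d samples, %d trials%s\n",
              nrow(x$wave), ncol(x$wave), x$n_trials,
              if (!is.null(x$meta$role)) paste0(" (", x$meta$role, ")") else ""))
  invisible(x)
}

#' @export
print.ow_wave <- function(x, ...) {
  cat(sprintf("<ow_wave> #%s %s [%s]\n", x$index, x$formula,
              if (isTRUE(x$identity)) "identity" else "derived"))
  invisible(x)
}

#' Average retained trials into a condition ERP
#'
#' Computes the arithmetic mean over the retained trials selected by `role`
#' (and optionally any further logical index), recording the number of trials
#' used. Only scalp channels (the montage, when present) enter the average.
#'
#' @param epochs An `ow_epochs`.
#' @param role `"standard"` or `"deviant"` (or `NULL` for all retained
#'   trials).
#' @param which Optional additional logical vector over trials.
#' @return An `ow_erp`.
#' @export
average_condition <- function(epochs, role = NULL, which = NULL) {
  keep <- epochs$trial_meta$retained
  if (!is.null(role)) keep <- keep & epochs$trial_meta$role == role
  if (!is.null(which)) keep <- keep & which
  if (!any(keep)) {
    abort(sprintf("no retained trials for role %s",
                  role %||% "<all>"))
  }
  scalp <- if (!is.null(epochs$montage)) epochs$montage$label else epochs$channels
  si <- match(scalp, epochs$channels)
  sub <- epochs$data[keep, si, , drop = FALSE]
  wave <- colMeans(sub) # over trials -> channel x time
  tm <- epochs$trial_meta
  pick <- function(col) if (col %in% names(tm)) unique(tm[[col]][keep])
  meta <- list(role = role, lexeme = pick("lexeme"),
               participant = pick("participant"), sub_block = pick("sub_block"))
  new_erp(wave, epochs$times, scalp, sum(keep), meta)
}

#' Pool condition ERPs weighted by trial count
#'
#' Combines averages over different stimulus sets into one ERP, weighting
#' each input by its number of retained trials (so the result equals the
#' average over all underlying trials).
#'
#' @param erps List of `ow_erp` objects on a common grid.
#' @return An `ow_erp` with `n_trials` the total count.
#' @export
pool_erps <- function(erps) {
  stopifnot(length(erps) >= 1)
  w <- vapply(erps, function(e) e$n_trials, numeric(1))
  wave <- Reduce(`+`, Map(function(e, wi) e$wave * wi, erps, w)) / sum(w)
  new_erp(wave, erps[[1]]$times, erps[[1]]$channels, sum(w),
          erps[[1]]$meta)
}

#' Identity difference wave (deviant minus standard, same stimuli)
#'
#' Subtracts the response to a stimulus set presented as standard from the
#' response to the *same* stimulus set presented as deviant (in the
#' direction-swapped sub-block), the construction that controls low-level
#' auditory responses. The token sets must match; mismatched sets are an
#' error so a non-identity subtraction cannot masquerade as an identity one.
#'
#' @param deviant_erp,standard_erp `ow_erp` objects for the same lexeme.
#' @param index Optional difference-wave index (1-4).
#' @return An `ow_wave` with `identity = TRUE`.
#' @export
identity_difference <- function(deviant_erp, standard_erp, index = NA_integer_) {
  lex_d <- deviant_erp$meta$lexeme
  lex_s <- standard_erp$meta$lexeme
  if (!is.null(lex_d) && !is.null(lex_s) &&
      !setequal(lex_d, lex_s)) {
    abort(sprintf("token sets differ (deviant: %s; standard: %s): not an identity subtraction",
                  paste(lex_d, collapse = ","), paste(lex_s, collapse = ",")))
  }
  if (!identical(dim(deviant_erp$wave), dim(standard_erp$wave))) {
    abort("deviant and standard ERPs are not on a common grid")
  }
  new_wave(deviant_erp$wave - standard_erp$wave,
           deviant_erp$times, deviant_erp$channels,
           index = index,
           formula = sprintf("%s Deviant - %s Standard",
                             deviant_erp$meta$sub_block %||% "?",
                             standard_erp$meta$sub_block %||% "?"),
           identity = TRUE,
           participant = deviant_erp$meta$participant %||% NA_integer_)
}

#' Collapse difference waves within a design cell
#'
#' Unweighted mean of difference waves computed from the two presentation
#' directions of the same condition (the directions carry equal design
#' weight).
#'
#' @param waves List of `ow_wave` objects on a common grid.
#' @param index Index tag for the collapsed wave.
#' @return An `ow_wave`; `identity` is `TRUE` only if all inputs are
#'   identity waves.
#' @export
collapse_waves <- function(waves, index = NA_integer_) {
  stopifnot(length(waves) >= 1)
  wave <- Reduce(`+`, lapply(waves, `[[`, "wave")) / length(waves)
  new_wave(wave, waves[[1]]$times, waves[[1]]$channels, index = index,
           formula = paste(vapply(waves, `[[`, "", "formula"),
                           collapse = " ; "),
           identity = all(vapply(waves, `[[`, NA, "identity")),
           participant = waves[[1]]$participant)
}

# wave arithmetic helpers (derived waves are not identity waves)
wave_sub <- function(a, b, index, formula) {
  new_wave(a$wave - b$wave, a$times, a$channels, index = index,
           formula = formula, identity = FALSE, participant = a$participant)
}

#' Derive the higher-order difference waves #5-#9
#'
#' From the four per-condition identity difference waves, derives the effect
#' waves: `#5 = #3 - #1` and `#6 = #4 - #2` (UR-relation effect within each
#' deviant type), `#7 = #2 - #1` and `#8 = #4 - #3` (deviant-sandhi-status
#' effect), and the interaction wave `#9 = #8 - #7`, which algebraically also
#' equals `#6 - #5` and `(#4 + #1) - (#3 + #2)`.
#'
#' @param waves A named list with elements `"1"` to `"4"` (or a list of
#'   `ow_wave` whose `index` fields cover 1-4) on a common grid.
#' @return Named list of `ow_wave` objects `"5"`..`"9"` (all with
#'   `identity = FALSE`, being differences of waves built from different
#'   stimulus pairs... except #5/#6 which inherit the identity construction
#'   of their inputs and keep `identity = TRUE`).
#' @export
derive_waves <- function(waves) {
  idx <- vapply(waves, `[[`, NA_integer_, "index")
  if (!all(1:4 %in% idx)) abort("need identity waves #1-#4")
  w <- setNames(waves[match(1:4, idx)], as.character(1:4))
  grids <- vapply(w, function(x) paste(dim(x$wave), collapse = "x"), "")
  if (length(unique(grids)) != 1) abort("waves #1-#4 are not on a common grid")
  out <- list(
    "5" = wave_sub(w[["3"]], w[["1"]], 5L, "#3 - #1"),
    "6" = wave_sub(w[["4"]], w[["2"]], 6L, "#4 - #2"),
    "7" = wave_sub(w[["2"]], w[["1"]], 7L, "#2 - #1"),
    "8" = wave_sub(w[["4"]], w[["3"]], 8L, "#4 - #3")
  )
  out[["5"]]$identity <- TRUE
  out[["6"]]$identity <- TRUE
  out[["9"]] <- wave_sub(out[["8"]], out[["7"]], 9L, "#8 - #7")
  out
}

#' Build the per-participant identity difference waves #1-#4
#'
#' Pairs every sub-block's deviant average with the standard average of the
#' direction-swapped sub-block of the same block (same stimuli), then
#' collapses the two resulting identity waves per condition.
#'
#' @param erps Tibble with columns `participant`, `block`, `direction`,
#'   `condition_id`, `role`, `wave` (list of `ow_erp`), as produced by
#'   [simulate_study()].
#' @param participant Participant id to extract.
#' @return Named list of `ow_wave` objects `"1"`..`"4"`.
#' @export
identity_waves <- function(erps, participant) {
  e <- erps[erps$participant == participant, ]
  get_erp <- function(block, direction, role) {
    row <- e[e$block == block & e$direction == direction & e$role == role, ]
    if (nrow(row) != 1) {
      abort(sprintf("missing ERP cell: participant %s, %s-%s %s",
                    participant, direction, block, role))
    }
    row$wave[[1]]
  }
  per_cond <- list()
  for (block in unique(e$block)) {
    for (dir in c("Original", "Reversed")) {
      other <- if (dir == "Original") "Reversed" else "Original"
      dev <- get_erp(block, dir, "deviant")
      std <- get_erp(block, other, "standard")
      cond <- e$condition_id[e$block == block & e$direction == dir][1]
      key <- as.character(cond)
      per_cond[[key]] <- c(per_cond[[key]],
                           list(identity_difference(dev, std, index = cond)))
    }
  }
  out <- lapply(sort(names(per_cond)), function(k) {
    collapse_waves(per_cond[[k]], index = as.integer(k))
  })
  setNames(out, sort(names(per_cond)))
}

#' Export / import a difference wave as TSV + JSON header
#'
#' The wave is written as a channel x time TSV (channels as rows, first
#' column the label) next to a JSON sidecar `<path>.json` holding the index,
#' formula, identity flag, time axis and participant.
#'
#' @param wave An `ow_wave`.
#' @param path TSV path.
#' @return `read_wave_tsv()` returns the `ow_wave`.
#' @export
write_wave_tsv <- function(wave, path) {
  meta <- list(index = wave$index, formula = wave$formula,
               identity = wave$identity, participant = wave$participant,
               times_ms = wave$times)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  tab <- data.frame(channel = wave$channels, wave$wave, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_wave_tsv
#' @export
read_wave_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  new_wave(as.matrix(tab[, -1]), meta$times_ms, tab[[1]],
           index = meta$index %||% NA_integer_, formula = meta$formula %||% "",
           identity = meta$identity %||% NA,
           participant = meta$participant %||% NA_integer_)
}
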