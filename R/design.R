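#' Stimulus inventory of the tone-sandhi oddball design
#'
#' The four disyllabic Mandarin lexical items used by the design, each
#' realized in four F0-trajectory renditions (16 distinct tokens). Two items
#' are underlyingly T2+T3 (non-sandhi) and two underlyingly T3+T3 (sandhi:
#' surfacing as T2+T3 after third-tone sandhi). All share the second syllable
#' /ma3/; the first syllable lasts 390 ms and the second 430 ms.
#'
#' @param s1_duration_ms,s2_duration_ms Syllable durations in ms.
#' @return Tibble with one row per (lexeme, rendition): columns `lexeme`,
#'   `gloss`, `underlying_tones`, `sandhi` (logical: underlyingly T3+T3),
#'   `rendition`, `token`, `s1_duration_ms`, `s2_duration_ms`.
#' @export
stimulus_inventory <- function(s1_duration_ms = 390, s2_duration_ms = 430) {
  lex <- tibble(
    lexeme = c("xe2ma3", "xuang2ma3", "xau3ma3", "xai3ma3"),
    gloss = c("hippo", "Real Madrid", "good horse", "seahorse"),
    underlying_tones = c("T2+T3", "T2+T3", "T3+T3", "T3+T3"),
    sandhi = c(FALSE, FALSE, TRUE, TRUE)
  )
  out <- tidyr::crossing(lex, rendition = 1:4)
  out$token <- paste0(out$lexeme, "_r", out$rendition)
  out$s1_duration_ms <- s1_duration_ms
  out$s2_duration_ms <- s2_duration_ms
  out[order(match(out$lexeme, lex$lexeme), out$rendition), ]
}

#' Catalogue of the eight oddball sub-blocks
#'
#' The 2x2 design crosses *UR Relation* (whether standard and deviant conflict
#' in underlying tone) with *Deviant Sandhi Status* (whether the deviant is
#' underlyingly T2+T3 or T3+T3). Four blocks (A-D) each contribute an Original
#' and a Reversed sub-block in which standard and deviant lexemes swap roles,
#' so every condition (1-4) is realized twice, once per direction:
#'
#' | condition | UR relation | deviant |
#' |-----------|-------------|-----------------|
#' | 1 | match    | non-sandhi (T2+T3) |
#' | 2 | match    | sandhi (T3+T3)     |
#' | 3 | mismatch | non-sandhi (T2+T3) |
#' | 4 | mismatch | sandhi (T3+T3)     |
#'
#' @param n_trials Trials per sub-block (default 400).
#' @param deviant_fraction Proportion of deviants (default 0.125, i.e. 50
#'   deviants in 400 trials).
#' @return Tibble with one row per sub-block: `block`, `direction`,
#'   `sub_block`, `standard_lexeme`, `deviant_lexeme`, `condition_id`,
#'   `ur_relation`, `deviant_sandhi`, `n_trials`, `deviant_fraction`.
#' @examples
#' condition_catalog()
#' @export
condition_catalog <- function(n_trials = 400, deviant_fraction = 0.125) {
  # per-block Original (standard, deviant) pairs and condition ids;
  # Reversed swaps the lexemes and takes the block's other condition cell
  orig <- tibble(
    block = c("A", "B", "C", "D"),
    standard_lexeme = c("xe2ma3", "xe2ma3", "xai3ma3", "xai3ma3"),
    deviant_lexeme = c("xuang2ma3", "xau3ma3", "xuang2ma3", "xau3ma3"),
    condition_id = c(1L, 4L, 3L, 2L)
  )
  rev <- tibble(
    block = orig$block,
    standard_lexeme = orig$deviant_lexeme,
    deviant_lexeme = orig$standard_lexeme,
    condition_id = c(1L, 3L, 4L, 2L)
  )
  out <- dplyr::bind_rows(
    dplyr::mutate(orig, direction = "Original"),
    dplyr::mutate(rev, direction = "Reversed")
  )
  out$sub_block <- paste0(out$direction, "-", out$block)
  out$ur_relation <- ifelse(out$condition_id %in% c(1L, 2L), "match", "mismatch")
  out$deviant_sandhi <- ifelse(out$condition_id %in% c(2L, 4L), "sandhi", "nonsandhi")
  out$n_trials <- as.integer(n_trials)
  out$deviant_fraction <- deviant_fraction
  if (abs(n_trials * deviant_fraction - round(n_trials * deviant_fraction)) > 1e-9) {
    abort("n_trials * deviant_fraction must be an integer")
  }
  out <- out[order(out$block, out$direction), ]
  out[, c("block", "direction", "sub_block", "standard_lexeme", "deviant_lexeme",
          "condition_id", "ur_relation", "deviant_sandhi",
          "n_trials", "deviant_fraction")]
}

# Balanced multiset of standards-gaps in {5..9} summing to n_standards
# (one gap precedes every deviant, including the first). When n_deviants is a
# multiple of 5 and the mean gap is exactly 7 (deviant_fraction = 1/8) this is
# ten-of-each-per-50; otherwise the flattest feasible multiset is adjusted to
# hit the exact total.
gap_multiset <- function(n_deviants, n_standards) {
  if (n_standards < 5 * n_deviants || n_standards > 9 * n_deviants) {
    abort(sprintf(
      "infeasible gap constraint: %d standards cannot be split into %d gaps of 5..9",
      n_standards, n_deviants))
  }
  gaps <- rep(5:9, length.out = n_deviants)
  gaps <- sort(gaps)
  slack <- n_standards - sum(gaps)
  i <- if (slack >= 0) 1L else n_deviants
  while (slack != 0) {
    step <- sign(slack)
    room <- if (step > 0) 9 - gaps[i] else gaps[i] - 5
    adj <- step * min(abs(slack), room)
    gaps[i] <- gaps[i] + adj
    slack <- slack - adj
    i <- i + if (step > 0) 1L else -1L
  }
  gaps
}

#' Generate a constrained pseudo-random oddball sequence
#'
#' Produces the ordered trial list for one sub-block under the design's
#' sequencing constraints:
#'
#' * exactly `n_trials * deviant_fraction` deviants;
#' * the number of standards before each deviant (including the first) lies in
#'   5..9, drawn by shuffling a balanced multiset (for the default 400-trial
#'   sub-block: ten gaps of each length, so each length occurs with exactly
#'   20% frequency);
#' * standard tokens are drawn uniformly from the standard lexeme's four
#'   renditions, never more than three identical tokens in succession;
#' * deviant tokens are drawn uniformly from the deviant lexeme's renditions,
#'   the same token occupying at most two consecutive deviant slots;
#' * each inter-stimulus interval is drawn uniformly from
#'   700, 750, ..., 900 ms.
#'
#' The output is bit-identical for a given seed.
#'
#' @param spec One row of [condition_catalog()] (or a list with the same
#'   fields).
#' @param seed Integer seed.
#' @param n_renditions Number of renditions per lexeme (default 4).
#' @return An `ow_sequence`: tibble with columns `position`, `role`
#'   (`"standard"`/`"deviant"`), `lexeme`, `rendition`, `token`, `isi_ms`,
#'   carrying the spec row and seed as attributes.
#' @examples
#' seqA <- generate_sequence(condition_catalog()[1, ], seed = 1)
#' table(seqA$role)
#' @export
generate_sequence <- function(spec, seed, n_renditions = 4) {
  spec <- as.list(spec)
  n_trials <- as.integer(spec$n_trials)
  n_dev <- round(n_trials * spec$deviant_fraction)
  if (abs(n_trials * spec$deviant_fraction - n_dev) > 1e-9) {
    abort("n_trials * deviant_fraction must be an integer")
  }
  n_std <- n_trials - n_dev
  if (n_renditions == 1 && n_dev > 0) {
    # any gap >= 4 forces four identical standards in a row
    abort("infeasible constraint set: run-length cap of 3 cannot be met with a single standard rendition")
  }
  with_seed(seed, {
    gaps <- sample(gap_multiset(n_dev, n_std))
    role <- unlist(lapply(gaps, function(g) c(rep("standard", g), "deviant")),
                   use.names = FALSE)
    rend <- integer(n_trials)
    run_tok <- 0L; run_len <- 0L       # current standard-token run
    dev_tok <- 0L; dev_run <- 0L       # consecutive deviant-slot token run
    for (i in seq_len(n_trials)) {
      if (role[i] == "standard") {
        repeat {
          r <- sample.int(n_renditions, 1)
          if (r != run_tok || run_len < 3L) break
        }
        run_len <- if (r == run_tok) run_len + 1L else 1L
        run_tok <- r
      } else {
        repeat {
          r <- sample.int(n_renditions, 1)
          if (r != dev_tok || dev_run < 2L) break
        }
        dev_run <- if (r == dev_tok) dev_run + 1L else 1L
        dev_tok <- r
        run_tok <- 0L; run_len <- 0L   # a deviant breaks a standard run
      }
      rend[i] <- r
    }
    isi <- sample(seq(700, 900, by = 50), n_trials, replace = TRUE)
    lex <- ifelse(role == "deviant", spec$deviant_lexeme, spec$standard_lexeme)
    out <- tibble(
      position = seq_len(n_trials),
      role = role,
      lexeme = lex,
      rendition = rend,
      token = paste0(lex, "_r", rend),
      isi_ms = isi
    )
    structure(out, spec = spec, seed = seed,
              class = c("ow_sequence", class(tibble())))
  })
}

#' Validate an oddball sequence against the design constraints
#'
#' Checks every sequencing invariant enforced by [generate_sequence()] and
#' reports each violation with the rule name and the trial position at which
#' it was detected.
#'
#' @param seq An `ow_sequence` (or a tibble with columns `position`, `role`,
#'   `token`, `isi_ms`).
#' @param n_trials,deviant_fraction Expected design sizes; taken from the
#'   sequence's spec attribute when absent.
#' @return Tibble of violations (`rule`, `position`, `detail`); zero rows when
#'   the sequence is valid.
#' @export
validate_sequence <- function(seq, n_trials = NULL, deviant_fraction = NULL) {
  spec <- attr(seq, "spec")
  n_trials <- n_trials %||% spec$n_trials %||% nrow(seq)
  deviant_fraction <- deviant_fraction %||% spec$deviant_fraction %||%
    mean(seq$role == "deviant")
  bad <- list()
  note <- function(rule, position, detail) {
    bad[[length(bad) + 1]] <<- tibble(rule = rule, position = as.integer(position),
                                      detail = detail)
  }
  if (nrow(seq) != n_trials) {
    note("trial-count", nrow(seq), sprintf("expected %d trials, found %d",
                                           n_trials, nrow(seq)))
  }
  n_dev_exp <- round(n_trials * deviant_fraction)
  dev_idx <- which(seq$role == "deviant")
  if (length(dev_idx) != n_dev_exp) {
    note("deviant-count", length(dev_idx),
         sprintf("expected %d deviants, found %d", n_dev_exp, length(dev_idx)))
  }
  # gaps of standards before each deviant, including the first
  bounds <- c(0L, dev_idx)
  gaps <- diff(bounds) - 1L
  for (k in which(gaps < 5 | gaps > 9)) {
    note("gap-range", dev_idx[k],
         sprintf("gap of %d standards before deviant %d", gaps[k], k))
  }
  # run-length cap on standard tokens (a deviant breaks the run)
  run <- 0L; last <- ""
  for (i in seq_len(nrow(seq))) {
    if (seq$role[i] == "standard") {
      run <- if (seq$token[i] == last) run + 1L else 1L
      last <- seq$token[i]
      if (run > 3L) note("run-length", i,
                         sprintf("standard token %s repeated %d times in succession",
                                 last, run))
    } else {
      run <- 0L; last <- ""
    }
  }
  # same deviant token on at most 2 consecutive deviant slots
  if (length(dev_idx) > 0) {
    dt <- seq$token[dev_idx]
    r <- rle(dt)
    ends <- cumsum(r$lengths)
    for (k in which(r$lengths > 2)) {
      note("deviant-repeat", dev_idx[ends[k]],
           sprintf("deviant token %s on %d consecutive deviant slots",
                   r$values[k], r$lengths[k]))
    }
  }
  for (i in which(!seq$isi_ms %in% seq(700, 900, by = 50))) {
    note("isi-value", i, sprintf("ISI %s ms not in 700..900 by 50", seq$isi_ms[i]))
  }
  if (length(bad) == 0) {
    tibble(rule = character(), position = integer(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' Export a sequence as BIDS-style events.tsv
#'
#' Writes one row per trial with `onset` (s, accumulated from stimulus
#' duration plus ISI), `duration` (s), `trial_type`, `stim_file`.
#'
#' @param seq An `ow_sequence`.
#' @param path Output path.
#' @param stim_duration_ms Stimulus duration used to accumulate onsets.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(seq, path, stim_duration_ms = 820) {
  onset_ms <- cumsum(c(0, head(stim_duration_ms + seq$isi_ms, -1)))
  ev <- tibble(
    onset = onset_ms / 1000,
    duration = stim_duration_ms / 1000,
    trial_type = seq$role,
    stim_file = paste0(seq$token, ".wav")
  )
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
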