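#' Configuration of the cluster-based permutation test
#'
#' @param window Analysis window in ms (`c(start, end)`).
#' @param tail `"two_sided"` (default), `"one_sided_negative"`, or
#'   `"one_sided_positive"`. One-sided tests form clusters only from the
#'   hypothesized sign.
#' @param n_permutations Number of random sign-flip permutations (default
#'   5000).
#' @param alpha Significance level for reporting (default 0.05).
#' @param cluster_forming_alpha Point-wise alpha defining the
#'   cluster-forming t threshold, `qt()` at `df = n - 1` (two-tailed for
#'   two-sided tests; default 0.05).
#' @param adjacency An `ow_adjacency` defining spatial neighbours (`NULL`
#'   for purely temporal clustering, e.g. single-channel data).
#' @param seed Seed for the permutation stream.
#' @return A list of class `ow_perm_config`.
#' @export
perm_config <- function(window, tail = c("two_sided", "one_sided_negative",
                                         "one_sided_positive"),
                        n_permutations = 5000, alpha = 0.05,
                        cluster_forming_alpha = 0.05, adjacency = NULL,
                        seed = 1L) {
  tail <- match.arg(tail)
  stopifnot_scalar_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  stopifnot_scalar_number(n_permutations, "n_permutations", 1)
  stopifnot(length(window) == 2, window[1] < window[2])
  structure(list(window = window, tail = tail,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 cluster_forming_alpha = cluster_forming_alpha,
                 adjacency = adjacency, seed = as.integer(seed)),
            class = "ow_perm_config")
}

# neighbour index list over the flattened (channel fastest, then time) grid:
# spatial neighbours at the same sample + the same channel at adjacent samples
grid_neighbours <- function(n_ch, n_t, adj_idx) {
  nbr <- vector("list", n_ch * n_t)
  for (t in seq_len(n_t)) {
    base <- (t - 1L) * n_ch
    for (c in seq_len(n_ch)) {
      v <- base + adj_idx[[c]]
      if (t > 1L) v <- c(v, base - n_ch + c)
      if (t < n_t) v <- c(v, base + n_ch + c)
      nbr[[base + c]] <- v
    }
  }
  nbr
}

# connected components of `mask` (logical over the flattened grid) under the
# neighbour lists; returns a list of member-index vectors
connected_components <- function(mask, nbr) {
  comp <- list()
  seen <- !mask
  for (s in which(mask)) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      members <- c(members, p)
      for (q in nbr[[p]]) {
        if (!seen[q]) {
          seen[q] <- TRUE
          stack <- c(stack, q)
        }
      }
    }
    comp[[length(comp) + 1]] <- members
  }
  comp
}

# cluster masses of a t map for one sign; returns list(members, mass)
sign_clusters <- function(tv, thr, sign, nbr) {
  mask <- if (sign > 0) tv > thr else tv < -thr
  if (!any(mask)) return(list(members = list(), mass = numeric(0)))
  comp <- connected_components(mask, nbr)
  list(members = comp,
       mass = vapply(comp, function(m) sum(tv[m]), numeric(1)))
}

# largest |cluster mass| of a t map under the configured tail
max_cluster_mass <- function(tv, thr, tail, nbr) {
  m <- 0
  if (tail != "one_sided_negative") {
    cm <- sign_clusters(tv, thr, +1, nbr)$mass
    if (length(cm)) m <- max(m, max(cm))
  }
  if (tail != "one_sided_positive") {
    cm <- sign_clusters(tv, thr, -1, nbr)$mass
    if (length(cm)) m <- max(m, max(abs(cm)))
  }
  m
}

# one-sample t over participants for every column of X (n x p), with the
# sign vector s applied to whole participants; second moments are invariant
# under sign flips, so only the means change
flip_t <- function(X, S, ss, n) {
  mu <- crossprod(X, S) / n                # p x nperm
  v <- (ss - n * mu^2) / (n - 1)
  mu / sqrt(pmax(v, 0) / n + 1e-300)
}

#' Spatiotemporal cluster-based sign-flip permutation test
#'
#' One-sample test of a set of per-participant difference waves against zero
#' over a channel x time window. Point-wise one-sample t statistics are
#' thresholded at the critical t of `cluster_forming_alpha` (df = n - 1);
#' supra-threshold points are grouped into clusters (spatial neighbours at
#' the same sample, same channel at adjacent samples; same-sign members
#' only); each cluster's mass is the sum of its member t values. The null
#' distribution is built by flipping the sign of whole participants' waves
#' and recording the maximum cluster |mass| per permutation; p-values use the
#' add-one estimator `(1 + #exceedances) / (1 + n_permutations)`.
#'
#' @param waves List of `ow_wave` (or plain channel x time matrices) on a
#'   common grid, one per participant; or a tibble with a `wave` list-column.
#' @param cfg An `ow_perm_config`.
#' @param times,channels Required when `waves` are bare matrices.
#' @return An `ow_clusters` object: `$clusters` (tibble with `cluster`,
#'   `sign`, `mass`, `p_value`, `n_points`, `t_start`, `t_end`,
#'   `peak_channel`, `peak_time`), `$members`, `$null_max_mass`, `$t_map`,
#'   plus the window/tail/seed used. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
cluster_test <- function(waves, cfg, times = NULL, channels = NULL) {
  if (is.data.frame(waves)) waves <- waves$wave
  first <- waves[[1]]
  if (inherits(first, "ow_wave")) {
    times <- first$times
    channels <- first$channels
    mats <- lapply(waves, `[[`, "wave")
  } else {
    mats <- waves
    if (is.null(times)) abort("`times` required for bare matrices")
    if (is.null(channels)) channels <- rownames(first) %||%
        paste0("ch", seq_len(nrow(first)))
  }
  n <- length(mats)
  if (n < 2) abort("need at least 2 participants")
  sel <- which(times >= cfg$window[1] & times <= cfg$window[2])
  if (length(sel) == 0) abort("analysis window is empty after cropping")
  tt <- times[sel]
  n_ch <- length(channels)
  n_t <- length(sel)
  p <- n_ch * n_t
  X <- t(vapply(mats, function(M) as.numeric(M[, sel, drop = FALSE]),
                numeric(p))) # n x p, channel fastest
  adj_idx <- if (!is.null(cfg$adjacency)) {
    lapply(channels, function(ch) {
      match(intersect(cfg$adjacency[[ch]], channels), channels)
    })
  } else {
    rep(list(integer(0)), n_ch)
  }
  nbr <- grid_neighbours(n_ch, n_t, adj_idx)

  df <- n - 1
  thr <- if (cfg$tail == "two_sided") {
    qt(1 - cfg$cluster_forming_alpha / 2, df)
  } else {
    qt(1 - cfg$cluster_forming_alpha, df)
  }
  mu <- colMeans(X)
  s2 <- apply(X, 2, var)
  t_obs <- mu / sqrt(s2 / n + 1e-300)
  t_obs[s2 == 0 & mu == 0] <- 0

  obs <- list(members = list(), mass = numeric(0), sign = integer(0))
  if (cfg$tail != "one_sided_negative") {
    cl <- sign_clusters(t_obs, thr, +1, nbr)
    obs$members <- c(obs$members, cl$members)
    obs$mass <- c(obs$mass, cl$mass)
    obs$sign <- c(obs$sign, rep(1L, length(cl$mass)))
  }
  if (cfg$tail != "one_sided_positive") {
    cl <- sign_clusters(t_obs, thr, -1, nbr)
    obs$members <- c(obs$members, cl$members)
    obs$mass <- c(obs$mass, cl$mass)
    obs$sign <- c(obs$sign, rep(-1L, length(cl$mass)))
  }

  # canonicalize the participant order entering the null stream so results
  # are invariant to the order in which waves are supplied
  can <- do.call(order, as.data.frame(X))
  null_max <- with_seed(cfg$seed, {
    S <- matrix(sample(c(-1, 1), n * cfg$n_permutations, replace = TRUE),
                n, cfg$n_permutations)
    ss <- colSums(X^2)
    tmat <- flip_t(X[can, , drop = FALSE], S, ss, n)
    apply(tmat, 2, max_cluster_mass, thr = thr, tail = cfg$tail, nbr = nbr)
  })

  pvals <- vapply(abs(obs$mass), function(m) {
    # count ties as exceedances (identity sign assignments reproduce the
    # observed mass exactly), robust to floating-point jitter
    (1 + sum(null_max >= m - 1e-9 * (1 + m))) / (1 + cfg$n_permutations)
  }, numeric(1))

  ord <- order(pvals, -abs(obs$mass))
  t_map <- matrix(t_obs, n_ch, n_t, dimnames = list(channels, NULL))
  clusters <- tibble(
    cluster = seq_along(ord),
    sign = obs$sign[ord],
    mass = obs$mass[ord],
    p_value = pvals[ord],
    n_points = lengths(obs$members)[ord],
    t_start = vapply(obs$members[ord], function(m) {
      tt[min((m - 1L) %/% n_ch + 1L)]
    }, numeric(1)),
    t_end = vapply(obs$members[ord], function(m) {
      tt[max((m - 1L) %/% n_ch + 1L)]
    }, numeric(1)),
    peak_channel = vapply(obs$members[ord], function(m) {
      channels[(m[which.max(abs(t_obs[m]))] - 1L) %% n_ch + 1L]
    }, character(1)),
    peak_time = vapply(obs$members[ord], function(m) {
      tt[(m[which.max(abs(t_obs[m]))] - 1L) %/% n_ch + 1L]
    }, numeric(1))
  )
  structure(list(
    clusters = clusters,
    members = lapply(obs$members[ord], function(m) {
      tibble(channel = channels[(m - 1L) %% n_ch + 1L],
             time = tt[(m - 1L) %/% n_ch + 1L])
    }),
    null_max_mass = null_max,
    t_map = t_map, times = tt, channels = channels,
    window = cfg$window, tail = cfg$tail, alpha = cfg$alpha,
    n_permutations = cfg$n_permutations, n_participants = n,
    threshold = thr, seed = cfg$seed
  ), class = "ow_clusters")
}

#' @export
print.ow_clusters <- function(x, ...) {
  cat(sprintf("<ow_clusters> window %g..%g ms, %s, %d participants, %d permutations\n",
              x$window[1], x$window[2], x$tail, x$n_participants,
              x$n_permutations))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}

#' Scan a set of analysis windows with independent cluster tests
#'
#' Runs [cluster_test()] per window. When `adjust_ms` is given and a
#' significant cluster touches a window bound, that window is re-tested once
#' with the window shifted by `adjust_ms` toward the touched bound (the
#' boundary-adjustment workflow for clusters cut off by a window edge); both
#' the original and the adjusted results are returned.
#'
#' @param waves As in [cluster_test()].
#' @param windows List of `c(start, end)` pairs in ms.
#' @param cfg An `ow_perm_config` (its `window` field is ignored).
#' @param adjust_ms Shift in ms for the boundary-adjustment re-test
#'   (`NULL` = off).
#' @return A tibble with one row per executed test: `window_start`,
#'   `window_end`, `adjusted`, `n_clusters`, `min_p`, `result` (list of
#'   `ow_clusters`).
#' @export
windowed_scan <- function(waves, windows, cfg, adjust_ms = NULL) {
  run_one <- function(win, adjusted) {
    cfg1 <- cfg
    cfg1$window <- win
    res <- cluster_test(waves, cfg1)
    tibble(window_start = win[1], window_end = win[2], adjusted = adjusted,
           n_clusters = nrow(res$clusters),
           min_p = if (nrow(res$clusters)) min(res$clusters$p_value) else NA_real_,
           result = list(res))
  }
  out <- purrr::map(windows, run_one, adjusted = FALSE)
  if (!is.null(adjust_ms)) {
    extra <- purrr::map(out, function(row) {
      res <- row$result[[1]]
      sig <- res$clusters[res$clusters$p_value < res$alpha, ]
      if (nrow(sig) == 0) return(NULL)
      dt <- diff(res$times[1:2]) # sample period in ms
      win <- c(row$window_start, row$window_end)
      if (any(abs(sig$t_end - max(res$times)) < dt / 2)) {
        run_one(win + adjust_ms, adjusted = TRUE)
      } else if (any(abs(sig$t_start - min(res$times)) < dt / 2)) {
        run_one(win - adjust_ms, adjusted = TRUE)
      }
    })
    out <- c(out, purrr::compact(extra))
  }
  dplyr::bind_rows(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy ow_clusters
tidy.ow_clusters <- function(x, ...) x$clusters

#' @export
#' @method glance ow_clusters
glance.ow_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_significant = sum(x$clusters$p_value < x$alpha),
         min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_,
         window_start = x$window[1], window_end = x$window[2],
         tail = x$tail, n_participants = x$n_participants,
         n_permutations = x$n_permutations, threshold_t = x$threshold)
}
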