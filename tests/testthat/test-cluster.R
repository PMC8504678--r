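mk_wave_set <- function(X, times, channel = "Cz") {
  # one single-channel ow_wave per participant from the rows of X
  lapply(seq_len(nrow(X)), function(i) {
    make_wave(matrix(X[i, ], nrow = 1), times = times, channels = channel)
  })
}

test_that("all-zero input yields no clusters and valid p-value bounds", {
  times <- seq(0, 396, by = 4)
  waves <- mk_wave_set(matrix(0, 8, length(times)), times)
  res <- cluster_test(waves, perm_config(c(0, 396), n_permutations = 100,
                                         seed = 1))
  expect_equal(nrow(res$clusters), 0)

  set.seed(3)
  waves2 <- mk_wave_set(matrix(rnorm(8 * length(times)), 8), times)
  res2 <- cluster_test(waves2, perm_config(c(0, 396), n_permutations = 99,
                                           seed = 1))
  if (nrow(res2$clusters) > 0) {
    expect_true(all(res2$clusters$p_value >= 1 / 100))
    expect_true(all(res2$clusters$p_value <= 1))
  }
  expect_error(cluster_test(waves2, perm_config(c(2000, 2100), seed = 1)),
               "empty")
  expect_error(cluster_test(waves2[1], perm_config(c(0, 396), seed = 1)),
               "2 participants")
})

test_that("permutation p matches exhaustive sign-flip enumeration (n = 10)", {
  set.seed(21)
  n <- 10
  times <- seq(0, 156, by = 4) # 40 samples
  X <- matrix(rnorm(n * length(times)), n)
  X[, 16:26] <- X[, 16:26] + 0.75 # planted square pulse
  cfg <- perm_config(c(0, 156), n_permutations = 4000, seed = 77)
  res <- cluster_test(mk_wave_set(X, times), cfg)
  expect_gt(nrow(res$clusters), 0)
  obs_mass <- abs(res$clusters$mass[1])

  null_exact <- exact_null_masses(X, res$threshold)
  p_exact <- mean(null_exact >= obs_mass - 1e-9)
  p_mc <- res$clusters$p_value[1]
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / cfg$n_permutations) + 2 / 1024
  expect_lt(abs(p_mc - p_exact), tol)
  # the planted effect should be detected comfortably
  expect_lt(p_mc, 0.05)
})

test_that("the test is scale-free and participant-order invariant", {
  set.seed(9)
  n <- 9
  times <- seq(0, 196, by = 4)
  X <- matrix(rnorm(n * length(times)), n)
  X[, 20:35] <- X[, 20:35] + 0.9
  cfg <- perm_config(c(0, 196), n_permutations = 300, seed = 5)
  waves <- mk_wave_set(X, times)
  res <- cluster_test(waves, cfg)
  res_scaled <- cluster_test(mk_wave_set(3.7 * X, times), cfg)
  expect_equal(res_scaled$clusters$p_value, res$clusters$p_value)
  expect_equal(res_scaled$clusters$t_start, res$clusters$t_start)
  expect_equal(res_scaled$t_map, res$t_map, tolerance = 1e-9)

  res_perm <- cluster_test(waves[sample(n)], cfg)
  expect_equal(res_perm$clusters$p_value, res$clusters$p_value)
  expect_equal(res_perm$clusters$mass, res$clusters$mass, tolerance = 1e-9)
})

test_that("stronger planted effects never raise the minimum cluster p", {
  set.seed(14)
  n <- 10
  times <- seq(0, 196, by = 4)
  noise <- matrix(rnorm(n * length(times)), n)
  cfg <- perm_config(c(0, 196), n_permutations = 400, seed = 8)
  minp <- vapply(c(0, 0.4, 0.8, 1.4), function(amp) {
    X <- noise
    X[, 18:32] <- X[, 18:32] + amp
    res <- cluster_test(mk_wave_set(X, times), cfg)
    if (nrow(res$clusters) == 0) 1 else min(res$clusters$p_value)
  }, numeric(1))
  expect_true(all(diff(minp) <= 1e-12))
})

test_that("cluster members are connected under the spatiotemporal rule", {
  set.seed(31)
  m <- tiny_montage(c("Fz", "Cz", "Pz", "C3", "C4"))
  adj <- build_adjacency(m, 8)
  n <- 8
  times <- seq(0, 96, by = 4)
  waves <- lapply(1:n, function(i) {
    W <- matrix(rnorm(5 * length(times), sd = 0.7), 5)
    W[1:2, 10:18] <- W[1:2, 10:18] + 1.5
    make_wave(W, times = times, channels = m$label)
  })
  res <- cluster_test(waves, perm_config(c(0, 96), n_permutations = 200,
                                         adjacency = adj, seed = 3))
  expect_gt(nrow(res$clusters), 0)
  for (k in seq_len(nrow(res$clusters))) {
    mem <- res$members[[k]]
    if (nrow(mem) == 1) next
    # grow a component from the first member using only the declared rule
    reached <- 1L
    repeat {
      new <- reached
      for (i in seq_len(nrow(mem))) {
        if (i %in% reached) next
        for (j in reached) {
          same_t <- mem$time[i] == mem$time[j] &&
            mem$channel[i] %in% adj[[mem$channel[j]]]
          same_c <- mem$channel[i] == mem$channel[j] &&
            abs(mem$time[i] - mem$time[j]) <= 4 + 1e-9
          if (same_t || same_c) { new <- c(new, i); break }
        }
      }
      new <- unique(new)
      if (length(new) == length(reached)) break
      reached <- new
    }
    expect_equal(sort(reached), seq_len(nrow(mem)))
  }
})

test_that("windowed scans support the boundary-adjustment workflow", {
  set.seed(6)
  n <- 12
  times <- seq(0, 496, by = 4)
  X <- matrix(rnorm(n * length(times), sd = 0.8), n)
  sel <- times >= 220 & times <= 300 # planted 220-300 ms effect
  X[, sel] <- X[, sel] + 1.4
  waves <- mk_wave_set(X, times)
  cfg <- perm_config(c(0, 1), n_permutations = 300, seed = 12)
  scan <- windowed_scan(waves, list(c(100, 300), c(150, 350)), cfg)
  expect_equal(nrow(scan), 2)
  expect_true(all(scan$min_p < 0.05))
  r1 <- scan$result[[1]]$clusters
  r2 <- scan$result[[2]]$clusters
  # the shifted window captures the full upper extent of the cluster
  expect_gte(r2$t_end[1], r1$t_end[1])

  # automatic re-test when a significant cluster touches the window bound
  scan2 <- windowed_scan(waves, list(c(100, 300)), cfg, adjust_ms = 50)
  expect_equal(nrow(scan2), 2)
  expect_true(scan2$adjusted[2])
  expect_equal(c(scan2$window_start[2], scan2$window_end[2]), c(150, 350))

  # six canonical windows on pure noise: no wild excess of significance
  set.seed(41)
  Xn <- matrix(rnorm(n * length(times), sd = 1), n)
  scan0 <- windowed_scan(mk_wave_set(Xn, times),
                         list(c(0, 150), c(150, 300), c(300, 450)),
                         cfg)
  expect_true(all(is.na(scan0$min_p) | scan0$min_p >= 0.01))
})

test_that("cluster results expose tidy/glance summaries", {
  set.seed(2)
  times <- seq(0, 96, by = 4)
  X <- matrix(rnorm(6 * length(times)), 6)
  X[, 10:20] <- X[, 10:20] + 2
  res <- cluster_test(mk_wave_set(X, times),
                      perm_config(c(0, 96), n_permutations = 100, seed = 1))
  td <- tidy(res)
  expect_true(all(c("mass", "p_value", "t_start", "t_end") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_participants, 6)
  expect_equal(gl$n_permutations, 100)
})
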