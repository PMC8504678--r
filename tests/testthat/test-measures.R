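test_that("closed-form shapes: triangle and rectangle", {
  times <- seq(0, 600, by = 2) # grid aligned with the window endpoints
  tri <- pmax(0, 10 * (1 - abs(times - 300) / 100)) # peak 10 at 300, 200-400
  w <- make_wave(matrix(tri, 1), times = times, channels = "Cz")
  ms <- measure_wave(w, measure_config(c(200, 400), "positive"))
  expect_equal(ms$peak_amplitude, 10, tolerance = 1e-9)
  expect_equal(ms$peak_time, 300, tolerance = 2)
  expect_equal(ms$frac_area_latency, 300, tolerance = 1e-6)
  expect_equal(ms$frac_prepeak_latency, 250, tolerance = 1e-6)
  expect_equal(ms$signed_area, 10 * 200 / 2, tolerance = 1e-6)

  rect <- rep(2, length(times))
  wr <- make_wave(matrix(rect, 1), times = times, channels = "Cz")
  mr <- measure_wave(wr, measure_config(c(250, 400), "positive"))
  expect_equal(mr$mean_amplitude, 2, tolerance = 1e-12)
  expect_equal(mr$signed_area, 2 * 150, tolerance = 1e-9)
  expect_equal(mr$frac_area_latency, 325, tolerance = 1e-9)

  # negative polarity mirrors the sign conventions
  wn <- make_wave(matrix(-tri, 1), times = times, channels = "Cz")
  mn <- measure_wave(wn, measure_config(c(200, 400), "negative"))
  expect_equal(mn$peak_amplitude, -10, tolerance = 1e-9)
  expect_equal(mn$signed_area, -1000, tolerance = 1e-6)
  expect_equal(mn$frac_area_latency, 300, tolerance = 1e-6)
})

test_that("measures agree with a dense-grid oracle on random smooth waves", {
  dt <- 4
  times <- seq(0, 700, by = dt)
  window <- c(150, 550)
  for (seed in 1:25) {
    f <- random_smooth_fun(seed)
    w <- make_wave(matrix(f(times), 1), times = times, channels = "Cz")
    for (pol in c("positive", "negative")) {
      got <- measure_wave(w, measure_config(window, pol))
      if (got$polarity_missing) next
      want <- dense_measures(f, window, pol, dt = dt)
      expect_lt(abs(got$mean_amplitude - want$mean_amplitude), 0.05)
      expect_equal(got$signed_area, want$signed_area,
                   tolerance = max(2 * dt, 0.01 * abs(want$signed_area)))
      expect_lt(abs(got$peak_time - want$peak_time), dt + 1e-9)
      if (!got$prepeak_flagged) {
        expect_lt(abs(got$frac_prepeak_latency - want$frac_prepeak_latency),
                  dt + 1e-9)
      }
      expect_lt(abs(got$frac_area_latency - want$frac_area_latency),
                dt + 1e-9)
    }
  }
})

test_that("latency measures shift with time and ignore amplitude scale", {
  times <- seq(0, 700, by = 4)
  f <- random_smooth_fun(99)
  base <- measure_wave(make_wave(matrix(f(times), 1), times = times,
                                 channels = "Cz"),
                       measure_config(c(150, 450), "positive"))
  # time shift by 40 ms shifts both latencies by 40
  shifted <- measure_wave(make_wave(matrix(f(times - 40), 1), times = times,
                                    channels = "Cz"),
                          measure_config(c(190, 490), "positive"))
  expect_equal(shifted$frac_area_latency - base$frac_area_latency, 40,
               tolerance = 2)
  expect_equal(shifted$frac_prepeak_latency - base$frac_prepeak_latency, 40,
               tolerance = 2)
  # scaling by k > 0 leaves latencies; scales amplitudes by k
  scaled <- measure_wave(make_wave(matrix(3 * f(times), 1), times = times,
                                   channels = "Cz"),
                         measure_config(c(150, 450), "positive"))
  expect_equal(scaled$frac_area_latency, base$frac_area_latency,
               tolerance = 1e-9)
  expect_equal(scaled$frac_prepeak_latency, base$frac_prepeak_latency,
               tolerance = 1e-9)
  expect_equal(scaled$mean_amplitude, 3 * base$mean_amplitude,
               tolerance = 1e-9)
  expect_equal(scaled$signed_area, 3 * base$signed_area, tolerance = 1e-9)
})

test_that("fractional-area latency is monotone in the fraction", {
  times <- seq(0, 700, by = 4)
  f <- random_smooth_fun(7)
  w <- make_wave(matrix(f(times), 1), times = times, channels = "Cz")
  lat <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(fr) {
    measure_wave(w, measure_config(c(150, 550), "positive",
                                   fraction = fr))$frac_area_latency
  }, numeric(1))
  expect_true(all(diff(lat) >= -1e-9))
})

test_that("a window with no sample of the required polarity is flagged", {
  times <- seq(0, 400, by = 4)
  w <- make_wave(matrix(rep(-1, length(times)), 1), times = times,
                 channels = "Cz")
  ms <- measure_wave(w, measure_config(c(100, 300), "positive"))
  expect_true(ms$polarity_missing)
  expect_true(is.na(ms$frac_area_latency))
  expect_true(is.na(ms$frac_prepeak_latency))
  expect_equal(ms$signed_area, 0)
  expect_equal(ms$mean_amplitude, -1, tolerance = 1e-12)
})

test_that("2x2 contrast algebra is exact on noiseless cell means", {
  cells <- c(3, 5, 4, 9) # conditions 1..4
  measures <- tidyr::expand_grid(participant = 1:6, index = 1:4,
                                 electrode = c("Fz", "Cz"))
  measures$value <- cells[measures$index]
  inf <- two_by_two_inference(measures, "value", method = "cell_means")
  est <- setNames(inf$effects$estimate, inf$effects$term)
  expect_equal(unname(est["interaction"]),
               (cells[4] - cells[3]) - (cells[2] - cells[1]), tolerance = 1e-12)
  expect_equal(unname(est["ur_relation"]),
               mean(cells[3:4]) - mean(cells[1:2]), tolerance = 1e-12)
  expect_equal(unname(est["deviant_sandhi"]),
               mean(cells[c(2, 4)]) - mean(cells[c(1, 3)]), tolerance = 1e-12)

  expect_error(two_by_two_inference(measures[measures$index != 3, ], "value"),
               "missing condition cells")
})

test_that("mixed-model inference recovers a planted sandhi latency shift", {
  set.seed(77)
  delta <- 8 # ms earlier for sandhi conditions
  n <- 29
  tab <- tidyr::expand_grid(participant = 1:n, index = 1:4,
                            electrode = c("Fz", "FCz", "Cz"))
  ppe <- rnorm(n, 0, 6)
  tab$value <- 330 + ppe[tab$participant] +
    ifelse(tab$index %in% c(2, 4), -delta, 0) +
    rnorm(nrow(tab), 0, 5)
  inf <- two_by_two_inference(tab, "value", method = "lmm")
  eff <- inf$effects[inf$effects$term == "deviant_sandhi", ]
  expect_lt(abs(eff$estimate - (-delta)), 3) # recovered within ~CI
  expect_lt(eff$p.value, 0.01)
  ur <- inf$effects[inf$effects$term == "ur_relation", ]
  expect_gt(ur$p.value, 0.01) # no planted UR effect
  expect_equal(nrow(inf$posthoc), 6)
  expect_true(all(inf$posthoc$p.value <= 1))

  # null simulation at small n: effects near zero, p uniform-ish
  set.seed(5)
  tab0 <- tidyr::expand_grid(participant = 1:12, index = 1:4,
                             electrode = "Cz")
  tab0$value <- rnorm(nrow(tab0))
  inf0 <- two_by_two_inference(tab0, "value", method = "cell_means")
  expect_true(all(abs(inf0$effects$estimate) < 1.5))
  expect_true(all(inf0$effects$p.value > 0.001))
})

test_that("split-half comparison is antisymmetric and null at no growth", {
  set.seed(3)
  tab <- tidyr::expand_grid(participant = 1:10, index = 1:4,
                            electrode = "Cz", half = c("first", "second"))
  tab$value <- rnorm(nrow(tab))
  res <- split_half(tab, "value")
  expect_equal(res$condition[1], "all")
  expect_gt(res$p.value[1], 0.001) # no planted growth

  swapped <- tab
  swapped$half <- ifelse(tab$half == "first", "second", "first")
  res_sw <- split_half(swapped, "value")
  expect_equal(res_sw$estimate, -res$estimate, tolerance = 1e-12)

  # planted second-half growth is detected
  tab2 <- tab
  tab2$value <- tab2$value + ifelse(tab2$half == "second", 2, 0)
  res2 <- split_half(tab2, "value")
  expect_lt(res2$p.value[1], 0.001)
  expect_equal(res2$estimate[1], 2, tolerance = 0.5)
})
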