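test_that("re-referencing subtracts the mastoid mean exactly", {
  ep <- flat_epochs(3, c("Fz", "Cz", "M1", "M2"))
  ep$data[, 1, ] <- 2; ep$data[, 2, ] <- -1

  # zero reference channels leave the data unchanged
  out <- rereference(ep)
  expect_equal(out$data, ep$data)

  # constant 5 uV on both mastoids shifts everything by -5
  ep2 <- ep
  ep2$data[, 3, ] <- 5; ep2$data[, 4, ] <- 5
  out2 <- rereference(ep2)
  expect_true(all(abs(out2$data[, 1, ] - (2 - 5)) < 1e-12))
  expect_true(all(abs(out2$data[, 3, ]) < 1e-12))

  # random data: the mean of the re-referenced mastoids is zero everywhere
  ep3 <- ep
  ep3$data[] <- rnorm(length(ep3$data))
  out3 <- rereference(ep3)
  expect_lt(max(abs((out3$data[, 3, ] + out3$data[, 4, ]) / 2)), 1e-12)

  expect_error(rereference(flat_epochs(2, c("Fz", "Cz"))), "M1")
})

test_that("low-pass filter has the designed zero-phase Butterworth response", {
  fs <- 250
  times <- seq(-300, 1200, by = 1000 / fs)
  tone <- function(f) sin(2 * pi * f * times / 1000)
  ep <- flat_epochs(1, c("Fz", "Cz", "Pz"), fs = fs)
  ep$data[1, 1, ] <- tone(5)
  ep$data[1, 2, ] <- tone(100)
  ep$data[1, 3, ] <- 1 # DC

  for (method in c("filtfilt", "fft")) {
    out <- lowpass_filter(ep, 30, method = method)
    mid <- seq(40, length(times) - 40) # avoid edge transients
    expect_equal(max(abs(out$data[1, 1, mid])), 1, tolerance = 0.02)
    expect_lt(max(abs(out$data[1, 2, mid])), 0.1)
    expect_equal(out$data[1, 3, mid], rep(1, length(mid)), tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
  expect_error(lowpass_filter(ep, 125), "Nyquist")
  expect_error(lowpass_filter(ep, 200), "Nyquist")

  # white-noise spectrum is shaped by the theoretical |H|^2 response
  set.seed(4)
  n_rep <- 60
  epn <- flat_epochs(n_rep, "Fz", fs = fs)
  epn$data[] <- rnorm(length(epn$data))
  outn <- lowpass_filter(epn, 30)
  n_t <- length(times)
  f <- (seq_len(n_t) - 1) * fs / n_t
  spec <- sapply(seq_len(n_rep), function(i) {
    Mod(fft(outn$data[i, 1, ]))^2 / n_t
  })
  emp <- rowMeans(spec)
  theo <- oddwave:::butter_mag2(f, 30, 4)^2 # two-pass power response
  bandpower <- function(x, lo, hi) mean(x[f >= lo & f <= hi])
  # passband and transition band match within Monte-Carlo error
  expect_equal(bandpower(emp, 1, 20), bandpower(theo, 1, 20), tolerance = 0.1)
  expect_equal(bandpower(emp, 30, 40), bandpower(theo, 30, 40), tolerance = 0.15)
  expect_lt(bandpower(emp, 80, 120), 5e-3) # >= 23 dB below passband
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- flat_epochs(4, c("Fz", "Cz"))
  ep$data[] <- rnorm(length(ep$data))
  ep$data[1, 1, ] <- 7 # constant trial collapses to zero
  out <- baseline_correct(ep)
  expect_true(all(abs(out$data[1, 1, ]) < 1e-12))
  base <- apply(out$data[, , out$times <= 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-12)
  # idempotence
  out2 <- baseline_correct(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(-900, -700)), "outside")
})

test_that("rejection rules fire as specified and interpolation is convex", {
  m <- build_montage()
  spec <- quick_catalog(n_trials = 48)[1, ]
  s <- generate_sequence(spec, seed = 6)
  cfg <- quick_cfg(noise_sd = 3)
  ep <- simulate_subblock(spec, s, cfg, m)
  ep <- baseline_correct(ep)

  # clean data: everything retained
  res0 <- reject_and_interpolate(ep)
  expect_true(all(res0$report$trials$decision == "retained"))

  # 120 uV on one frontal channel -> that channel flagged, trial interpolated
  ep1 <- ep
  fp1 <- match("FP1", ep1$channels)
  ti <- which(ep1$times > 300 & ep1$times < 500)
  ep1$data[5, fp1, ti] <- ep1$data[5, fp1, ti] + 120
  res1 <- reject_and_interpolate(ep1)
  expect_equal(res1$report$trials$decision[5], "interpolated")
  expect_equal(res1$report$trials$bad_abs_channels[[5]], "FP1")
  # interpolated samples are convex combinations of good neighbours
  adj <- build_adjacency(m)
  nbrs <- match(adj[["FP1"]], ep1$channels)
  lo <- apply(res1$epochs$data[5, nbrs, ], 2, min)
  hi <- apply(res1$epochs$data[5, nbrs, ], 2, max)
  v <- res1$epochs$data[5, fp1, ]
  expect_true(all(v >= lo - 1e-9 & v <= hi + 1e-9))

  # four channels beyond 100 uV -> trial rejected
  ep4 <- ep
  ci <- match(c("FP1", "FP2", "Fz", "F3"), ep4$channels)
  for (cc in ci) ep4$data[7, cc, ti] <- ep4$data[7, cc, ti] + 130
  res4 <- reject_and_interpolate(ep4)
  expect_equal(res4$report$trials$decision[7], "rejected")
  expect_false(res4$epochs$trial_meta$retained[7])

  # a variance-inflated channel triggers the 5-SD distribution rule
  epv <- ep
  cz <- match("Cz", epv$channels)
  epv$data[3, cz, ] <- epv$data[3, cz, ] + rnorm(length(epv$times), 0, 20)
  resv <- reject_and_interpolate(epv)
  expect_true("Cz" %in% resv$report$trials$bad_channels[[3]])

  # decisions are invariant to trial and channel order
  perm_t <- sample(seq_len(dim(ep1$data)[1]))
  ep_p <- subset_trials(ep1, perm_t)
  res_p <- reject_and_interpolate(ep_p)
  expect_equal(res_p$report$trials$decision,
               res1$report$trials$decision[perm_t])
  perm_c <- sample(seq_len(31))
  m_c <- build_montage(m$label[perm_c])
  ep_c <- ep1
  ep_c$data <- ep1$data[, c(perm_c, 32, 33), , drop = FALSE]
  ep_c$channels <- c(ep1$channels[perm_c], "M1", "M2")
  ep_c$montage <- m_c
  res_c <- reject_and_interpolate(ep_c)
  expect_equal(res_c$report$trials$decision, res1$report$trials$decision)
})
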