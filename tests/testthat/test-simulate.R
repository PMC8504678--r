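test_that("component table encodes the planted orderings", {
  comps <- default_components()
  pk <- function(nm) unique(comps$peak_latency_ms[comps$name == nm])
  am <- function(nm) unique(abs(comps$amplitude[comps$name == nm]))
  # mapping < UR-mismatch < base in peak latency
  expect_lt(pk("mapping_positivity"), pk("ur_mismatch_positivity"))
  expect_lt(pk("ur_mismatch_positivity"), pk("base_positivity"))
  # mapping < UR-mismatch ~ base in amplitude
  expect_lt(am("mapping_positivity"), am("ur_mismatch_positivity"))
  expect_equal(am("ur_mismatch_positivity"), am("base_positivity"))
  expect_equal(pk("segmental_mmn"), 269)
  # S2 negativity peaks inside the canonical window, sandhi earlier
  s2 <- comps[comps$name == "s2_negativity", ]
  expect_true(all(s2$peak_latency_ms >= 550 & s2$peak_latency_ms <= 700))
})

test_that("forward model is an exact component sum at zero noise", {
  m <- tiny_montage(c("FCz", "Cz", "Pz"))
  spec <- quick_catalog()[1, ] # condition 1, standard xe2ma3 / deviant xuang2ma3
  s <- generate_sequence(spec, seed = 1)

  # zero components, zero noise -> all-zero epochs
  cfg0 <- quick_cfg(components = default_components()[0, ], noise_sd = 0,
                    ramp_gain = 0, include_mastoids = FALSE)
  ep0 <- simulate_subblock(spec, s, cfg0, m)
  expect_true(all(ep0$data == 0))

  # one component: voltage at its centre and peak latency equals `amplitude`
  one <- default_components()[default_components()$name == "base_positivity", ]
  one$role <- "any" # present in both roles so habituation is observable
  one$spatial_center <- "FCz"
  cfg1 <- quick_cfg(components = one, noise_sd = 0, ramp_gain = 0,
                    habituation_factor = 0.6, include_mastoids = FALSE)
  ep1 <- simulate_subblock(spec, s, cfg1, m)
  di <- which(ep1$trial_meta$role == "deviant")[1]
  ti <- which.min(abs(ep1$times - one$peak_latency_ms))
  expect_equal(unname(ep1$data[di, 1, ti]), one$amplitude, tolerance = 1e-9)
  # habituation scales standards by the configured factor
  si <- which(ep1$trial_meta$role == "standard")[1]
  expect_equal(unname(ep1$data[si, 1, ti]), 0.6 * one$amplitude, tolerance = 1e-9)

  # per-trial ramp: trial i is scaled by 1 + ramp_gain * i / n
  cfgr <- quick_cfg(components = one, noise_sd = 0, ramp_gain = 0.4,
                    include_mastoids = FALSE)
  epr <- simulate_subblock(spec, s, cfgr, m)
  d <- which(epr$trial_meta$role == "deviant")
  expect_equal(unname(epr$data[d[2], 1, ti] / epr$data[d[1], 1, ti]),
               (1 + 0.4 * d[2] / nrow(s)) / (1 + 0.4 * d[1] / nrow(s)),
               tolerance = 1e-9)

  # linearity: simulating with C1 u C2 equals the sum of the separate runs
  comps <- default_components()
  c1 <- comps[1:3, ]; c2 <- comps[4:9, ]
  mk <- function(cc) simulate_subblock(
    spec, s, quick_cfg(components = cc, noise_sd = 0, include_mastoids = FALSE),
    m)$data
  expect_equal(mk(comps), mk(c1) + mk(c2), tolerance = 1e-12)
})

test_that("identity subtraction retains the habituation residual analytically", {
  # condition 2 block D: both roles are sandhi tokens carrying the mapping
  # component; the identity wave must equal (1 - h) * mapping + deviant-only
  # components, computed here from an independent Gaussian evaluation
  m <- tiny_montage(c("FCz", "Cz"))
  cat2 <- quick_catalog()
  h <- 0.7
  cfg <- quick_cfg(habituation_factor = h, noise_sd = 0, ramp_gain = 0,
                   include_mastoids = FALSE)
  st <- simulate_study(cfg, m, cat2[cat2$block == "D", ], participants = 1,
                       rules = NULL)
  w2 <- identity_waves(st$erps, 1)[["2"]]

  times <- w2$times
  gauss <- function(a, mu, sd) a * exp(-0.5 * ((times - mu) / sd)^2)
  comps <- default_components()
  row <- function(nm, cond = NULL) {
    k <- comps$name == nm &
      vapply(comps$conditions, function(cc) is.null(cc) || is.null(cond) ||
               cond %in% cc, NA)
    comps[which(k)[1], ]
  }
  at_fcz <- function(r) gauss(r$amplitude, r$peak_latency_ms, r$temporal_sd_ms)
  expected <-
    at_fcz(row("base_positivity")) +
    at_fcz(row("early_negativity", 2)) +
    at_fcz(row("s2_negativity", 2)) +
    (1 - h) * at_fcz(row("mapping_positivity"))
  expect_equal(w2$wave["FCz", ], expected, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("simulation is reproducible and participant-specific", {
  m <- tiny_montage(c("FCz", "FP1", "FP2", "Cz", "Pz"))
  spec <- quick_catalog()[1, ]
  s <- generate_sequence(spec, seed = 5)
  cfg <- generator_config(sampling_rate = 250, seed = 9, artifact_rate = 0.1)
  a <- simulate_subblock(spec, s, cfg, m, participant = 1)
  b <- simulate_subblock(spec, s, cfg, m, participant = 1)
  expect_identical(a$data, b$data)
  expect_identical(a$trial_meta$artifact_type, b$trial_meta$artifact_type)
  c_ <- simulate_subblock(spec, s, cfg, m, participant = 2)
  expect_false(identical(a$data, c_$data))

  # mastoids are near-zero-signal channels
  expect_true(all(c("M1", "M2") %in% a$channels))
  mi <- match(c("M1", "M2"), a$channels)
  expect_lt(max(abs(a$data[, mi, ])), 6 * cfg$mastoid_noise_sd)

  # total noise SD is close to the configured value on a scalp channel
  expect_equal(sd(a$data[, 1, a$times < 0]), cfg$noise_sd, tolerance = 0.1)
})

test_that("artifact injection logs what it plants", {
  m <- build_montage()
  spec <- quick_catalog()[1, ]
  s <- generate_sequence(spec, seed = 2)
  cfg0 <- quick_cfg(noise_sd = 1)
  ep <- simulate_subblock(spec, s, cfg0, m)

  same <- inject_artifacts(ep, quick_cfg(artifact_rate = 0), seed = 1)
  expect_identical(same$data, ep$data)

  cfg1 <- quick_cfg(artifact_rate = 1, noise_sd = 1)
  art <- inject_artifacts(ep, cfg1, seed = 11)
  expect_true(all(!is.na(art$trial_meta$artifact_type)))
  expect_setequal(unique(art$trial_meta$artifact_type),
                  c("blink", "multi", "noisy"))
  # a blink deflection exceeds the 100 uV rule on exactly its logged channels
  bi <- which(art$trial_meta$artifact_type == "blink")[1]
  chs <- art$trial_meta$artifact_channels[[bi]]
  mx <- apply(abs(art$data[bi, , , drop = FALSE])[1, , ], 1, max)
  expect_true(all(mx[match(chs, art$channels)] > 100))
})

test_that("epoch container round-trips through text and BrainVision export", {
  ep <- flat_epochs(3, c("Fz", "Cz"), fs = 250)
  ep$data[] <- rnorm(length(ep$data))
  d <- tempfile()
  write_epochs(ep, d)
  ep2 <- read_epochs(d)
  expect_equal(ep2$data, ep$data, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(ep2$channels, ep$channels)
  expect_equal(ep2$fs, 250)

  bv <- tempfile()
  write_brainvision(ep, bv)
  expect_true(file.exists(paste0(bv, ".vhdr")))
  expect_true(file.exists(paste0(bv, ".vmrk")))
  expect_equal(file.size(paste0(bv, ".eeg")), 4 * length(ep$data))
  hdr <- readLines(paste0(bv, ".vhdr"))
  expect_true(any(grepl("NumberOfChannels=2", hdr)))
  expect_true(any(grepl("SamplingInterval=4000", hdr)))
})
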