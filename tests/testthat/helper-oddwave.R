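# shared fixtures and independent oracles

tiny_montage <- function(labels = c("Fz", "Cz", "Pz", "C3", "C4"),
                         circumference = 56) {
  build_montage(labels, circumference)
}

# fast generator settings for unit tests: short sub-blocks, low rate
quick_cfg <- function(...) {
  args <- list(n_participants = 2, sampling_rate = 250, artifact_rate = 0,
               participant_amp_sd = 0, participant_lat_sd = 0, seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

quick_catalog <- function(n_trials = 64) {
  condition_catalog(n_trials = n_trials, deviant_fraction = 0.125)
}

# bare ow_wave for algebra tests
make_wave <- function(mat, times = seq_len(ncol(mat)),
                      channels = paste0("ch", seq_len(nrow(mat))),
                      index = NA_integer_, identity = NA) {
  oddwave:::new_wave(mat, times, channels, index = index, identity = identity)
}

# independent brute-force adjacency oracle: O(n^2) pairwise comparison
brute_adjacency <- function(montage, threshold) {
  P <- as.matrix(montage[, c("x", "y", "z")])
  labs <- montage$label
  out <- setNames(vector("list", length(labs)), labs)
  for (i in seq_along(labs)) {
    nb <- character(0)
    for (j in seq_along(labs)) {
      if (i == j) next
      if (sqrt(sum((P[i, ] - P[j, ])^2)) <= threshold) nb <- c(nb, labs[j])
    }
    out[[i]] <- nb
  }
  out
}

# independent single-channel cluster machinery for the exact sign-flip oracle:
# clusters are runs of supra-threshold samples along time
runs_max_mass <- function(tv, thr, tail = "two_sided") {
  best <- 0
  for (sgn in c(1, -1)) {
    if (sgn > 0 && tail == "one_sided_negative") next
    if (sgn < 0 && tail == "one_sided_positive") next
    mask <- if (sgn > 0) tv > thr else tv < -thr
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    for (k in which(r$values)) {
      m <- abs(sum(tv[(ends[k] - r$lengths[k] + 1):ends[k]]))
      if (m > best) best <- m
    }
  }
  best
}

# exact distribution of the max cluster mass over all 2^n sign assignments
# (single channel; X is n x time)
exact_null_masses <- function(X, thr, tail = "two_sided") {
  n <- nrow(X)
  vapply(0:(2^n - 1), function(code) {
    s <- ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, -1, 1)
    Y <- X * s
    mu <- colMeans(Y)
    se <- apply(Y, 2, sd) / sqrt(n)
    runs_max_mass(mu / se, thr, tail)
  }, numeric(1))
}

# dense-grid point-measure oracle: measures computed from the analytic
# waveform `f` sampled at `oversample` times the implementation's resolution
dense_measures <- function(f, window, polarity = "positive", fraction = 0.5,
                           oversample = 1000, dt = 4) {
  tt <- seq(window[1], window[2], by = dt / oversample)
  v <- f(tt)
  sgn <- if (polarity == "positive") 1 else -1
  u <- sgn * v
  gated <- pmax(u, 0)
  area <- c(0, cumsum(diff(tt) * (head(gated, -1) + tail(gated, -1)) / 2))
  pk <- which.max(u)
  target <- fraction * u[pk]
  pre <- which(u[seq_len(pk)] < target)
  frac_prepeak <- if (length(pre) == 0) tt[1] else tt[max(pre)]
  tot <- area[length(area)]
  k <- which(area >= fraction * tot)[1]
  list(mean_amplitude = mean(v),
       signed_area = sgn * tot,
       peak_time = tt[pk],
       peak_amplitude = v[pk],
       frac_prepeak_latency = frac_prepeak,
       frac_area_latency = tt[k])
}

# random smooth analytic waveform: a few Gaussian bumps of either sign
random_smooth_fun <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  a <- runif(k, -5, 5)
  mu <- runif(k, 150, 550)
  sd <- runif(k, 30, 90)
  function(t) {
    out <- rep(0, length(t))
    for (i in seq_len(k)) out <- out + a[i] * exp(-0.5 * ((t - mu[i]) / sd[i])^2)
    out + 0.5 # offset so both polarities occur often
  }
}

# noise-free epochs with a single planted square effect on given channels
flat_epochs <- function(n_trial = 4, channels = c("Fz", "Cz"), fs = 250,
                        window = c(-300, 1200), value = 0) {
  times <- seq(window[1], window[2], by = 1000 / fs)
  data <- array(value, dim = c(n_trial, length(channels), length(times)))
  epoch_set(data, times, channels, fs)
}
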