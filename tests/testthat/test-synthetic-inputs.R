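test_that("gaussian envelope hits its closed-form landmarks and symmetry", {
  sp <- envelope_spec("gaussian", F_pre_max = 15)
  expect_equal(envelope_rate(sp$T_center, sp), 2 * 15)
  expect_equal(envelope_rate(sp$T_center + 1 / (2 * sp$f0), sp), 0,
               tolerance = 1e-12)
  # exact symmetry about the field center
  dl <- seq(0.01, 4, by = 0.37)
  expect_equal(envelope_rate(sp$T_center + dl, sp),
               envelope_rate(sp$T_center - dl, sp))
  expect_error(envelope_spec("triangular"), "arg")
  expect_error(envelope_spec("gaussian", sigma = -1), "sigma")
})

test_that("reflected Erlang envelope peaks at its analytic mode and
           vanishes beyond the reflection point", {
  sp <- envelope_spec("erlang", T_center = 5, lam = 5, k = 25)
  tt <- seq(0, 5, by = 1e-4)
  factor_only <- envelope_rate(tt, sp) / (1 + cos(2 * pi * sp$f0 * (tt - 5)))
  t_hat <- tt[which.max(factor_only)]
  expect_equal(t_hat, 5 - (25 - 1) / 5, tolerance = 1e-3)  # 0.2 s
  expect_identical(envelope_rate(c(5.01, 7, 9.9), sp), c(0, 0, 0))
})

test_that("noise application respects the mode definitions and rectifies", {
  base <- presyn_rate_series(envelope_spec(), n_synapses = 4, dt = 1e-3)
  expect_identical(apply_noise(base, noise_spec("none"))$values, base$values)
  expect_identical(apply_noise(base, noise_spec("additive_white", 0))$values,
                   base$values)
  # multiplicative noise cannot create rate where there is none
  m <- apply_noise(base, noise_spec("multiplicative_white", 0.5, seed = 3))
  zero_before <- base$values == 0
  expect_true(all(m$values[zero_before] == 0))
  for (mode in c("additive_white", "multiplicative_white", "additive_pink")) {
    out <- apply_noise(base, noise_spec(mode, 5e-3, seed = 11))
    expect_true(all(out$values >= 0))
  }
  expect_error(noise_spec("additive_white", -1), "nonnegative")
  # reproducible from the seed, different across seeds
  a <- apply_noise(base, noise_spec("additive_white", 1e-3, seed = 5))
  b <- apply_noise(base, noise_spec("additive_white", 1e-3, seed = 5))
  d <- apply_noise(base, noise_spec("additive_white", 1e-3, seed = 6))
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, d$values))
})

test_that("pink noise has a ~1/f spectral roll-off around the cutoff", {
  set.seed(99)
  dt <- 1e-3
  n <- 8192
  cutoff <- 5
  acc <- 0
  for (r in 1:120) {
    xi <- placefieldinfo:::pink_noise_matrix(n, 1, dt, cutoff)[, 1]
    sp <- Mod(stats::fft(xi))^2 / n
    acc <- acc + sp
  }
  freqs <- (seq_len(n) - 1) / (n * dt)
  band <- freqs >= cutoff / 2 & freqs <= 2 * cutoff
  fit <- stats::lm(log10(acc[band]) ~ log10(freqs[band]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.3)
})

test_that("spike sampling follows the per-step Bernoulli rule", {
  grid <- seq(0, 10, by = 1e-3)
  zero <- rate_series(grid, matrix(0, length(grid), 2))
  sts <- sample_spike_trains(zero, n_trials = 2, seed = 1)
  expect_identical(sum(lengths(unlist(sts$spikes, recursive = FALSE))), 0L)

  const <- rate_series(grid, matrix(10, length(grid), 1))
  sts <- sample_spike_trains(const, n_trials = 500, seed = 7)
  counts <- vapply(sts$spikes, function(tr) length(tr[[1]]), numeric(1))
  expected <- 10 * 10  # n * p summed over the grid
  se <- sqrt(expected * (1 - 0.01)) / sqrt(500)
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.15)

  s1 <- sample_spike_trains(const, n_trials = 1, seed = 1)
  s2 <- sample_spike_trains(const, n_trials = 1, seed = 2)
  expect_false(identical(s1$spikes, s2$spikes))
  s1b <- sample_spike_trains(const, n_trials = 1, seed = 1)
  expect_identical(s1$spikes, s1b$spikes)

  hot <- rate_series(c(0, 0.01, 0.02), matrix(200, 3, 1))
  expect_error(sample_spike_trains(hot, 1, seed = 1), "overflow")
  warm <- rate_series(c(0, 0.01, 0.02), matrix(15, 3, 1))
  expect_warning(sample_spike_trains(warm, 1, seed = 1), "finer")
})

test_that("expected total spike count matches the rate integral", {
  sp <- envelope_spec("gaussian", F_pre_max = 8)
  rs <- presyn_rate_series(sp, n_synapses = 1, dt = 1e-3)
  sts <- sample_spike_trains(rs, n_trials = 500, seed = 21)
  counts <- vapply(sts$spikes, function(tr) length(tr[[1]]), numeric(1))
  integral <- sum(rs$values[, 1]) * rs$dt
  se <- sqrt(integral) / sqrt(500)
  expect_lt(abs(mean(counts) - integral), 3 * se + 0.15)
})

test_that("ensemble drive is symmetric and peaks at the postsynaptic center", {
  one <- ensemble_spec(n_pre = 1)
  d1 <- build_ensemble_drive(one, envelope_spec())
  expect_length(d1, 1)
  expect_equal(d1[[1]]$weight, 1)
  expect_equal(d1[[1]]$envelope$T_center, 5)

  es <- ensemble_spec(n_pre = 15)
  expect_equal(es$weights, rev(es$weights))
  expect_equal(which.max(es$weights), 8L)  # middle neuron nearest center

  drive <- build_ensemble_drive(es, envelope_spec())
  tt <- seq(0, 10, by = 1e-3)
  total <- Reduce(`+`, lapply(drive, function(d) {
    d$weight * exp(-(tt - d$envelope$T_center)^2 / (2 * d$envelope$sigma^2))
  }))
  expect_lt(abs(tt[which.max(total)] - 5), 0.2)
})

test_that("spike trains export as two-column delimited text", {
  rs <- presyn_rate_series(envelope_spec(), n_synapses = 3, dt = 1e-3)
  sts <- sample_spike_trains(rs, n_trials = 1, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_spike_trains(sts, path)
  df <- utils::read.delim(path)
  expect_named(df, c("synapse_id", "time_s"))
  expect_identical(nrow(df), sum(lengths(sts$spikes[[1]])))
})
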