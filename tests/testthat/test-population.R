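test_that("parameter sampling stays in range, is seeded, and is uniform", {
  tab <- parameter_table()
  ps <- sample_parameters(200, seed = 8)
  for (p in ps) {
    v <- unlist(p[tab$name])
    expect_true(all(v >= tab$lo & v <= tab$hi))
  }
  expect_identical(sample_parameters(5, seed = 3), sample_parameters(5, seed = 3))
  expect_false(identical(sample_parameters(5, seed = 3),
                         sample_parameters(5, seed = 4)))
  # per-parameter uniformity over the sampled range
  big <- sample_parameters(5000, seed = 12)
  mat <- t(vapply(big, function(p) unlist(p[tab$name]), numeric(nrow(tab))))
  pvals <- vapply(seq_len(nrow(tab)), function(j) {
    suppressWarnings(stats::ks.test(mat[, j], "punif",
                                    tab$lo[j], tab$hi[j])$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("model validation flags out-of-bound measurements by name", {
  # high membrane resistivity, low axial load, weak h: input resistance
  # far above the 100 MOhm bound
  leaky <- model_params(Rm_soma = 250, Rm_end = 170, R_a = 250,
                        gh_soma = 12.5, gh_fold = 6)
  v <- validate_model(leaky, seed = 2)
  expect_false(v$valid)
  expect_true("R_in" %in% v$failed)
  # a weak drive cannot clear the 56 Hz tuning gate
  v2 <- validate_model(model_params(),
                       envelope = envelope_spec("gaussian", F_pre_max = 15),
                       seed = 2)
  expect_true("F_max" %in% v2$failed)
  # the base model passes every somatic bound
  v3 <- validate_model(model_params(), seed = 2)
  expect_true(v3$valid)
  expect_length(v3$failed, 0)
})

test_that("SSI transition classification follows the highest-noise ratio", {
  expect_identical(classify_ssi_transition(c(0.4, 0.6, 0.8)), "slope_maximal")
  expect_identical(classify_ssi_transition(c(0.5, 0.9, 1.3)), "peak_maximal")
  expect_error(classify_ssi_transition(numeric(0)), "empty")
  expect_error(classify_ssi_transition(c(0.5, 0.9)), ">= 3")
})

test_that("knockout of an already-absent component changes nothing, and
           spike-generator knockouts are refused", {
  p <- model_params(gKM = 0)
  cal <- calibrate_unitary_epsp(p)
  entry <- list(params = p, P_ampa = cal$P_ampa, P_nmda = cal$P_nmda,
                model_id = 1L)
  ko <- virtual_knockout(entry, "KM", noise_spec("additive_white", 5e-4),
                         n_trials = 2, seed = 9)
  expect_true(all(abs(unlist(ko[placefieldinfo:::ko_metric_cols])) == 0))
  dummy <- as.data.frame(as.list(stats::setNames(
    rep(1, length(placefieldinfo:::ko_metric_cols)),
    placefieldinfo:::ko_metric_cols)))
  expect_error(virtual_knockout(entry, "NaF", baseline = dummy),
               "ceases spiking")
  expect_error(virtual_knockout(entry, "KDR", baseline = dummy),
               "ceases spiking")
  expect_error(virtual_knockout(entry, "XYZ", baseline = dummy), "unknown")
})

test_that("correlation reports categorize strengths and stay symmetric", {
  n <- 200
  x <- seq_len(n)
  rep_lin <- correlation_report(cbind(x = x, y = 2 * x + 3, z = rev(x)))
  expect_equal(rep_lin$r["x", "y"], 1)
  expect_identical(rep_lin$category["x", "y"], "Very Strong")
  expect_equal(rep_lin$r, t(rep_lin$r))
  expect_true(all(diag(rep_lin$r) == 1))

  # construct a pair with sample correlation exactly 0.39
  set.seed(2)
  z <- rnorm(n)
  xs <- scale(x)[, 1]
  zs <- scale(stats::resid(stats::lm(z ~ xs)))[, 1]
  y39 <- 0.39 * xs + sqrt(1 - 0.39^2) * zs
  rep39 <- correlation_report(cbind(a = xs, b = y39))
  expect_equal(rep39$r["a", "b"], 0.39, tolerance = 1e-9)
  expect_identical(rep39$category["a", "b"], "Weak")

  const <- correlation_report(cbind(a = x, b = rep(1, n)))
  expect_true(is.na(const$r["a", "b"]))
  expect_error(correlation_report(cbind(1:2, 2:3)))
})

test_that("subpopulation PCA reports nonincreasing variance fractions and
           finds a planted dominant direction", {
  ga <- sample_parameters(5, seed = 1)
  pc <- pca_subpopulations(ga, ga)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-9)
  # identical groups produce identical score distributions
  expect_equal(pc$scores[1:5, 1], pc$scores[6:10, 1])

  # one dominant linear direction across three conductances
  tvals <- seq(-1, 1, length.out = 8)
  gb <- lapply(tvals, function(t) {
    model_params(gNa = 16 * (1 + 0.4 * t), gKDR = 10 * (1 + 0.4 * t),
                 gSK = 1.5 * (1 + 0.4 * t))
  })
  pc2 <- pca_subpopulations(gb[1:4], gb[5:8])
  expect_gt(pc2$explained[1], 0.9)
})

test_that("place-field asymmetry expresses through MI far more than SSI", {
  swe <- sweep_erlang_low()
  expect_gt(stats::median(swe$MI2), stats::median(swe$MI1))
  ssi_rel <- abs(swe$SSI1 - swe$SSI2) / pmax(swe$SSI1, swe$SSI2)
  mi_rel <- abs(swe$MI1 - swe$MI2) / pmax(swe$MI1, swe$MI2)
  expect_lt(stats::median(ssi_rel), stats::median(mi_rel))
})

test_that("additive noise raises the peak rate of the simulated field", {
  sw <- sweep_agwn()
  med <- vapply(split(sw$F_max, sw$sigma_noise), stats::median, numeric(1))
  expect_true(all(diff(med) > 0))
})
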