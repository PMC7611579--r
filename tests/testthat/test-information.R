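test_that("joint histograms conserve counts and marginals", {
  grid <- seq(0, 10, by = 0.01)
  rp <- rate_profile_set(grid, matrix(7, length(grid), 3))
  h <- build_joint_histogram(rp, stim_edges = c(0, 10),
                             resp_edges = seq(0, 10, length.out = 6))
  expect_equal(sum(h$counts), 3)          # one sample per stim bin per trial
  expect_equal(h$counts[1, 4], 3)         # all mass in the 7 Hz cell

  set.seed(4)
  rp2 <- rate_profile_set(grid, matrix(runif(length(grid) * 5, 0, 40),
                                       ncol = 5))
  se <- seq(0, 10, length.out = 21)
  h2 <- build_joint_histogram(rp2, se, seq(0, 40, length.out = 11),
                              sample_mode = "all_samples")
  expect_equal(sum(h2$counts), length(grid) * 5)
  p_s <- rowSums(h2$counts) / h2$n
  expect_equal(sum(p_s), 1)
  expect_equal(sum(colSums(h2$counts)) / h2$n, 1)
})

test_that("mutual information matches entropy limits on designed tables", {
  # independent uniform joint
  expect_lt(mutual_information(matrix(5, 4, 20)), 1e-12)
  # bijective map over 4 equiprobable stimuli
  bij <- matrix(0, 4, 20)
  bij[cbind(1:4, c(3, 8, 13, 18))] <- 25
  expect_equal(mutual_information(bij), 2, tolerance = 1e-12)
  expect_error(mutual_information(matrix(0, 2, 2)), "empty")
})

test_that("mutual information equals the brute-force double sum on random
           tables", {
  set.seed(101)
  for (r in 1:200) {
    counts <- random_joint()
    expect_equal(mutual_information(counts), mi_bruteforce(counts),
                 tolerance = 1e-12)
  }
})

test_that("specific information obeys its defining identities", {
  # deterministic encoder over 80 stimuli: Isp = log2(80) everywhere
  det <- matrix(0, 80, 80); det[cbind(1:80, 1:80)] <- 30
  isp <- specific_information(det)
  expect_equal(unname(isp), rep(log2(80), 80), tolerance = 1e-12)
  # response independent of stimulus: Isp = 0
  ind <- matrix(3, 10, 8)
  expect_equal(unname(specific_information(ind)), rep(0, 8),
               tolerance = 1e-12)
  # sum_j p(F_j) Isp(F_j) = I(S;F) against the brute-force oracle
  set.seed(77)
  for (r in 1:200) {
    counts <- random_joint(6, 12, 300)
    p_f <- colSums(counts) / sum(counts)
    isp <- specific_information(counts)
    lhs <- sum(p_f[p_f > 0] * isp[p_f > 0])
    expect_equal(lhs, mi_bruteforce(counts), tolerance = 1e-12)
  }
})

test_that("the bias-correction constant follows its closed form", {
  expect_equal(treves_panzeri_c1(80, 40, 2400),
               79 * 39 / (2 * 2400 * log(2)), tolerance = 1e-15)
  expect_equal(treves_panzeri_c1(1, 40, 100), 0)
  ns <- 10^(2:6)
  c1s <- vapply(ns, function(n) treves_panzeri_c1(80, 40, n), numeric(1))
  expect_true(all(diff(c1s) < 0))
  expect_equal(c1s[1] / c1s[5], 1e4, tolerance = 1e-9)
})

test_that("SSI averages to the global mutual information and hits the
           deterministic limit", {
  set.seed(13)
  for (r in 1:100) {
    counts <- random_joint(8, 10, 400)
    keep <- rowSums(counts) > 0
    counts <- counts[keep, , drop = FALSE]
    if (nrow(counts) < 2) next
    ssi <- ssi_values(counts, bias_correct = FALSE)
    p_s <- rowSums(counts) / sum(counts)
    expect_equal(sum(p_s * ssi), mi_bruteforce(counts), tolerance = 1e-12)
  }
  # deterministic 80-bin encoder through the profile interface
  grid <- seq(0, 10, length.out = 1001)
  ramp <- matrix(seq(0, 81, length.out = 1001), ncol = 1)[, rep(1, 30)]
  rp <- rate_profile_set(grid, ramp)
  cfg <- binning_config(ssi_response_bins = 80, n_trials = 30)
  prof <- ssi_profile(rp, cfg, bias_correct = FALSE)
  expect_equal(prof$values, rep(log2(80), 80), tolerance = 1e-9)
})

test_that("piecewise MI reaches 2 bits for a fully discriminable ramp and
           zero for a constant response", {
  grid <- seq(0, 10, length.out = 2001)
  rp_const <- rate_profile_set(grid, matrix(5, length(grid), 4))
  prof0 <- mi_profile(rp_const, binning_config(n_trials = 4),
                      bias_correct = FALSE)
  expect_length(prof0$values, 20)
  expect_true(all(prof0$values < 1e-12))

  ramp <- matrix(seq(0, 100, length.out = length(grid)), ncol = 1)[, rep(1, 4)]
  rp <- rate_profile_set(grid, ramp)
  cfg <- binning_config(n_trials = 4, response_range_mode = "per_location")
  prof <- mi_profile(rp, cfg, bias_correct = FALSE)
  expect_equal(prof$values, rep(2, 20), tolerance = 1e-9)
})

test_that("coarsening response bins never increases mutual information", {
  set.seed(31)
  for (r in 1:100) {
    counts <- random_joint(5, 40, 600)
    coarse <- counts[, seq(1, 39, by = 2)] + counts[, seq(2, 40, by = 2)]
    expect_lte(mutual_information(coarse),
               mutual_information(counts) + 1e-12)
  }
})

test_that("bias-corrected specific information shrinks toward zero with
           more trials on stimulus-independent data", {
  mean_abs_corr <- function(n_trials, seed) {
    set.seed(seed)
    grid <- seq(0, 10, length.out = 401)
    rp <- rate_profile_set(grid, matrix(runif(401 * n_trials, 0, 30),
                                        ncol = n_trials))
    se <- seq(0, 10, length.out = 81)
    re <- seq(0, 30, length.out = 41)
    h <- build_joint_histogram(rp, se, re)
    isp <- specific_information(h)
    c1 <- treves_panzeri_c1(80, 40, h$n)
    abs(mean(isp - c1, na.rm = TRUE))
  }
  b30 <- mean_abs_corr(30, 5)
  b300 <- mean_abs_corr(300, 5)
  expect_lt(b300, b30)
})

test_that("profile metrics characterize constructed profiles correctly", {
  pos <- seq(0, 10, by = 0.05)
  grid <- seq(0, 10, by = 0.01)
  rate <- rate_profile_set(grid, cbind(60 * exp(-(grid - 5)^2 / 2)))
  a <- 1.5
  two_bump <- exp(-(pos - (5 - a))^2 / (2 * 0.25)) +
              exp(-(pos - (5 + a))^2 / (2 * 0.25))
  ip <- info_profile(pos, two_bump, "SSI")
  pm <- profile_metrics(ip, rate)
  expect_false(pm$unimodal)
  expect_equal(pm$peak1, pm$peak2, tolerance = 1e-9)
  expect_equal(pm$d, 2 * a, tolerance = 0.1)
  expect_equal(pm$d_ratio, 1, tolerance = 0.05)
  expect_lt(pm$dip, 0)

  single <- exp(-(pos - 5)^2 / (2 * 0.8^2))
  pms <- profile_metrics(info_profile(pos, single, "SSI"), rate)
  expect_true(pms$unimodal)
  expect_equal(pms$dip, 0)
  expect_equal(pms$d, 0)
  # FWHM of a Gaussian profile
  expect_equal(fwhm <- pms$fwhm, 2 * sqrt(2 * log(2)) * 0.8, tolerance = 0.01)
})
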