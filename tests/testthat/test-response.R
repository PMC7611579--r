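make_trace <- function(v, dt = 0.1) {
  structure(list(time_ms = seq(0, by = dt, length.out = length(v)),
                 v = v, dt = dt), class = "voltage_trace")
}

test_that("spike detection counts one event per rising crossing", {
  flat <- make_trace(rep(-65, 1000))
  expect_length(detect_spikes(flat), 0)
  v <- rep(-65, 3000)
  for (at in c(500, 1500, 2500)) v[at + 0:20] <- 30  # 2 ms pulses
  expect_length(detect_spikes(make_trace(v)), 3)
  # a sample landing exactly on the threshold during a rise counts once
  v2 <- c(-65, -40, -20, 0, -65)
  expect_length(detect_spikes(make_trace(v2, dt = 1)), 1)
})

test_that("kernel rate estimation is normalized and shift-equivariant", {
  grid <- seq(0, 10, by = 0.01)
  expect_identical(estimate_rate(numeric(0), 0.2, grid), numeric(length(grid)))
  r1 <- estimate_rate(5, 0.2, grid)
  expect_equal(max(r1), 1 / (0.2 * sqrt(2 * pi)), tolerance = 1e-4)
  spikes <- c(3, 4.5, 5, 5.2, 7)
  r <- estimate_rate(spikes, 0.2, grid)
  expect_equal(sum(r) * 0.01, length(spikes), tolerance = 0.01)
  # shifting all spikes shifts the profile
  r_shift <- estimate_rate(spikes + 1, 0.2, grid)
  idx <- grid >= 2 & grid <= 8
  expect_equal(r_shift[which(idx) + 100], r[idx], tolerance = 1e-9)
})

test_that("place-field metrics recover closed-form peak and width", {
  grid <- seq(0, 10, by = 0.01)
  prof <- 60 * exp(-(grid - 5)^2 / (2 * 0.8^2))
  rp <- rate_profile_set(grid, cbind(prof, prof))
  pf <- place_field_metrics(rp)
  expect_equal(pf$F_max, 60)
  expect_equal(pf$FWHM, 2 * sqrt(2 * log(2)) * 0.8, tolerance = 1e-3)
  # scaling doubles the peak, leaves the width unchanged
  pf2 <- place_field_metrics(rate_profile_set(grid, cbind(2 * prof)))
  expect_equal(pf2$F_max, 120)
  expect_equal(pf2$FWHM, pf$FWHM, tolerance = 1e-9)
  flat <- rate_profile_set(grid, cbind(rep(4, length(grid))))
  expect_true(is.na(place_field_metrics(flat)$FWHM))
})

test_that("median filtering separates ramp and theta components", {
  dt <- 0.5  # ms
  tt <- seq(0, 10000 - dt, by = dt) / 1000
  const <- make_trace(rep(-60, length(tt)), dt)
  sf <- subthreshold_features(const, rest = -65)
  expect_equal(sf$V_ramp, 5)
  expect_lt(sf$theta_power, 1e-10)

  osc <- make_trace(-65 + 2 * sin(2 * pi * 8 * tt), dt)
  sfo <- subthreshold_features(osc, rest = -65)
  # theta survives the 50 ms filter ...
  n <- length(tt)
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  filt <- placefieldinfo:::median_filter(osc$v, round(0.05 / (dt / 1000)))
  filt <- filt - mean(filt)
  npad <- stats::nextn(n, c(2, 3, 5))
  sp <- Mod(stats::fft(c(filt * hann, numeric(npad - n))))^2
  freqs <- (seq_len(npad) - 1) / (npad * dt / 1000)
  p8 <- sp[which.min(abs(freqs - 8))]
  p2 <- sp[which.min(abs(freqs - 2))]
  expect_gt(p8 / max(p2, 1e-12), 100)
  # ... and is removed by the 0.75 s filter
  expect_lt(sfo$V_ramp, 0.3)
  # a DC offset moves the ramp, not the theta power
  sfd <- subthreshold_features(make_trace(osc$v + 3, dt), rest = -65)
  expect_equal(sfd$V_ramp - sfo$V_ramp, 3, tolerance = 1e-6)
  expect_equal(sfd$theta_power, sfo$theta_power, tolerance = 1e-6)
})

test_that("impedance measures match closed forms for linear membranes", {
  ch <- inject_protocol("chirp")
  # pure resistor
  R <- 80
  imp <- impedance_measures(ch$i_nA, R * ch$i_nA, ch$dt)
  expect_true(all(abs(imp$Zmag - R) / R < 0.01))
  expect_equal(imp$Q, 1, tolerance = 0.01)
  expect_lt(imp$Phi_L, 1e-3)
  # passive RC: |Z| = R / sqrt(1 + (2 pi f tau)^2), no inductive phase
  v_rc <- rc_response(ch$i_nA, R_MOhm = 100, tau_ms = 20, dt_ms = ch$dt)
  imp_rc <- impedance_measures(ch$i_nA, v_rc, ch$dt)
  expected <- 100 / sqrt(1 + (2 * pi * imp_rc$freq * 0.02)^2)
  expect_true(all(abs(imp_rc$Zmag - expected) / expected < 0.01))
  expect_lt(imp_rc$Phi_L, 1e-3)
  expect_gte(imp_rc$Q + 1e-9, 1)
  # resonant two-variable membrane vs its analytic impedance
  p <- model_params()
  memb <- derive_surrogate(p)
  tr <- simulate_response(params = p, protocol = ch, spiking = FALSE)
  imp_res <- impedance_measures(tr$i_inj, tr$v, ch$dt)
  z_th <- Mod(resonator_impedance(imp_res$freq, memb$gL, memb$gw,
                                  memb$C, memb$tau_w))
  expect_true(all(abs(imp_res$Zmag - z_th) / z_th < 0.02))
  expect_gt(imp_res$f_R, 0)
  expect_gt(imp_res$Q, 1)
  expect_error(impedance_measures(numeric(100) , numeric(100), 0.1), "energy")
})

test_that("input resistance from an RC step settles to the true resistance", {
  dt <- 0.1
  n <- round(500 / dt)
  i <- rep(-0.1, n)
  v <- -65 + rc_response(i, R_MOhm = 80, tau_ms = 20, dt_ms = dt)
  tr <- make_trace(v, dt)
  expect_equal(input_resistance(tr, -100, rest = -65), 80, tolerance = 0.005)
})
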