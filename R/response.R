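#' Detect spikes from a voltage trace
#'
#' One event per upward threshold crossing, defined as
#' `v[i-1] < threshold <= v[i]`; detected events closer than 1 ms to the
#' previous one are discarded.
#'
#' @param trace A `voltage_trace` (or list with `time_ms`, `v`).
#' @param threshold Detection threshold (mV); default -20 mV, on the rising
#'   phase of the surrogate's pasted spike waveform.
#' @return Spike times (ms).
#' @export
detect_spikes <- function(trace, threshold = -20) {
  v <- trace$v
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  tt <- trace$time_ms[up]
  if (length(tt) > 1) {
    keep <- rep(TRUE, length(tt))
    last <- tt[1]
    for (i in 2:length(tt)) {
      if (tt[i] - last < 1) keep[i] <- FALSE else last <- tt[i]
    }
    tt <- tt[keep]
  }
  tt
}

#' Gaussian-kernel firing-rate estimate
#'
#' `rate(t) = sum_spikes N(t - t_spike; sigma)` with the kernel normalized
#' to unit integral, so the rate integrates to the spike count.
#'
#' @param spikes Spike times (s).
#' @param sigma_kernel Kernel width (s); default 200 ms.
#' @param grid Time grid (s) on which to evaluate the rate.
#' @return Rate (Hz) on `grid`.
#' @export
estimate_rate <- function(spikes, sigma_kernel = 0.2, grid) {
  stopifnot(sigma_kernel > 0)
  if (length(spikes) == 0) return(numeric(length(grid)))
  colSums(matrix(stats::dnorm(outer(spikes, grid, "-"), sd = sigma_kernel),
                 nrow = length(spikes)))
}

#' Per-trial firing-rate profiles on a common grid
#'
#' @param time Common time grid (s).
#' @param rates Matrix `length(time)` x `n_trials` of rates (Hz).
#' @return Object of class `rate_profile_set`.
#' @export
rate_profile_set <- function(time, rates) {
  rates <- as.matrix(rates)
  stopifnot(nrow(rates) == length(time), all(rates >= 0))
  structure(list(time = time, rates = rates, n_trials = ncol(rates)),
            class = "rate_profile_set")
}

#' @export
print.rate_profile_set <- function(x, ...) {
  cat(sprintf("<rate_profile_set> %d samples x %d trials, peak trial-mean %.1f Hz\n",
              length(x$time), x$n_trials, max(rowMeans(x$rates))))
  invisible(x)
}

#' Build rate profiles from trial spike times
#'
#' @param spike_times_s List with one numeric vector of spike times (s)
#'   per trial.
#' @param t_start,t_end Window (s).
#' @param dt_grid Analysis grid step (s).
#' @param sigma_kernel Kernel width (s).
#' @return A [rate_profile_set()].
#' @export
rate_profiles_from_spikes <- function(spike_times_s, t_start = 0, t_end = 10,
                                      dt_grid = 0.01, sigma_kernel = 0.2) {
  grid <- seq(t_start, t_end, by = dt_grid)
  rates <- vapply(spike_times_s,
                  function(s) estimate_rate(s, sigma_kernel, grid),
                  numeric(length(grid)))
  rate_profile_set(grid, matrix(rates, nrow = length(grid)))
}

# Outermost half-maximum crossings of a profile, linear interpolation.
fwhm_of_profile <- function(x, y, innermost = FALSE) {
  ymax <- max(y)
  half <- ymax / 2
  above <- y >= half
  if (all(above) || ymax <= 0) return(NA_real_)
  ipk <- which.max(y)
  cross_left <- which(!above[-length(above)] & above[-1])      # rising
  cross_right <- which(above[-length(above)] & !above[-1])     # falling
  interp <- function(i, rising) {
    # crossing between sample i and i+1
    x[i] + (half - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  }
  lefts <- cross_left[cross_left < ipk]
  rights <- cross_right[cross_right >= ipk]
  if (!length(lefts) || !length(rights)) return(NA_real_)
  li <- if (innermost) max(lefts) else min(lefts)
  ri <- if (innermost) min(rights) else max(rights)
  interp(ri) - interp(li)
}

#' Peak rate and full width at half maximum of a place-field profile
#'
#' `F_max` is the maximum of the trial-mean rate; `FWHM` is the temporal
#' distance between the outermost half-maximum crossings of that mean
#' profile (linear interpolation between samples). A profile that never
#' drops below half its maximum inside the window has no defined FWHM.
#'
#' @param rate A [rate_profile_set()].
#' @param innermost Use the innermost rather than outermost half-max
#'   crossings.
#' @return List with `F_max` (Hz), `FWHM` (s; `NA` with attribute
#'   `undefined` when not measurable), `t_peak` (s).
#' @export
place_field_metrics <- function(rate, innermost = FALSE) {
  m <- rowMeans(rate$rates)
  F_max <- max(m)
  if (diff(range(m)) == 0) {
    fw <- structure(NA_real_, undefined = TRUE)
  } else {
    fw <- fwhm_of_profile(rate$time, m, innermost)
    if (is.na(fw)) fw <- structure(NA_real_, undefined = TRUE)
  }
  list(F_max = F_max, FWHM = fw, t_peak = rate$time[which.max(m)])
}

# Median filter with edge reflection; window given in samples (forced odd).
median_filter <- function(v, width_samples) {
  k <- max(3L, as.integer(width_samples))
  if (k %% 2 == 0) k <- k + 1L
  half <- (k - 1L) %/% 2L
  n <- length(v)
  padded <- c(rev(v[seq_len(half) + 1L]), v, v[(n - 1L):(n - half)])
  as.numeric(stats::runmed(padded, k, endrule = "keep"))[half + seq_along(v)]
}

#' Subthreshold ramp and theta power of a traversal trace
#'
#' The depolarizing ramp is exposed by a 0.75 s wide median filter (which
#' removes spikes); `V_ramp` is its maximum minus the resting potential.
#' Theta power is the Fourier power at 8 Hz (nearest bin after Hann
#' windowing) of the 50 ms median-filtered trace with its mean removed.
#'
#' @param trace A `voltage_trace` of at least 2 s.
#' @param rest Resting potential (mV).
#' @param theta_freq Frequency (Hz) at which to read the power.
#' @return List with `V_ramp` (mV) and `theta_power` (mV^2).
#' @export
subthreshold_features <- function(trace, rest = -65, theta_freq = 8) {
  n <- length(trace$v)
  dt_s <- trace$dt / 1000
  if (n * dt_s < 2) stop("trace must span at least 2 s")
  w_ramp <- round(0.75 / dt_s)
  w_theta <- round(0.05 / dt_s)
  ramp_trace <- median_filter(trace$v, w_ramp)
  # the ramp maximum is read where the filter window fits fully inside the
  # record; edge values rest on mirrored extrapolation
  interior <- seq.int(w_ramp %/% 2 + 1L, n - w_ramp %/% 2)
  v_ramp <- max(ramp_trace[interior]) - rest
  th <- median_filter(trace$v, w_theta)
  th <- th - mean(th)
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  npad <- stats::nextn(n, c(2, 3, 5))
  sp <- stats::fft(c(th * hann, numeric(npad - n)))
  freqs <- (seq_len(npad) - 1) / (npad * dt_s)
  bin <- which.min(abs(freqs - theta_freq))
  # one-sided power normalised by the window energy
  theta_power <- 2 * Mod(sp[bin])^2 / sum(hann^2)^2 * sum(hann^2) / n
  list(V_ramp = v_ramp, theta_power = theta_power)
}

#' Impedance-based resonance measures from a chirp response
#'
#' `Z(f) = FFT(V) / FFT(I)` evaluated over the band \[0.5, 15\] Hz.
#' Reports the impedance magnitude profile, `|Z|_max`, the resonance
#' frequency `f_R` (argmax of `|Z|`), the resonance strength
#' `Q = |Z|_max / |Z|(0.5 Hz)`, and the total inductive phase
#' `Phi_L = integral of the positive part of the phase profile` (rad Hz).
#'
#' @param current Injected current (nA) per sample.
#' @param voltage Voltage response (mV), same grid.
#' @param dt Sample step (ms).
#' @param band Frequency band (Hz).
#' @return List with `freq`, `Zmag` (MOhm), `phase` (rad), `Z_max`, `f_R`,
#'   `Q`, `Phi_L`.
#' @export
impedance_measures <- function(current, voltage, dt, band = c(0.5, 15)) {
  stopifnot(length(current) == length(voltage))
  dt_s <- dt / 1000
  # zero-pad to a highly composite length: keeps the FFT O(n log n)
  n <- stats::nextn(length(current), c(2, 3, 5))
  pad <- function(v) c(v - mean(v), numeric(n - length(v)))
  fi <- stats::fft(pad(current))
  fv <- stats::fft(pad(voltage))
  freqs <- (seq_len(n) - 1) / (n * dt_s)
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep) || all(Mod(fi[keep]) < 1e-12)) {
    stop("current spectrum has no energy in the analysis band")
  }
  # cross-spectral estimate with a ~0.4 Hz boxcar: suppresses the leakage
  # ripple a single chirp record leaves in the raw FFT ratio
  df <- 1 / (n * dt_s)
  half <- max(1L, as.integer(round(0.2 / df)))
  box <- rep(1, 2 * half + 1)
  s_vi <- fv * Conj(fi)
  s_ii <- Mod(fi)^2
  smooth_c <- function(x) {
    out <- stats::filter(Re(x), box, sides = 2) +
      1i * stats::filter(Im(x), box, sides = 2)
    as.complex(out)
  }
  Z <- smooth_c(s_vi)[keep] / Re(smooth_c(s_ii))[keep]
  freq <- freqs[keep]
  Zmag <- Mod(Z)
  phase <- Arg(Z)
  ipk <- which.max(Zmag)
  df <- diff(freq[1:2])
  pos <- pmax(phase, 0)
  phi_l <- sum((pos[-1] + pos[-length(pos)]) / 2) * df
  list(freq = freq, Zmag = Zmag, phase = phase,
       Z_max = Zmag[ipk], f_R = freq[ipk], Q = Zmag[ipk] / Zmag[1],
       Phi_L = phi_l)
}

#' Input resistance from a current-step response
#'
#' `R_in = |deltaV / I|`, with the deflection measured as the mean of the
#' last 100 ms of the step relative to the pre-step baseline.
#'
#' @param trace A `voltage_trace` from a step protocol.
#' @param step Step amplitude (pA), nonzero.
#' @param rest Pre-step baseline potential (mV); defaults to the first
#'   sample of the trace.
#' @param step_start_ms,step_end_ms Step window within the trace (ms);
#'   defaults to the whole trace.
#' @return `R_in` (MOhm).
#' @export
input_resistance <- function(trace, step, rest = NULL, step_start_ms = 0,
                             step_end_ms = NULL) {
  if (step == 0) stop("step current must be nonzero")
  if (is.null(step_end_ms)) step_end_ms <- max(trace$time_ms)
  base <- if (!is.null(rest)) {
    rest
  } else if (step_start_ms > 0) {
    mean(trace$v[trace$time_ms < step_start_ms])
  } else trace$v[1]
  tail_win <- trace$time_ms >= step_end_ms - 100 & trace$time_ms <= step_end_ms
  dv <- mean(trace$v[tail_win]) - base
  abs(dv / (step / 1000))  # pA -> nA; mV/nA = MOhm
}

#' Somatic intrinsic measurements of a surrogate model
#'
#' Runs the standard protocols: a -100 pA, 500 ms step for input
#' resistance; a 0-15 Hz chirp for the impedance measures; and 1 s
#' depolarizing steps at 100/150/200/250 pA for the firing-rate curve.
#'
#' @param params A [model_params()].
#' @param dt Integration step (ms).
#' @return List with `R_in`, `Z_max`, `f_R`, `Q`, `Phi_L` and
#'   `rate_100/150/200/250` (Hz).
#' @export
intrinsic_measurements <- function(params = model_params(), dt = 0.1) {
  stepp <- inject_protocol("step", -100, 0.5, dt = dt)
  tr <- simulate_response(params = params, protocol = stepp, dt = dt,
                          spiking = FALSE)
  r_in <- input_resistance(tr, -100, rest = params$E_leak)
  ch <- inject_protocol("chirp", dt = dt)
  trc <- simulate_response(params = params, protocol = ch, dt = dt,
                           spiking = FALSE)
  imp <- impedance_measures(trc$i_inj, trc$v, dt)
  rates <- vapply(c(100, 150, 200, 250), function(a) {
    p <- inject_protocol("step", a, 1, dt = dt)
    trs <- simulate_response(params = params, protocol = p, dt = dt)
    length(trs$spikes_ms)  # spikes per 1 s
  }, numeric(1))
  list(R_in = r_in, Z_max = imp$Z_max, f_R = imp$f_R, Q = imp$Q,
       Phi_L = imp$Phi_L,
       rate_100 = rates[1], rate_150 = rates[2],
       rate_200 = rates[3], rate_250 = rates[4])
}
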