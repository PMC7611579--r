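#' Presynaptic place-field envelope specification
#'
#' Defines the deterministic firing-rate envelope that drives every afferent
#' synapse while the virtual animal traverses a linear arena at constant
#' velocity (so time and position are interchangeable). Two forms are
#' supported: a Gaussian-modulated cosinusoid (symmetric place field with
#' theta modulation) and a horizontally reflected Erlang-modulated cosinusoid
#' (experience-dependent asymmetric field, slow rise and steep fall).
#'
#' @param form `"gaussian"` or `"erlang"`.
#' @param F_pre_max Peak rate scale of the envelope (Hz). The Gaussian form
#'   attains `2 * F_pre_max` at the field center; the Erlang form multiplies
#'   `F_pre_max` by the reflected Erlang density.
#' @param f0 Theta modulation frequency (Hz).
#' @param T_center For the Gaussian form, the field center (s). For the
#'   Erlang form, the reflection point of the density (the envelope is zero
#'   for `t > T_center` and its mode sits at `T_center - (k - 1) / lam`).
#'   Default: 5 s (Gaussian); for the Erlang form the default places the
#'   mode at the window center, i.e. `5 + (k - 1) / lam`.
#' @param sigma Gaussian width (s).
#' @param lam,k Erlang rate (1/s) and integer shape.
#' @param t_start,t_end Traversal window (s).
#' @return An object of class `envelope_spec`.
#' @examples
#' spec <- envelope_spec()
#' envelope_rate(5, spec)  # 2 * F_pre_max at the field center
#' @export
envelope_spec <- function(form = c("gaussian", "erlang"),
                          F_pre_max = 15, f0 = 8, T_center = NULL,
                          sigma = 1, lam = 5, k = 25,
                          t_start = 0, t_end = 10) {
  form <- match.arg(form)
  if (is.null(T_center)) {
    T_center <- if (form == "gaussian") 5 else 5 + (k - 1) / lam
  }
  stopifnot(F_pre_max > 0, f0 > 0, t_start < t_end)
  if (form == "gaussian" && sigma <= 0) {
    stop("sigma must be positive for the gaussian form")
  }
  if (form == "erlang") {
    if (k < 1 || k != round(k)) stop("k must be a positive integer")
    if (lam <= 0) stop("lam must be positive")
  }
  if (!(t_start < T_center && T_center < t_end)) {
    stop("T_center must lie strictly inside [t_start, t_end]")
  }
  structure(list(form = form, F_pre_max = F_pre_max, f0 = f0,
                 T_center = T_center, sigma = sigma, lam = lam, k = k,
                 t_start = t_start, t_end = t_end),
            class = "envelope_spec")
}

#' @export
print.envelope_spec <- function(x, ...) {
  cat(sprintf("<envelope_spec> %s | F_pre_max=%g Hz f0=%g Hz T=%g s window=[%g, %g] s\n",
              x$form, x$F_pre_max, x$f0, x$T_center, x$t_start, x$t_end))
  invisible(x)
}

#' Evaluate a place-field rate envelope
#'
#' Returns the deterministic presynaptic firing rate at times `t`. The
#' Gaussian form is
#' `F_pre_max * (1 + cos(2 pi f0 (t - T))) * exp(-(t - T)^2 / (2 sigma^2))`;
#' the Erlang form replaces the Gaussian factor by the horizontally
#' reflected Erlang density
#' `lam^k (T - t)^(k-1) exp(-lam (T - t)) / (k - 1)!`, which is zero for
#' `t > T` (the reflected support ends at the reflection point).
#'
#' @param t Time (s), vectorised.
#' @param spec An [envelope_spec()].
#' @return Rate (Hz), nonnegative.
#' @export
envelope_rate <- function(t, spec) {
  stopifnot(inherits(spec, "envelope_spec"))
  u <- t - spec$T_center
  theta <- 1 + cos(2 * pi * spec$f0 * u)
  env <- switch(spec$form,
    gaussian = exp(-u^2 / (2 * spec$sigma^2)),
    erlang = {
      e <- numeric(length(t))
      left <- u <= 0
      e[left] <- stats::dgamma(-u[left], shape = spec$k, rate = spec$lam)
      e
    },
    stop("unknown envelope form")
  )
  spec$F_pre_max * theta * env
}

#' Peak value of the envelope factor (excluding the theta cosine)
#'
#' For the Gaussian form this is 1 (at the field center); for the Erlang
#' form it is the reflected Erlang density evaluated at its mode
#' `T - (k - 1) / lam`. Used to match peak drive across envelope forms.
#'
#' @param spec An [envelope_spec()].
#' @return Scalar peak of the envelope factor.
#' @export
envelope_factor_peak <- function(spec) {
  switch(spec$form,
    gaussian = 1,
    erlang = stats::dgamma((spec$k - 1) / spec$lam, shape = spec$k,
                           rate = spec$lam))
}

#' Time-gridded presynaptic rate series
#'
#' One rate trace per synapse on a uniform grid. All synapses share the
#' deterministic envelope; [apply_noise()] later perturbs them
#' independently.
#'
#' @param time Uniform, strictly increasing time grid (s).
#' @param values Numeric matrix, `length(time)` rows, one column per
#'   synapse; all entries nonnegative (Hz).
#' @return Object of class `rate_series` with elements `time`, `values`,
#'   `dt`.
#' @export
rate_series <- function(time, values) {
  values <- as.matrix(values)
  stopifnot(length(time) >= 2, nrow(values) == length(time))
  dts <- diff(time)
  if (any(dts <= 0) || diff(range(dts)) > 1e-9 * dts[1]) {
    stop("time grid must be strictly increasing and uniform")
  }
  if (any(values < 0)) stop("rates must be nonnegative")
  structure(list(time = time, values = values, dt = dts[1]),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %d samples x %d synapses, dt=%g s, max=%.3g Hz\n",
              nrow(x$values), ncol(x$values), x$dt, max(x$values)))
  invisible(x)
}

#' Build the noiseless per-synapse rate series for an envelope
#'
#' @param spec An [envelope_spec()].
#' @param n_synapses Number of afferent synapses (default 80).
#' @param dt Rate-grid step (s); noise is later sampled on this grid.
#' @return A [rate_series()].
#' @export
presyn_rate_series <- function(spec, n_synapses = 80, dt = 1e-3) {
  tt <- seq(spec$t_start, spec$t_end, by = dt)
  base <- envelope_rate(tt, spec)
  rate_series(tt, matrix(base, nrow = length(tt), ncol = n_synapses))
}

#' Trial-to-trial variability specification
#'
#' `sigma_noise` is interpreted as
#' the variance of the perturbation expressed in the units of the quantity
#' it perturbs on the per-millisecond scale. For additive noise the
#' perturbation acts on the rate in ms^-1, so the standard deviation in Hz
#' is `1000 * sqrt(sigma_noise)`; for multiplicative noise the perturbation
#' is a dimensionless gain fluctuation with standard deviation
#' `sqrt(sigma_noise)`. Pink noise is additive noise low-pass filtered to a
#' 1/f-like spectrum and rescaled to the same variance. Set
#' `value_is_std = TRUE` to interpret `sigma_noise` as a standard deviation
#' instead of a variance.
#'
#' @param mode One of `"none"`, `"additive_white"`, `"multiplicative_white"`,
#'   `"additive_pink"`.
#' @param sigma_noise Noise level (variance by default).
#' @param cutoff Pink-noise low-pass cutoff (Hz).
#' @param seed Optional integer; when given, [apply_noise()] seeds the RNG
#'   before drawing so realizations are reproducible.
#' @param value_is_std Interpret `sigma_noise` as a standard deviation.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("none", "additive_white",
                                "multiplicative_white", "additive_pink"),
                       sigma_noise = 0, cutoff = 5, seed = NULL,
                       value_is_std = FALSE) {
  mode <- match.arg(mode)
  if (sigma_noise < 0) stop("sigma_noise must be nonnegative")
  if (mode == "additive_pink" && cutoff <= 0) {
    stop("cutoff must be positive for pink noise")
  }
  structure(list(mode = mode, sigma_noise = sigma_noise, cutoff = cutoff,
                 seed = seed, value_is_std = value_is_std),
            class = "noise_spec")
}

noise_sd <- function(noise) {
  if (noise$value_is_std) noise$sigma_noise else sqrt(noise$sigma_noise)
}

#' Perturb a rate series with trial-to-trial noise
#'
#' Draws an independent realization per synapse (column), applies it
#' additively (`F + xi`, xi in Hz), multiplicatively (`F * (1 + xi)`, xi
#' dimensionless) or as additive pink noise (first-order low-pass filtered
#' white noise rescaled to the requested variance), then rectifies at zero.
#' Noise is sampled on the rate grid and held constant within each step.
#'
#' @param rates A [rate_series()].
#' @param noise A [noise_spec()].
#' @return A rectified [rate_series()].
#' @export
apply_noise <- function(rates, noise) {
  stopifnot(inherits(rates, "rate_series"), inherits(noise, "noise_spec"))
  if (noise$mode == "none" || noise$sigma_noise == 0) return(rates)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  n <- nrow(rates$values)
  m <- ncol(rates$values)
  sdv <- noise_sd(noise)
  v <- switch(noise$mode,
    additive_white = rates$values +
      matrix(stats::rnorm(n * m, sd = 1000 * sdv), n, m),
    multiplicative_white = rates$values *
      (1 + matrix(stats::rnorm(n * m, sd = sdv), n, m)),
    additive_pink = {
      xi <- pink_noise_matrix(n, m, rates$dt, noise$cutoff)
      rates$values + 1000 * sdv * xi
    })
  rates$values <- pmax(v, 0)
  rates
}

# First-order low-pass filtered white noise, each column rescaled to unit
# variance. alpha = exp(-2 pi fc dt) gives a -3 dB-like corner near fc with
# an asymptotic 1/f^2 roll-off; the slope passes through ~ -1 around fc.
pink_noise_matrix <- function(n, m, dt, cutoff) {
  alpha <- exp(-2 * pi * cutoff * dt)
  w <- matrix(stats::rnorm(n * m), n, m)
  y <- apply(w, 2, function(col) stats::filter(col, alpha, method = "recursive"))
  y <- matrix(as.numeric(y), n, m)
  sds <- apply(y, 2, stats::sd)
  sweep(y, 2, sds, "/")
}

#' Sample per-synapse Bernoulli spike trains from a rate series
#'
#' At each sampling step and for each synapse, an independent uniform(0,1)
#' draw emits a presynaptic event iff it is below `dt * rate(t)`. Trials are
#' independent realizations of the same rates.
#'
#' @param rates A [rate_series()].
#' @param n_trials Number of independent trials.
#' @param seed Optional integer RNG seed.
#' @param dt Sampling step (s); defaults to the rate-grid step. A finer `dt`
#'   uses zero-order hold of the rate grid.
#' @return Object of class `spike_train_set`: `spikes[[trial]][[synapse]]`
#'   are event times (s), plus `dt`, `n_synapses`, `n_trials`.
#' @export
sample_spike_trains <- function(rates, n_trials = 1, seed = NULL, dt = NULL) {
  stopifnot(inherits(rates, "rate_series"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt)) dt <- rates$dt
  v <- rates$values
  tt <- rates$time
  if (dt < rates$dt) {  # zero-order hold onto the finer sampling grid
    tt <- seq(rates$time[1], rates$time[length(rates$time)], by = dt)
    idx <- pmin(floor((tt - rates$time[1]) / rates$dt) + 1L, nrow(v))
    v <- v[idx, , drop = FALSE]
  }
  pmax_step <- dt * max(v)
  if (pmax_step >= 1) stop("dt * max(rate) >= 1: per-step probability overflow")
  if (pmax_step >= 0.1) {
    warning("dt * max(rate) >= 0.1; consider a finer sampling step")
  }
  n <- nrow(v); m <- ncol(v)
  p <- dt * v
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    u <- matrix(stats::runif(n * m), n, m)
    hit <- u < p
    trials[[tr]] <- lapply(seq_len(m), function(j) tt[hit[, j]])
  }
  structure(list(spikes = trials, dt = dt, n_synapses = m,
                 n_trials = n_trials,
                 t_start = rates$time[1], t_end = rates$time[length(rates$time)]),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  counts <- vapply(x$spikes, function(tr) sum(lengths(tr)), numeric(1))
  cat(sprintf("<spike_train_set> %d synapses x %d trials, dt=%g s, mean events/trial=%.1f\n",
              x$n_synapses, x$n_trials, x$dt, mean(counts)))
  invisible(x)
}

#' Export one trial of spike trains as two-column delimited text
#'
#' Columns: `synapse_id`, `time_s`.
#'
#' @param sts A [sample_spike_trains()] result.
#' @param path Output file path.
#' @param trial Trial index to export.
#' @export
write_spike_trains <- function(sts, path, trial = 1) {
  stopifnot(inherits(sts, "spike_train_set"), trial <= sts$n_trials)
  tr <- sts$spikes[[trial]]
  df <- data.frame(
    synapse_id = rep(seq_along(tr), lengths(tr)),
    time_s = unlist(tr, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Multi-presynaptic CA3 ensemble specification
#'
#' A bank of presynaptic place cells whose field centers tile the traversal
#' window and whose synaptic weights follow a Gaussian profile peaking for
#' the neuron whose field center is nearest the postsynaptic field center.
#' The weighted sum of their envelopes approximates the single-envelope
#' symmetric field.
#'
#' @param n_pre Number of presynaptic neurons.
#' @param centers Per-neuron field centers (s); default tiles the window.
#' @param weight_sigma Width (s) of the Gaussian weight profile.
#' @param post_center Postsynaptic field center (s).
#' @param t_start,t_end Traversal window (s).
#' @return Object of class `ensemble_spec` including the normalized
#'   weights (max 1).
#' @export
ensemble_spec <- function(n_pre = 15, centers = NULL, weight_sigma = 1.2,
                          post_center = 5, t_start = 0, t_end = 10) {
  stopifnot(n_pre >= 1, weight_sigma > 0)
  if (is.null(centers)) {
    centers <- if (n_pre == 1) post_center else
      seq(t_start + 0.1 * (t_end - t_start),
          t_end - 0.1 * (t_end - t_start), length.out = n_pre)
  }
  stopifnot(length(centers) == n_pre)
  w <- exp(-(centers - post_center)^2 / (2 * weight_sigma^2))
  w <- w / max(w)
  structure(list(n_pre = n_pre, centers = centers,
                 weight_sigma = weight_sigma, post_center = post_center,
                 weights = w, t_start = t_start, t_end = t_end),
            class = "ensemble_spec")
}

#' Per-presynaptic-neuron envelopes and weights for an ensemble
#'
#' @param spec An [ensemble_spec()].
#' @param base The base [envelope_spec()] whose shape each presynaptic
#'   neuron reuses at its own field center.
#' @return A list with one element per presynaptic neuron, each holding
#'   `weight` and `envelope` (an `envelope_spec` recentered at that
#'   neuron's field center).
#' @export
build_ensemble_drive <- function(spec, base) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(base, "envelope_spec"))
  lapply(seq_len(spec$n_pre), function(i) {
    env <- base
    env$T_center <- spec$centers[i]
    env$t_start <- spec$t_start
    env$t_end <- spec$t_end
    list(weight = spec$weights[i], envelope = env)
  })
}
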