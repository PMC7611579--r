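#' Table of biophysical parameters: base values and sampling ranges
#'
#' The 22 passive and active parameters of the place-cell model family,
#' with the published base values and the uniform sampling ranges used by the
#' stochastic population search (0.5-2x of base, except the axial
#' resistivity whose published range is 100-250 Ohm cm).
#'
#' @return A data.frame with columns `name`, `base`, `lo`, `hi`, `unit`.
#' @export
parameter_table <- function() {
  p <- rbind(
    c("R_a",        120,  100,   250,  "Ohm cm"),
    c("Rm_soma",    125,  62.5,  250,  "kOhm cm2"),
    c("Rm_end",     85,   42.5,  170,  "kOhm cm2"),
    c("Rm_hmp",     300,  150,   600,  "um"),
    c("Rm_slope",   50,   25,    100,  "um"),
    c("gNa",        16,   8,     32,   "mS/cm2"),
    c("gKDR",       10,   5,     20,   "mS/cm2"),
    c("gh_soma",    25,   12.5,  50,   "uS/cm2"),
    c("gh_fold",    12,   6,     24,   ""),
    c("gh_hmp",     320,  160,   640,  "um"),
    c("gh_slope",   50,   25,    100,  "um"),
    c("gCaT_soma",  80,   40,    160,  "uS/cm2"),
    c("gCaT_fold",  30,   15,    60,   ""),
    c("gCaT_hmp",   350,  175,   700,  "um"),
    c("gCaT_slope", 50,   25,    100,  "um"),
    c("gKA_soma",   3.1,  1.55,  6.2,  "mS/cm2"),
    c("gKA_fold",   8,    4,     16,   "per 100 um"),
    c("gCaN",       15,   7.5,   30,   "uS/cm2"),
    c("gCaR",       15,   7.5,   30,   "uS/cm2"),
    c("gCaL",       1.20, 0.6,   2.4,  "mS/cm2"),
    c("gSK",        1.5,  0.75,  3,    "uS/cm2"),
    c("gKM",        1,    0.5,   2,    "uS/cm2"))
  data.frame(name = p[, 1], base = as.numeric(p[, 2]),
             lo = as.numeric(p[, 3]), hi = as.numeric(p[, 4]),
             unit = p[, 5], stringsAsFactors = FALSE)
}

#' Model parameter vector for the place-cell surrogate
#'
#' Holds the 22 biophysical parameters (defaulting to their base values)
#' plus the surrogate-specific spiking fields. The surrogate maps each
#' conductance family onto a scalar excitability or adaptation term (see
#' [derive_surrogate()]), so that virtual knockouts of individual channel
#' families are expressible in a single compartment.
#'
#' @param ... Named overrides of the biophysical parameters (see
#'   [parameter_table()] for names).
#' @param E_leak Resting/leak reversal potential (mV).
#' @param threshold Base spike threshold (mV).
#' @param reset Post-spike reset potential (mV).
#' @param refractory Absolute refractory period (ms).
#' @param dnaf_scale Dendritic fast-sodium analogue strength in \[0, 1\];
#'   set to 0 by the dendritic-NaF virtual knockout.
#' @return Object of class `model_params`.
#' @export
model_params <- function(..., E_leak = -65, threshold = -50, reset = -60,
                         refractory = 2, dnaf_scale = 1) {
  tab <- parameter_table()
  vals <- as.list(stats::setNames(tab$base, tab$name))
  dots <- list(...)
  bad <- setdiff(names(dots), tab$name)
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  vals[names(dots)] <- dots
  if (any(unlist(vals) < 0)) stop("conductances/parameters must be >= 0")
  structure(c(vals, list(E_leak = E_leak, threshold = threshold,
                         reset = reset, refractory = refractory,
                         dnaf_scale = dnaf_scale)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  tab <- parameter_table()
  ratio <- unlist(x[tab$name]) / tab$base
  cat(sprintf("<model_params> %d biophysical parameters; mean ratio to base %.2f\n",
              nrow(tab), mean(ratio)))
  invisible(x)
}

#' Somatodendritic distribution profiles
#'
#' Local values of the spatially non-uniform mechanisms as functions of
#' radial distance from the soma: sigmoidally decreasing membrane
#' resistivity, linearly increasing A-type potassium density, and
#' sigmoidally increasing HCN (h) and T-type calcium densities.
#'
#' @param x Radial distance from the soma (um), vectorised, `x >= 0`.
#' @param which One of `"Rm"`, `"KA"`, `"h"`, `"CaT"`.
#' @param params A [model_params()].
#' @return Local value in the parameter's own units (kOhm cm2 for Rm,
#'   mS/cm2 for KA, uS/cm2 for h and CaT).
#' @export
distribution_profile <- function(x, which = c("Rm", "KA", "h", "CaT"),
                                 params = model_params()) {
  which <- match.arg(which)
  stopifnot(all(x >= 0))
  switch(which,
    Rm = params$Rm_soma + (params$Rm_end - params$Rm_soma) /
      (1 + exp((params$Rm_hmp - x) / params$Rm_slope)),
    KA = params$gKA_soma * (1 + params$gKA_fold * x / 100),
    h  = params$gh_soma * (1 + params$gh_fold /
      (1 + exp((params$gh_hmp - x) / params$gh_slope))),
    CaT = params$gCaT_soma * (1 + params$gCaT_fold /
      (1 + exp((params$gCaT_hmp - x) / params$gCaT_slope))))
}

# Fixed surrogate coupling constants (calibrated once so the base
# parameter vector lands mid-range of the somatic validation bounds).
surrogate_constants <- function() {
  list(
    span_um = 350,        # somatodendritic span averaged over
    kR = 0.936,           # MOhm per sqrt(kOhm cm2 * Ohm cm): leak resistance
    kh = 7.91e-5,         # uS per (uS/cm2): resonant (h-like) conductance
    tau_w = 60,           # ms, slow feedback time constant
    C_nF = 0.30,          # membrane capacitance
    kKA = 3,              # mV threshold shift per unit KA ratio change
    kNa = 2,              # mV threshold shift per unit dendritic-NaF ratio
    kKDR = 1.5,           # mV reset deepening per unit KDR ratio change
    b0 = 0.012,           # nA adaptation increment per spike at base
    tau_adapt = 120,      # ms adaptation decay
    w_ca = c(CaT = 0.4, CaN = 0.2, CaR = 0.2, CaL = 0.2),
    sk_share = 0.55, km_share = 0.45)
}

# Spatial mean of a distribution profile over the somatodendritic span.
profile_mean <- function(params, which, span = surrogate_constants()$span_um) {
  xs <- seq(0, span, by = 5)
  mean(distribution_profile(xs, which, params))
}

#' Effective surrogate quantities implied by a parameter vector
#'
#' Maps the 22 biophysical parameters onto the scalar quantities the
#' single-compartment surrogate integrates: leak conductance (from the
#' spatially averaged membrane resistivity and the axial resistivity),
#' resonant conductance (from the averaged h-channel density), spike
#' threshold (raised by A-type potassium, lowered by the dendritic-NaF
#' analogue), reset depth (KDR), and spike-triggered adaptation (KM plus
#' SK coupled to the calcium-channel densities). These couplings are
#' surrogate-specific design constants, not measured biophysics.
#'
#' @param params A [model_params()].
#' @return List with `gL`, `gw` (uS), `tau_w`, `C` (nF), `EL`, `theta`,
#'   `reset`, `refrac` (ms), `b_adapt` (nA), `tau_adapt` (ms), `v0`.
#' @export
derive_surrogate <- function(params = model_params()) {
  k <- surrogate_constants()
  base <- model_params()
  rm_eff <- profile_mean(params, "Rm")
  h_eff <- profile_mean(params, "h")
  ka_eff <- profile_mean(params, "KA")
  ka_base <- profile_mean(base, "KA")
  cat_eff <- profile_mean(params, "CaT")
  cat_base <- profile_mean(base, "CaT")

  gL <- 1 / (k$kR * sqrt(rm_eff * params$R_a))
  gw <- k$kh * h_eff
  dnaf_ratio <- params$dnaf_scale * params$gNa / base$gNa
  theta <- params$threshold + k$kKA * (ka_eff / ka_base - 1) -
    k$kNa * (dnaf_ratio - 1)
  reset <- params$reset - k$kKDR * (params$gKDR / base$gKDR - 1)
  ca_ratio <- sum(k$w_ca * c(cat_eff / cat_base, params$gCaN / base$gCaN,
                             params$gCaR / base$gCaR, params$gCaL / base$gCaL))
  b_adapt <- k$b0 * (k$sk_share * (params$gSK / base$gSK) * ca_ratio +
                     k$km_share * (params$gKM / base$gKM))
  list(gL = gL, gw = gw, tau_w = k$tau_w, C = k$C_nF, EL = params$E_leak,
       theta = theta, reset = reset, refrac = params$refractory,
       b_adapt = b_adapt, tau_adapt = k$tau_adapt, v0 = params$E_leak)
}

syn_pack <- function(P_ampa, P_nmda, env = ion_environment(),
                     ampa = default_ampar(), nmda = default_nmdar()) {
  perm3 <- function(rp) {
    out <- c(Na = 0, K = 0, Ca = 0)
    out[names(rp)] <- rp
    out
  }
  list(p_ampa = P_ampa, p_nmda = P_nmda,
       tau_r_a = ampa$tau_r, tau_d_a = ampa$tau_d,
       tau_r_n = nmda$tau_r, tau_d_n = nmda$tau_d,
       norm_a = ampa$norm, norm_n = nmda$norm,
       z = unname(ion_valence[c("Na", "K", "Ca")]),
       ci = vapply(c("Na", "K", "Ca"), function(i) env$conc[[i]][["inside"]], 0),
       co = vapply(c("Na", "K", "Ca"), function(i) env$conc[[i]][["outside"]], 0),
       perm_a = unname(perm3(ampa$rel_perm)),
       perm_n = unname(perm3(nmda$rel_perm)),
       rtf = env$rtf_mV, F_const = env$F_const, mg_out = env$Mg_out)
}

#' Current-injection protocols
#'
#' `step`: constant current of the given amplitude for `duration`.
#' `chirp`: constant-amplitude cosine whose instantaneous frequency rises
#' linearly from 0 to 15 Hz over 15 s (peak-to-peak 100 pA by default).
#'
#' @param kind `"step"` or `"chirp"`.
#' @param amplitude Amplitude in pA (step level, or chirp half peak-to-peak).
#' @param duration Seconds.
#' @param dt Integration step (ms).
#' @param f_max Chirp end frequency (Hz).
#' @return List with `time_ms`, `i_nA`, `dt`, `kind`.
#' @export
inject_protocol <- function(kind = c("step", "chirp"),
                            amplitude = NULL, duration = NULL,
                            dt = 0.1, f_max = 15) {
  kind <- match.arg(kind)
  if (is.null(amplitude)) amplitude <- if (kind == "step") -100 else 50
  if (is.null(duration)) duration <- if (kind == "step") 0.5 else 15
  stopifnot(duration > 0)
  tt <- seq(0, duration * 1000, by = dt)
  i <- switch(kind,
    step = rep(amplitude / 1000, length(tt)),
    chirp = {
      ts <- tt / 1000
      (amplitude / 1000) * cos(pi * f_max / duration * ts^2)
    })
  list(time_ms = tt, i_nA = i, dt = dt, kind = kind)
}

#' Simulate the surrogate's voltage response
#'
#' Integrates `C dV/dt = -gL (V - E_leak) - gw w - I_adapt - I_syn + I_inj`
#' with a slow resonant variable `tau_w dw/dt = (V - E_leak) - w`,
#' threshold-reset spiking with refractory period and spike-triggered
#' adaptation, and GHK AMPAR/NMDAR synaptic currents driven by presynaptic
#' events. With no drive the trace rests at `E_leak` (-65 mV). A
#' stereotyped 1 ms spike waveform is pasted into the returned trace for
#' downstream threshold-based spike detection. Deterministic given the
#' drive.
#'
#' @param drive `NULL` (current protocols only), a `spike_train_set`
#'   (one trial is used), or a list with `events_ms` and `weights` giving
#'   aggregated presynaptic event times and weights.
#' @param params A [model_params()].
#' @param dt Integration step (ms); default 0.1, use 0.025 to match the
#'   reference integration step.
#' @param duration Seconds; defaults to the protocol/drive span.
#' @param protocol Output of [inject_protocol()], a numeric vector of
#'   injected current (nA) per step, or `NULL`.
#' @param P_ampa,P_nmda Synaptic permeability scales (see
#'   [calibrate_unitary_epsp()]); `0` disables the receptor.
#' @param spiking Enable threshold-reset spiking.
#' @param trial Trial of a `spike_train_set` to use.
#' @return Object of class `voltage_trace`: `time_ms`, `v` (mV), `i_inj`
#'   (nA), `spikes_ms`, `dt`.
#' @export
simulate_response <- function(drive = NULL, params = model_params(),
                              dt = 0.1, duration = NULL, protocol = NULL,
                              P_ampa = 0, P_nmda = 0, spiking = TRUE,
                              trial = 1) {
  memb <- derive_surrogate(params)
  ev_time <- numeric(0); ev_weight <- numeric(0)
  if (inherits(drive, "spike_train_set")) {
    tr <- drive$spikes[[trial]]
    ev_time <- unlist(tr, use.names = FALSE) * 1000
    ev_weight <- rep(1, length(ev_time))
    o <- order(ev_time)
    ev_time <- ev_time[o]; ev_weight <- ev_weight[o]
    if (is.null(duration)) duration <- drive$t_end - drive$t_start
  } else if (is.list(drive) && !is.null(drive$events_ms)) {
    o <- order(drive$events_ms)
    ev_time <- drive$events_ms[o]
    w <- if (is.null(drive$weights)) rep(1, length(ev_time)) else drive$weights
    ev_weight <- rep_len(w, length(ev_time))[o]
  } else if (!is.null(drive)) {
    stop("unsupported drive type")
  }
  if (is.list(protocol) && !is.null(protocol$i_nA)) {
    if (abs(protocol$dt - dt) > 1e-12) {
      stop("protocol dt must match the integration dt")
    }
    i_inj <- protocol$i_nA
    if (is.null(duration)) duration <- length(i_inj) * dt / 1000
  } else if (is.numeric(protocol)) {
    i_inj <- protocol
    if (is.null(duration)) duration <- length(i_inj) * dt / 1000
  } else {
    i_inj <- 0
  }
  if (is.null(duration)) stop("duration must be given when it cannot be inferred")
  n_steps <- max(length(i_inj), round(duration * 1000 / dt))
  if (length(i_inj) > 1 && length(i_inj) < n_steps) {
    i_inj <- c(i_inj, rep(0, n_steps - length(i_inj)))
  }
  res <- sim_core(n_steps, dt, as.numeric(i_inj),
                  matrix(0, 0, 0), 1, numeric(0), integer(0),
                  ev_time, ev_weight,
                  syn_pack(P_ampa, P_nmda), memb,
                  spiking, TRUE, FALSE)
  structure(list(time_ms = seq(0, by = dt, length.out = n_steps),
                 v = res$v,
                 i_inj = if (length(i_inj) == 1) rep(i_inj, n_steps) else i_inj,
                 spikes_ms = res$spikes_ms, dt = dt),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %.3f s at dt=%g ms, V in [%.1f, %.1f] mV, %d spikes\n",
              length(x$v) * x$dt / 1000, x$dt, min(x$v), max(x$v),
              length(x$spikes_ms)))
  invisible(x)
}

#' Simulate one place-field traversal with in-loop spike sampling
#'
#' Drives the surrogate with per-synapse Bernoulli presynaptic events
#' sampled at every integration step from a zero-order-held rate grid
#' (one column per synapse or per presynaptic neuron). This is the
#' workhorse used by the population sweeps; randomness goes through R's
#' RNG so runs are reproducible with `set.seed()`.
#'
#' @param rates A [rate_series()] (Hz; typically the noise-perturbed
#'   per-synapse rates for one trial).
#' @param params A [model_params()].
#' @param P_ampa,P_nmda Synaptic permeability scales.
#' @param weights Per-column synaptic weight (ensemble scaling), recycled.
#' @param syn_per_col Number of independent synapses represented by each
#'   rate column (e.g. 80 synapses per presynaptic neuron in the ensemble
#'   configuration).
#' @param dt Integration step (ms).
#' @param return_trace Also return the voltage trace.
#' @return List with `spikes_ms`, `n_presyn_events`, and optionally `v`
#'   and `time_ms`.
#' @export
simulate_traversal <- function(rates, params = model_params(),
                               P_ampa, P_nmda, weights = 1,
                               syn_per_col = 1, dt = 0.1,
                               return_trace = FALSE) {
  stopifnot(inherits(rates, "rate_series"))
  memb <- derive_surrogate(params)
  n_cols <- ncol(rates$values)
  weights <- rep_len(weights, n_cols)
  mult <- rep_len(as.integer(syn_per_col), n_cols)
  dur_ms <- (rates$time[length(rates$time)] - rates$time[1]) * 1000
  n_steps <- round(dur_ms / dt)
  res <- sim_core(n_steps, dt, 0,
                  rates$values / 1000, rates$dt * 1000, weights, mult,
                  numeric(0), numeric(0),
                  syn_pack(P_ampa, P_nmda), memb,
                  TRUE, return_trace, TRUE)
  out <- list(spikes_ms = res$spikes_ms, n_presyn_events = res$n_presyn_events)
  if (return_trace) {
    out$v <- res$v
    out$time_ms <- seq(0, by = dt, length.out = n_steps)
  }
  out
}
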