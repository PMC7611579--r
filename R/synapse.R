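#' Ionic environment for GHK synaptic currents
#'
#' Intra/extracellular concentrations (mM), extracellular magnesium and the
#' thermodynamic temperature used by the Goldman-Hodgkin-Katz flux
#' expressions. The temperature stored here is the physical temperature in
#' kelvin (34 degrees C by default), not the place-field center.
#'
#' @param Na_in,Na_out,K_in,K_out,Ca_in,Ca_out Ion concentrations (mM).
#' @param Mg_out Extracellular magnesium (mM).
#' @param temperature Kelvin.
#' @return Object of class `ion_environment`, with Faraday constant `F_const`
#'   (C/mol), gas constant `R_const` (J/mol/K) and the thermal voltage
#'   `rtf_mV = 1000 * R T / F`.
#' @export
ion_environment <- function(Na_in = 18, Na_out = 140,
                            K_in = 140, K_out = 5,
                            Ca_in = 1e-4, Ca_out = 2,
                            Mg_out = 2, temperature = 307.15) {
  conc <- c(Na_in, Na_out, K_in, K_out, Ca_in, Ca_out, Mg_out)
  if (any(conc <= 0)) stop("all concentrations must be positive")
  F_const <- 96485.33212
  R_const <- 8.31446262
  structure(list(
    conc = list(Na = c(inside = Na_in, outside = Na_out),
                K  = c(inside = K_in,  outside = K_out),
                Ca = c(inside = Ca_in, outside = Ca_out)),
    Mg_out = Mg_out, temperature = temperature,
    F_const = F_const, R_const = R_const,
    rtf_mV = 1000 * R_const * temperature / F_const),
    class = "ion_environment")
}

ion_valence <- c(Na = 1, K = 1, Ca = 2)

#' Receptor parameter set
#'
#' Double-exponential kinetics with a normalization constant so that each
#' event's open fraction peaks at 1, plus per-ion relative permeabilities
#' and (for NMDARs) the voltage-dependent magnesium block.
#'
#' @param P_max Maximum permeability scale (maps GHK flux to current in nA
#'   for the single-compartment surrogate; set by [calibrate_unitary_epsp()]).
#' @param rel_perm Named relative permeabilities, e.g.
#'   `c(Na = 1, K = 1, Ca = 10.6)`.
#' @param tau_r,tau_d Rise and decay time constants (ms), `tau_d > tau_r`.
#' @param has_mg_block Apply the magnesium block (NMDAR).
#' @return Object of class `receptor_params`.
#' @export
receptor_params <- function(P_max = 1, rel_perm = c(Na = 1, K = 1),
                            tau_r = 2, tau_d = 10, has_mg_block = FALSE) {
  if (tau_d <= tau_r || tau_r <= 0) stop("need tau_d > tau_r > 0")
  if (P_max < 0) stop("P_max must be nonnegative")
  bad <- setdiff(names(rel_perm), names(ion_valence))
  if (length(bad)) stop("unknown ions: ", paste(bad, collapse = ", "))
  structure(list(P_max = P_max, rel_perm = rel_perm,
                 tau_r = tau_r, tau_d = tau_d,
                 has_mg_block = has_mg_block,
                 norm = kinetics_norm(tau_r, tau_d)),
            class = "receptor_params")
}

#' @rdname receptor_params
#' @export
default_ampar <- function(P_max = 1) {
  receptor_params(P_max = P_max, rel_perm = c(Na = 1, K = 1),
                  tau_r = 2, tau_d = 10, has_mg_block = FALSE)
}

#' @rdname receptor_params
#' @export
default_nmdar <- function(P_max = 1.5) {
  receptor_params(P_max = P_max, rel_perm = c(Na = 1, K = 1, Ca = 10.6),
                  tau_r = 5, tau_d = 50, has_mg_block = TRUE)
}

kinetics_norm <- function(tau_r, tau_d) {
  tp <- kinetics_peak_time(tau_r, tau_d)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

#' Time of peak of the double-exponential kinetic scheme
#'
#' `t* = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)` (ms).
#'
#' @param tau_r,tau_d Rise and decay time constants (ms).
#' @export
kinetics_peak_time <- function(tau_r, tau_d) {
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Normalized receptor open fraction after a presynaptic event
#'
#' `s(t) = a (exp(-t/tau_d) - exp(-t/tau_r))`, with `a` chosen so the peak
#' is exactly 1; `s(0) = 0`. Multiple events superpose linearly.
#'
#' @param t Milliseconds since the presynaptic event (vectorised, `t >= 0`).
#' @param params A [receptor_params()].
#' @return Open fraction in \[0, 1\] per event.
#' @export
receptor_kinetics <- function(t, params) {
  stopifnot(inherits(params, "receptor_params"), all(t >= 0))
  params$norm * (exp(-t / params$tau_d) - exp(-t / params$tau_r))
}

#' Voltage-dependent magnesium block of the NMDAR
#'
#' `MgB(v) = 1 / (1 + [Mg]_o exp(-0.062 v) / 3.57)`, strictly increasing in
#' `v` and confined to (0, 1).
#'
#' @param v Membrane potential (mV), vectorised.
#' @param env An [ion_environment()].
#' @export
mg_block <- function(v, env = ion_environment()) {
  1 / (1 + env$Mg_out * exp(-0.062 * v) / 3.57)
}

#' Goldman-Hodgkin-Katz flux per unit permeability
#'
#' Evaluates `z^2 v F^2 / (R T) * ([X]_i - [X]_o exp(-z v F / R T)) /
#' (1 - exp(-z v F / R T))` with `v` in volts internally. The removable
#' singularity at `v = 0` is handled by a series expansion of
#' `u / (1 - exp(-u))` for small `u = z v F / (R T)`; at `v = 0` the flux is
#' `z F ([X]_i - [X]_o)`. The flux is zero exactly at the ion's Nernst
#' potential and positive (outward) above it.
#'
#' @param v Membrane potential (mV), vectorised.
#' @param ion `"Na"`, `"K"` or `"Ca"`.
#' @param env An [ion_environment()].
#' @return Flux per unit permeability (current once multiplied by `P_max *
#'   rel_perm`).
#' @export
ghk_flux <- function(v, ion = c("Na", "K", "Ca"), env = ion_environment()) {
  ion <- match.arg(ion)
  z <- ion_valence[[ion]]
  ci <- env$conc[[ion]][["inside"]]
  co <- env$conc[[ion]][["outside"]]
  u <- z * v / env$rtf_mV
  emu <- exp(-u)
  num <- ci - co * emu
  out <- numeric(length(v))
  small <- abs(u) < 1e-4
  # u / (1 - exp(-u)) = 1 + u/2 + u^2/12 + O(u^4)
  out[small] <- z * env$F_const *
    (1 + u[small] / 2 + u[small]^2 / 12) * num[small]
  out[!small] <- z * env$F_const * u[!small] * num[!small] / (1 - emu[!small])
  out
}

#' Nernst (reversal) potential of an ion
#'
#' @param ion `"Na"`, `"K"` or `"Ca"`.
#' @param env An [ion_environment()].
#' @return Potential (mV) at which the GHK flux crosses zero.
#' @export
nernst_potential <- function(ion = c("Na", "K", "Ca"), env = ion_environment()) {
  ion <- match.arg(ion)
  z <- ion_valence[[ion]]
  ci <- env$conc[[ion]][["inside"]]
  co <- env$conc[[ion]][["outside"]]
  env$rtf_mV / z * log(co / ci)
}

#' Total synaptic current through colocalized AMPARs and NMDARs
#'
#' Sums the per-ion GHK fluxes weighted by each receptor's permeabilities
#' and kinetic state; the NMDAR component is additionally scaled by the
#' magnesium block. The GHK sign convention is kept: inward (depolarizing)
#' current is negative, and the surrogate integrates `-I_syn` so synaptic
#' activation depolarizes.
#'
#' @param v Membrane potential (mV).
#' @param s_ampa,s_nmda Kinetic states (sums of normalized per-event
#'   double-exponentials).
#' @param ampa,nmda [receptor_params()] for the two receptors.
#' @param env An [ion_environment()].
#' @return Current (nA, GHK sign convention).
#' @export
synaptic_current <- function(v, s_ampa, s_nmda,
                             ampa = default_ampar(), nmda = default_nmdar(),
                             env = ion_environment()) {
  i_a <- 0
  for (ion in names(ampa$rel_perm)) {
    i_a <- i_a + ampa$rel_perm[[ion]] * ghk_flux(v, ion, env)
  }
  i_n <- 0
  for (ion in names(nmda$rel_perm)) {
    i_n <- i_n + nmda$rel_perm[[ion]] * ghk_flux(v, ion, env)
  }
  blk <- if (nmda$has_mg_block) mg_block(v, env) else 1
  ampa$P_max * s_ampa * i_a + nmda$P_max * s_nmda * blk * i_n
}

#' Calibrate the unitary somatic EPSP to ~0.2 mV
#'
#' Tunes the AMPAR permeability scale of a single synapse so that one
#' presynaptic event produces a peak somatic depolarization of 0.2 mV in
#' the resting surrogate, mirroring the synaptic-democracy normalization of
#' unitary responses. The NMDAR scale is then set by the NMDAR-to-AMPAR
#' ratio (default 1.5). Because the response is nearly linear in `P_max`
#' near rest, one simulate-and-rescale pass followed by a verification run
#' suffices.
#'
#' @param params Surrogate [model_params()].
#' @param target Peak unitary EPSP (mV).
#' @param ratio NMDAR-to-AMPAR permeability ratio.
#' @param dt Integration step (ms).
#' @return List with `P_ampa`, `P_nmda` and the achieved `epsp_mV`.
#' @export
calibrate_unitary_epsp <- function(params = model_params(), target = 0.2,
                                   ratio = 1.5, dt = 0.025) {
  p0 <- 1e-9
  peak <- unitary_epsp_peak(params, p0, ratio, dt)
  p1 <- p0 * target / peak
  achieved <- unitary_epsp_peak(params, p1, ratio, dt)
  # one secant refinement for the mild NMDAR nonlinearity
  p2 <- p1 * target / achieved
  achieved2 <- unitary_epsp_peak(params, p2, ratio, dt)
  list(P_ampa = p2, P_nmda = ratio * p2, epsp_mV = achieved2)
}

unitary_epsp_peak <- function(params, P_ampa, ratio, dt) {
  tr <- simulate_response(
    drive = list(events_ms = 20, weights = 1),
    params = params, dt = dt, duration = 0.25,
    P_ampa = P_ampa, P_nmda = ratio * P_ampa, spiking = FALSE)
  max(tr$v) - params$E_leak
}
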