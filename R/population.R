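#' Default drive and sweep settings
#'
#' The study conditions used throughout: theta-modulated envelopes on a
#' 10 s traversal, 80 afferent synapses, 30 trials, and the three standard
#' levels of additive and multiplicative noise. `F_pre_max` is the
#' calibrated default peak input rate: it is not an experimentally
#' reported number, and is set so the base surrogate's noiseless field
#' clears the 56 Hz tuning-sharpness gate with margin.
#'
#' @return Named list of defaults.
#' @export
drive_defaults <- function() {
  list(F_pre_max = 60, n_synapses = 80, dt_rate = 1e-3,
       agwn_levels = c(5e-4, 1e-3, 5e-3),
       mgwn_levels = c(0.01, 0.1, 0.5),
       n_trials = 30, dt_sim = 0.1, dt_grid = 0.01,
       sigma_kernel = 0.2)
}

#' Default envelope for a given form
#'
#' The Gaussian form uses the standard field (center 5 s, width 1 s,
#' theta at 8 Hz). The Erlang form matches the Gaussian's peak drive by
#' scaling `F_pre_max` with the reciprocal of the Erlang density's modal
#' value, and places the density's mode at the window center so the
#' asymmetric field (slow rise, steep fall) is fully contained in the
#' traversal.
#'
#' @param form `"gaussian"` or `"erlang"`.
#' @param F_pre_max Peak-rate scale before the Erlang peak matching;
#'   defaults to `drive_defaults()$F_pre_max`.
#' @return An [envelope_spec()].
#' @export
default_envelope <- function(form = c("gaussian", "erlang"),
                             F_pre_max = NULL) {
  form <- match.arg(form)
  if (is.null(F_pre_max)) F_pre_max <- drive_defaults()$F_pre_max
  if (form == "gaussian") {
    envelope_spec("gaussian", F_pre_max = F_pre_max)
  } else {
    sp <- envelope_spec("erlang", F_pre_max = F_pre_max)
    sp$F_pre_max <- F_pre_max / envelope_factor_peak(sp)
    sp
  }
}

#' Electrophysiological validation bounds (somatic subset)
#'
#' Somatic bounds on input resistance, impedance measures, step-evoked
#' firing rates and place-field tuning sharpness. Dendritic and
#' backpropagating-AP bounds are structurally unavailable in a
#' single-compartment surrogate and are not part of this subset.
#'
#' @return Data.frame with `measurement`, `lower`, `upper`.
#' @export
validation_bounds <- function() {
  b <- rbind(
    c("R_in",     40,   100),
    c("Z_max",    50,   110),
    c("f_R",      2,    7),
    c("Q",        1.01, 1.5),
    c("Phi_L",    0,    0.3),
    c("rate_100", 0,    20),
    c("rate_150", 0,    30),
    c("rate_200", 0,    40),
    c("rate_250", 5,    45),
    c("F_max",    56,   Inf),
    c("FWHM",     0,    2.5))
  data.frame(measurement = b[, 1], lower = as.numeric(b[, 2]),
             upper = as.numeric(b[, 3]), stringsAsFactors = FALSE)
}

#' Sample a heterogeneous model population
#'
#' Draws each biophysical parameter independently and uniformly from its
#' published sampling range (the stochastic-search strategy: unbiased
#' sampling followed by measurement-based validation).
#'
#' @param n_models Number of parameter vectors.
#' @param seed RNG seed.
#' @return List of [model_params()].
#' @export
sample_parameters <- function(n_models, seed = NULL) {
  stopifnot(n_models >= 1)
  if (!is.null(seed)) set.seed(seed)
  tab <- parameter_table()
  lapply(seq_len(n_models), function(i) {
    vals <- stats::runif(nrow(tab), tab$lo, tab$hi)
    do.call(model_params, as.list(stats::setNames(vals, tab$name)))
  })
}

# deterministic per-trial seed below 2^31
trial_seed <- function(master, model_id, cond_id, trial) {
  as.integer((as.numeric(master %% 1000003L) * 1009 +
              model_id * 100003 + cond_id * 1013 + trial * 7) %%
             2147483629) + 1L
}

# Simulate n_trials traversals of one model under one drive condition.
# Returns the rate_profile_set plus per-trial spike times.
traversal_trials <- function(params, P_ampa, P_nmda, envelope, noise,
                             n_trials, seed, model_id = 1L, cond_id = 1L,
                             dt = 0.1, n_synapses = 80, dt_rate = 1e-3,
                             dt_grid = 0.01, sigma_kernel = 0.2) {
  base <- presyn_rate_series(envelope, n_synapses, dt_rate)
  spikes <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(trial_seed(seed, model_id, cond_id, tr))
    noisy <- apply_noise(base, noise)
    sim <- simulate_traversal(noisy, params, P_ampa, P_nmda, dt = dt)
    spikes[[tr]] <- sim$spikes_ms / 1000 + envelope$t_start
  }
  rp <- rate_profiles_from_spikes(spikes, envelope$t_start, envelope$t_end,
                                  dt_grid, sigma_kernel)
  list(rates = rp, spikes = spikes)
}

# Depolarization-block style failure: zero spikes in at least half of the
# in-field segments in at least half of the trials.
field_block_flag <- function(spikes, envelope) {
  tt <- seq(envelope$t_start, envelope$t_end, by = 0.01)
  env <- envelope_rate(tt, envelope)
  infield <- range(tt[env >= max(env) / 2])
  seg <- seq(infield[1], infield[2], length.out = 9)
  bad_trials <- vapply(spikes, function(s) {
    zero <- vapply(seq_len(8), function(i) {
      !any(s >= seg[i] & s < seg[i + 1])
    }, logical(1))
    mean(zero) >= 0.5
  }, logical(1))
  mean(bad_trials) >= 0.5
}

#' Validate one model against the electrophysiological bounds
#'
#' Calibrates the unitary EPSP, runs the step/chirp/place-field
#' protocols, and compares every measurement against
#' [validation_bounds()]. A model is valid iff all measurements pass.
#'
#' @param params A [model_params()].
#' @param bounds Bounds table.
#' @param envelope Noiseless drive used for the tuning-sharpness check.
#' @param n_field_trials Traversal trials averaged for `F_max`/`FWHM`.
#' @param seed RNG seed for the traversal spike sampling.
#' @param dt Integration step (ms).
#' @return List with `measurements`, `valid`, `failed`, `P_ampa`,
#'   `P_nmda`.
#' @export
validate_model <- function(params, bounds = validation_bounds(),
                           envelope = default_envelope("gaussian"),
                           n_field_trials = 3, seed = 1, dt = 0.1) {
  cal <- tryCatch(calibrate_unitary_epsp(params, dt = dt),
                  error = function(e) NULL)
  if (is.null(cal)) {
    return(list(measurements = NULL, valid = FALSE,
                failed = "calibration failure", P_ampa = NA, P_nmda = NA))
  }
  meas <- tryCatch({
    im <- intrinsic_measurements(params, dt = dt)
    tv <- traversal_trials(params, cal$P_ampa, cal$P_nmda, envelope,
                           noise_spec("none"), n_field_trials, seed,
                           dt = dt)
    pf <- place_field_metrics(tv$rates)
    c(im, list(F_max = pf$F_max,
               FWHM = if (is.na(pf$FWHM)) Inf else pf$FWHM))
  }, error = function(e) NULL)
  if (is.null(meas)) {
    return(list(measurements = NULL, valid = FALSE,
                failed = "simulation failure", P_ampa = cal$P_ampa,
                P_nmda = cal$P_nmda))
  }
  failed <- character(0)
  for (i in seq_len(nrow(bounds))) {
    v <- meas[[bounds$measurement[i]]]
    if (is.na(v) || v < bounds$lower[i] || v > bounds$upper[i]) {
      failed <- c(failed, bounds$measurement[i])
    }
  }
  list(measurements = meas, valid = length(failed) == 0, failed = failed,
       P_ampa = cal$P_ampa, P_nmda = cal$P_nmda)
}

#' Build a validated fixture ensemble
#'
#' Samples parameter vectors and validates them until `n` valid models
#' are found (the desk-scale analogue of the stochastic-search
#' population).
#'
#' @param n Number of valid models wanted.
#' @param seed Master RNG seed.
#' @param max_candidates Sampling budget.
#' @param dt Integration step (ms).
#' @param verbose Print progress.
#' @return List of validated entries: `params`, `P_ampa`, `P_nmda`,
#'   `measurements`, `model_id`.
#' @export
fixture_ensemble <- function(n = 20, seed = 1, max_candidates = 60 * n,
                             dt = 0.1, verbose = FALSE) {
  cand <- sample_parameters(max_candidates, seed = seed)
  out <- list()
  for (i in seq_along(cand)) {
    v <- validate_model(cand[[i]], seed = seed + i, dt = dt)
    if (v$valid) {
      out[[length(out) + 1]] <- list(params = cand[[i]], P_ampa = v$P_ampa,
                                     P_nmda = v$P_nmda,
                                     measurements = v$measurements,
                                     model_id = length(out) + 1L)
      if (verbose) message(sprintf("valid model %d/%d after %d candidates",
                                   length(out), n, i))
      if (length(out) == n) return(out)
    }
  }
  stop(sprintf("only %d of %d requested models validated within %d candidates",
               length(out), n, max_candidates))
}

condition_metrics <- function(rp, cfg) {
  ssi <- ssi_profile(rp, cfg)
  mi <- mi_profile(rp, cfg)
  pm_s <- profile_metrics(ssi, rp)
  pm_m <- profile_metrics(mi, rp)
  pf <- place_field_metrics(rp)
  data.frame(
    SSI1 = pm_s$peak1, SSI2 = pm_s$peak2, SSI_FWHM = pm_s$fwhm,
    SSI_dRatio = pm_s$d_ratio, SSI_dip = pm_s$dip, SSI_d = pm_s$d,
    ssi_peak_over_slope = pm_s$peak_over_slope,
    ssi_unimodal = pm_s$unimodal,
    MI1 = pm_m$peak1, MI2 = pm_m$peak2, MI_FWHM = pm_m$fwhm,
    MI_dRatio = pm_m$d_ratio, MI_dip = pm_m$dip, MI_d = pm_m$d,
    mi_peak_over_slope = pm_m$peak_over_slope,
    mi_unimodal = pm_m$unimodal,
    F_max = pf$F_max, FWHM = as.numeric(pf$FWHM))
}

#' Run a trial-to-trial variability sweep over a model ensemble
#'
#' For every model and every (noise mode, level) condition, simulates
#' `n_trials` traversals, estimates the rate profiles, and computes the
#' bias-corrected SSI and MI profiles with their scalar metrics plus the
#' place-field measurements. Fully seeded: identical arguments give an
#' identical result table.
#'
#' @param models Validated entries from [fixture_ensemble()].
#' @param noise_grid Data.frame with columns `mode` and `sigma` (one row
#'   per condition); defaults to the three additive white-noise levels.
#' @param envelope Drive envelope.
#' @param n_trials Trials per condition.
#' @param seed Master seed.
#' @param dt Integration step (ms).
#' @param cfg A [binning_config()].
#' @param cond_offset Condition-id offset (keeps seeds distinct across
#'   sweeps in a larger experiment).
#' @return Long-format data.frame, one row per (model, condition),
#'   including a depolarization-block flag.
#' @export
run_variability_sweep <- function(models,
                                  noise_grid = data.frame(
                                    mode = "additive_white",
                                    sigma = drive_defaults()$agwn_levels),
                                  envelope = default_envelope("gaussian"),
                                  n_trials = 30, seed = 1, dt = 0.1,
                                  cfg = binning_config(n_trials = n_trials),
                                  cond_offset = 0L) {
  rows <- list()
  dd <- drive_defaults()
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    for (ci in seq_len(nrow(noise_grid))) {
      noise <- noise_spec(as.character(noise_grid$mode[ci]),
                          noise_grid$sigma[ci])
      tv <- traversal_trials(m$params, m$P_ampa, m$P_nmda, envelope, noise,
                             n_trials, seed, model_id = m$model_id,
                             cond_id = ci + cond_offset, dt = dt,
                             dt_grid = dd$dt_grid,
                             sigma_kernel = dd$sigma_kernel)
      met <- condition_metrics(tv$rates, cfg)
      met$model_id <- m$model_id
      met$noise_type <- as.character(noise_grid$mode[ci])
      met$sigma_noise <- noise_grid$sigma[ci]
      met$envelope <- envelope$form
      met$seed <- seed
      met$blocked <- field_block_flag(tv$spikes, envelope)
      rows[[length(rows) + 1]] <- met
    }
  }
  do.call(rbind, rows)
}

#' Classify a model's SSI transition across noise levels
#'
#' A model is `peak_maximal` when, at the highest noise level, it
#' transfers more stimulus-specific information at the peak-firing
#' location than at the high-slope locations (ratio above unity);
#' otherwise it is `slope_maximal`.
#'
#' @param ratios `ssi_peak_over_slope` values ordered by increasing
#'   noise level (at least 3).
#' @return `"peak_maximal"` or `"slope_maximal"`.
#' @export
classify_ssi_transition <- function(ratios) {
  if (length(ratios) == 0) stop("empty sweep: no ratios supplied")
  if (length(ratios) < 3) stop("need ssi_peak_over_slope at >= 3 noise levels")
  if (ratios[length(ratios)] > 1) "peak_maximal" else "slope_maximal"
}

knockout_components <- c("KA", "KM", "SK", "HCN", "CaT", "CaN", "CaR",
                         "CaL", "dNaF", "NMDAR")

apply_knockout <- function(entry, component) {
  if (component %in% c("NaF", "KDR")) {
    stop("virtual knockout of the spike-generating conductances (NaF/KDR) ",
         "is infeasible: the neuron ceases spiking")
  }
  if (!component %in% knockout_components) {
    stop("unknown knockout component: ", component)
  }
  p <- entry$params
  switch(component,
    KA = { p$gKA_soma <- 0 },
    KM = { p$gKM <- 0 },
    SK = { p$gSK <- 0 },
    HCN = { p$gh_soma <- 0 },
    CaT = { p$gCaT_soma <- 0 },
    CaN = { p$gCaN <- 0 },
    CaR = { p$gCaR <- 0 },
    CaL = { p$gCaL <- 0 },
    dNaF = { p$dnaf_scale <- 0 },
    NMDAR = { entry$P_nmda <- 0 })
  entry$params <- p
  entry
}

ko_metric_cols <- c("SSI1", "SSI2", "SSI_FWHM", "SSI_dRatio", "SSI_dip",
                    "SSI_d", "MI1", "MI2", "MI_FWHM", "MI_dRatio",
                    "MI_dip", "MI_d")

#' Virtual knockout of one channel/receptor analogue
#'
#' Sets the component's strength to zero (conductance analogue, the
#' dendritic-NaF analogue, or the NMDAR permeability), reruns the given
#' condition with identical seeds, and reports the percentage change of
#' every information metric relative to baseline. Knocking out the
#' global spike-generating conductances is refused, since the surrogate
#' (like the full model) cannot spike without them.
#'
#' @param entry Validated model entry ([fixture_ensemble()] element).
#' @param component One of `"KA"`, `"KM"`, `"SK"`, `"HCN"`, `"CaT"`,
#'   `"CaN"`, `"CaR"`, `"CaL"`, `"dNaF"`, `"NMDAR"`.
#' @param noise A [noise_spec()] for the condition.
#' @param envelope Drive envelope.
#' @param n_trials,seed,dt,cfg,cond_id As in [run_variability_sweep()].
#' @param baseline Optional precomputed baseline metrics row (from
#'   [run_variability_sweep()] at the same condition and seeds).
#' @return One-row data.frame of percentage changes (plus `component`,
#'   `model_id`).
#' @export
virtual_knockout <- function(entry, component,
                             noise = noise_spec("additive_white", 5e-4),
                             envelope = default_envelope("gaussian"),
                             n_trials = 30, seed = 1, dt = 0.1,
                             cfg = binning_config(n_trials = n_trials),
                             cond_id = 1L, baseline = NULL) {
  dd <- drive_defaults()
  run_one <- function(e) {
    tv <- traversal_trials(e$params, e$P_ampa, e$P_nmda, envelope, noise,
                           n_trials, seed, model_id = e$model_id,
                           cond_id = cond_id, dt = dt,
                           dt_grid = dd$dt_grid,
                           sigma_kernel = dd$sigma_kernel)
    condition_metrics(tv$rates, cfg)
  }
  if (is.null(baseline)) baseline <- run_one(entry)
  ko <- run_one(apply_knockout(entry, component))
  pct <- vapply(ko_metric_cols, function(cc) {
    b <- baseline[[cc]]; k <- ko[[cc]]
    if (isTRUE(all.equal(b, k))) return(0)
    100 * (k - b) / b
  }, numeric(1))
  out <- as.data.frame(as.list(pct))
  out$component <- component
  out$model_id <- entry$model_id
  out
}

#' Pairwise Pearson correlations with strength categories
#'
#' @param table Data.frame or matrix of numeric columns (parameters,
#'   measurements and/or information metrics; at least 3 rows).
#' @return List with `r` (correlation matrix; `NA` for zero-variance
#'   columns, unit diagonal) and `category` (matrix of strength labels
#'   by absolute coefficient: <0.2 very weak, <0.4 weak, <0.6 moderate,
#'   <0.8 strong, else very strong).
#' @export
correlation_report <- function(table) {
  x <- as.matrix(table)
  stopifnot(nrow(x) >= 3, is.numeric(x))
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[, sds == 0] <- NA
  r[sds == 0, ] <- NA
  diag(r) <- 1
  labels <- c("Very Weak", "Weak", "Moderate", "Strong", "Very Strong")
  category <- matrix(labels[findInterval(abs(r), c(0.2, 0.4, 0.6, 0.8)) + 1],
                     nrow(r), dimnames = dimnames(r))
  category[is.na(r)] <- NA
  list(r = r, category = category)
}

#' PCA of the parameters of two labeled subpopulations
#'
#' Standardizes the biophysical parameters of both groups jointly,
#' projects onto principal components, and reports the per-model
#' coefficients with group labels together with the explained-variance
#' fractions - the standard check for structured parametric differences
#' between subpopulations.
#'
#' @param group_a,group_b Lists of [model_params()] (>= 3 each).
#' @return List with `scores` (data.frame incl. `group`), `explained`
#'   (variance fractions, nonincreasing), and the `prcomp` fit.
#' @export
pca_subpopulations <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  tab <- parameter_table()
  to_mat <- function(g) t(vapply(g, function(p) unlist(p[tab$name]),
                                 numeric(nrow(tab))))
  x <- rbind(to_mat(group_a), to_mat(group_b))
  keep <- apply(x, 2, stats::sd) > 0
  fit <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as.data.frame(fit$x)
  scores$group <- rep(c("A", "B"), c(length(group_a), length(group_b)))
  list(scores = scores, explained = expl, fit = fit)
}
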