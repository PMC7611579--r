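#' Canonical pipeline configuration
#'
#' A single nested list holding every tunable setting of the pipeline
#' with its default: envelope, noise levels, synapse and ionic
#' parameters, surrogate integration settings, and the information
#' binning scheme. Serializable to JSON for provenance alongside results.
#'
#' @return Nested named list.
#' @export
pipeline_config <- function() {
  dd <- drive_defaults()
  env <- ion_environment()
  list(
    envelope = list(form = "gaussian", F_pre_max = dd$F_pre_max, f0 = 8,
                    T_center = 5, sigma = 1, lam = 5, k = 25,
                    t_start = 0, t_end = 10),
    noise = list(agwn_levels = dd$agwn_levels, mgwn_levels = dd$mgwn_levels,
                 pink_cutoff_hz = 5, value_is_std = FALSE),
    drive = list(n_synapses = dd$n_synapses, dt_rate_s = dd$dt_rate,
                 n_trials = dd$n_trials),
    ensemble = list(n_pre = 15, weight_sigma = 1.2),
    synapse = list(nmdar_to_ampar_ratio = 1.5, unitary_epsp_mv = 0.2,
                   ampa = list(tau_r = 2, tau_d = 10, P_Na = 1, P_K = 1),
                   nmda = list(tau_r = 5, tau_d = 50, P_Na = 1, P_K = 1,
                               P_Ca = 10.6, mg_block = TRUE)),
    ions = list(Na = unname(env$conc$Na), K = unname(env$conc$K),
                Ca = unname(env$conc$Ca), Mg_out = env$Mg_out,
                temperature_K = env$temperature),
    surrogate = c(surrogate_constants()[c("kR", "kh", "tau_w", "C_nF",
                                          "kKA", "kNa", "kKDR", "b0",
                                          "tau_adapt")],
                  list(threshold_mv = -50, reset_mv = -60,
                       refractory_ms = 2, E_leak_mv = -65,
                       dt_sim_ms = dd$dt_sim)),
    analysis = list(sigma_kernel_s = dd$sigma_kernel,
                    dt_grid_s = dd$dt_grid,
                    binning = unclass(binning_config())))
}

#' Write / read the pipeline configuration as JSON
#'
#' @param config A configuration list (default [pipeline_config()]).
#' @param path File path.
#' @name config_io
#' @export
write_pipeline_config <- function(config = pipeline_config(), path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for config serialization")
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname config_io
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for config serialization")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
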