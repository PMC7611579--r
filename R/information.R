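#' Binning configuration for the information metrics
#'
#' Defaults follow the standard analysis: 20 locations for piecewise
#' mutual information, each subdivided into 4 stimulus bins with the rate
#' quantized into 20 response bins; stimulus-specific information uses 80
#' stimulus and 40 response bins over the whole traversal; 30 trials.
#'
#' @param n_locations Number of MI locations.
#' @param stimulus_bins_per_location Stimulus bins within each location.
#' @param mi_response_bins Response bins for the piecewise MI.
#' @param ssi_stimulus_bins,ssi_response_bins Bins for the SSI histogram.
#' @param n_trials Trials per condition.
#' @param response_range_mode `"global"` (equal-width bins spanning
#'   \[0, max rate\] across all trials and positions; keeps locations
#'   comparable) or `"per_location"` (bins span each location's own range).
#' @param sample_mode `"bin_center"` decimates the analysis grid to one
#'   sample per (stimulus bin, trial) - the rate at the bin center - so
#'   the number of stimulus-response pairs is `n_S * n_trials`;
#'   `"all_samples"` counts every grid sample.
#' @return Object of class `binning_config`.
#' @export
binning_config <- function(n_locations = 20, stimulus_bins_per_location = 4,
                           mi_response_bins = 20, ssi_stimulus_bins = 80,
                           ssi_response_bins = 40, n_trials = 30,
                           response_range_mode = c("global", "per_location"),
                           sample_mode = c("bin_center", "all_samples")) {
  stopifnot(n_locations >= 2, stimulus_bins_per_location >= 2,
            mi_response_bins >= 2, ssi_stimulus_bins >= 2,
            ssi_response_bins >= 2)
  structure(list(n_locations = n_locations,
                 stimulus_bins_per_location = stimulus_bins_per_location,
                 mi_response_bins = mi_response_bins,
                 ssi_stimulus_bins = ssi_stimulus_bins,
                 ssi_response_bins = ssi_response_bins,
                 n_trials = n_trials,
                 response_range_mode = match.arg(response_range_mode),
                 sample_mode = match.arg(sample_mode)),
            class = "binning_config")
}

# Decimate a rate_profile_set to one sample per (stimulus bin, trial):
# the sample nearest each stimulus-bin center. Returns n_bins x n_trials.
decimate_to_bins <- function(rates, stim_edges) {
  centers <- (stim_edges[-1] + stim_edges[-length(stim_edges)]) / 2
  idx <- vapply(centers, function(ct) which.min(abs(rates$time - ct)), 0L)
  rates$rates[idx, , drop = FALSE]
}

#' Build a stimulus-response joint histogram
#'
#' Bins firing-rate responses against stimulus (position/time) bins.
#' In `bin_center` mode each (stimulus bin, trial) contributes one count -
#' the rate at the bin center; in `all_samples` mode every grid sample in
#' the window contributes. The stimulus marginal is uniform by
#' construction (constant traversal velocity, uniform grid). Responses
#' falling outside the response range are clipped into the end bins.
#'
#' @param rates A [rate_profile_set()].
#' @param stim_edges Strictly increasing stimulus bin edges (s).
#' @param resp_edges Strictly increasing response bin edges (Hz).
#' @param sample_mode See [binning_config()].
#' @return Object of class `joint_histogram` with `counts`
#'   (`n_S` x `n_R`), the edges, and the total count `n`.
#' @export
build_joint_histogram <- function(rates, stim_edges, resp_edges,
                                  sample_mode = "bin_center") {
  stopifnot(inherits(rates, "rate_profile_set"),
            all(diff(stim_edges) > 0), all(diff(resp_edges) > 0),
            rates$n_trials >= 1)
  n_s <- length(stim_edges) - 1
  n_r <- length(resp_edges) - 1
  if (sample_mode == "bin_center") {
    vals <- decimate_to_bins(rates, stim_edges)           # n_s x n_trials
    sbin <- rep(seq_len(n_s), times = ncol(vals))
    v <- as.vector(vals)
  } else {
    keep <- rates$time >= stim_edges[1] & rates$time <= stim_edges[length(stim_edges)]
    tt <- rates$time[keep]
    sb <- pmin(pmax(findInterval(tt, stim_edges, rightmost.closed = TRUE), 1), n_s)
    sbin <- rep(sb, times = rates$n_trials)
    v <- as.vector(rates$rates[keep, , drop = FALSE])
  }
  rbin <- findInterval(v, resp_edges, rightmost.closed = TRUE)
  rbin <- pmin(pmax(rbin, 1L), n_r)  # clip out-of-range into end bins
  counts <- matrix(0, n_s, n_r)
  tab <- table(factor(sbin, levels = seq_len(n_s)),
               factor(rbin, levels = seq_len(n_r)))
  counts[] <- as.numeric(tab)
  structure(list(counts = counts, stim_edges = stim_edges,
                 resp_edges = resp_edges, n = sum(counts)),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> %d stimulus x %d response bins, n=%d\n",
              nrow(x$counts), ncol(x$counts), as.integer(x$n)))
  invisible(x)
}

xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Mutual information of a joint histogram (bits)
#'
#' `I = H(F) - H(F|S)` with the `0 log 0 = 0` convention; always in
#' `[0, min(log2 n_S, log2 n_F)]`.
#'
#' @param h A [build_joint_histogram()] result (or a plain counts matrix).
#' @return Bits.
#' @export
mutual_information <- function(h) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  p <- counts / n
  p_s <- rowSums(p)
  p_f <- colSums(p)
  h_f <- -sum(xlogx(p_f))
  h_f_given_s <- 0
  for (i in seq_along(p_s)) {
    if (p_s[i] > 0) {
      cond <- p[i, ] / p_s[i]
      h_f_given_s <- h_f_given_s - p_s[i] * sum(xlogx(cond))
    }
  }
  max(h_f - h_f_given_s, 0)
}

#' Specific information of one response bin (bits)
#'
#' `I_sp(F_j) = H(S) - H(S|F_j)`: the reduction in stimulus uncertainty
#' gained from observing a response in bin `j`. Undefined (NA) for an
#' empty response bin.
#'
#' @param h A [build_joint_histogram()] result (or counts matrix).
#' @param j Response bin index; omit to get all bins.
#' @return Bits (vector if `j` omitted).
#' @export
specific_information <- function(h, j = NULL) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  n <- sum(counts)
  p <- counts / n
  p_s <- rowSums(p)
  p_f <- colSums(p)
  h_s <- -sum(xlogx(p_s))
  isp <- vapply(seq_along(p_f), function(jj) {
    if (p_f[jj] == 0) return(NA_real_)
    cond <- p[, jj] / p_f[jj]  # p(S | F_j)
    h_s + sum(xlogx(cond))
  }, numeric(1))
  if (is.null(j)) isp else isp[j]
}

#' Treves-Panzeri bias-correction constant (bits)
#'
#' `C1 = (n_S - 1)(n_R - 1) / (2 n_SRP ln 2)`, subtracted from each
#' plug-in specific-information estimate to remove the leading-order
#' finite-sampling bias.
#'
#' @param n_S Total number of stimulus bins.
#' @param n_R Total number of response bins.
#' @param n_SRP Total number of stimulus-response pairs.
#' @export
treves_panzeri_c1 <- function(n_S, n_R, n_SRP) {
  stopifnot(n_SRP > 0)
  (n_S - 1) * (n_R - 1) / (2 * n_SRP * log(2))
}

#' Stimulus-wise SSI of a joint histogram
#'
#' `SSI(S_i) = sum_j p(F_j|S_i) Isp(F_j)` with empty response bins
#' excluded, optionally subtracting the Treves-Panzeri constant from each
#' specific-information value.
#'
#' @param h A [build_joint_histogram()] result (or counts matrix).
#' @param bias_correct Subtract [treves_panzeri_c1()] from each `Isp`.
#' @return One SSI value (bits) per stimulus bin (`NA` for empty bins).
#' @export
ssi_values <- function(h, bias_correct = TRUE) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  n <- sum(counts)
  p <- counts / n
  p_s <- rowSums(p)
  isp <- specific_information(counts)
  c1 <- if (bias_correct) {
    treves_panzeri_c1(nrow(counts), ncol(counts), n)
  } else 0
  vapply(seq_len(nrow(counts)), function(i) {
    if (p_s[i] == 0) return(NA_real_)
    cond <- p[i, ] / p_s[i]     # p(F_j | S_i)
    occ <- cond > 0             # empty response bins excluded
    sum(cond[occ] * (isp[occ] - c1))
  }, numeric(1))
}

#' Location-resolved information profile
#'
#' @param positions Location centers (s).
#' @param values Information (bits).
#' @param kind `"SSI"` or `"MI"`.
#' @param bias_corrected Whether the Treves-Panzeri constant was
#'   subtracted.
#' @return Object of class `info_profile`.
#' @export
info_profile <- function(positions, values, kind = c("SSI", "MI"),
                         bias_corrected = FALSE) {
  kind <- match.arg(kind)
  stopifnot(length(positions) == length(values))
  structure(list(positions = positions, values = values, kind = kind,
                 bias_corrected = bias_corrected),
            class = "info_profile")
}

#' @export
print.info_profile <- function(x, ...) {
  cat(sprintf("<info_profile> %s%s, %d locations, max %.3f bits\n",
              x$kind, if (x$bias_corrected) " (bias-corrected)" else "",
              length(x$values), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Piecewise mutual information across locations
#'
#' Splits the traversal window into `n_locations` segments; within each,
#' builds a (stimulus-bins-per-location x response-bins) histogram and
#' computes its mutual information. Response-bin edges are global
#' equal-width bins over \[0, max rate\] by default, or per-location
#' ranges.
#'
#' @param rates A [rate_profile_set()].
#' @param cfg A [binning_config()].
#' @param bias_correct Subtract the Treves-Panzeri constant for each
#'   location's histogram.
#' @return An [info_profile()] of kind `"MI"`.
#' @export
mi_profile <- function(rates, cfg = binning_config(), bias_correct = TRUE) {
  t0 <- rates$time[1]; t1 <- rates$time[length(rates$time)]
  loc_edges <- seq(t0, t1, length.out = cfg$n_locations + 1)
  gmax <- max(rates$rates)
  vals <- numeric(cfg$n_locations)
  for (i in seq_len(cfg$n_locations)) {
    se <- seq(loc_edges[i], loc_edges[i + 1],
              length.out = cfg$stimulus_bins_per_location + 1)
    re <- if (cfg$response_range_mode == "global") {
      seq(0, max(gmax, 1e-12), length.out = cfg$mi_response_bins + 1)
    } else {
      vals_loc <- decimate_to_bins(rates, se)
      rng <- range(vals_loc)
      if (diff(rng) == 0) rng <- rng + c(0, 1e-9)
      seq(rng[1], rng[2], length.out = cfg$mi_response_bins + 1)
    }
    h <- build_joint_histogram(rates, se, re, cfg$sample_mode)
    v <- mutual_information(h)
    if (bias_correct) {
      v <- v - treves_panzeri_c1(nrow(h$counts), ncol(h$counts), h$n)
    }
    vals[i] <- v
  }
  info_profile((loc_edges[-1] + loc_edges[-length(loc_edges)]) / 2, vals,
               "MI", bias_corrected = bias_correct)
}

#' Stimulus-specific information profile
#'
#' Builds the full-traversal (ssi-stimulus-bins x ssi-response-bins)
#' histogram and returns `SSI(S_i) = sum_j p(F_j|S_i) Isp(F_j)` per
#' stimulus bin, with the Treves-Panzeri constant subtracted from each
#' specific-information value when `bias_correct` is on.
#'
#' @inheritParams mi_profile
#' @return An [info_profile()] of kind `"SSI"`.
#' @export
ssi_profile <- function(rates, cfg = binning_config(), bias_correct = TRUE) {
  t0 <- rates$time[1]; t1 <- rates$time[length(rates$time)]
  se <- seq(t0, t1, length.out = cfg$ssi_stimulus_bins + 1)
  re <- seq(0, max(max(rates$rates), 1e-12),
            length.out = cfg$ssi_response_bins + 1)
  h <- build_joint_histogram(rates, se, re, cfg$sample_mode)
  info_profile((se[-1] + se[-length(se)]) / 2,
               ssi_values(h, bias_correct), "SSI",
               bias_corrected = bias_correct)
}

# local maxima of a vector (strictly greater than at least one neighbour,
# not less than either)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] >= v[i - 1] & v[i] >= v[i + 1] & (v[i] > v[i - 1] | v[i] > v[i + 1])]
}

#' Scalar metrics of an information profile
#'
#' Locates the two flanking peaks of a (typically bimodal) information
#' profile relative to the center of the firing-rate profile, and derives
#' the standard summary metrics: the two peak values, the profile FWHM,
#' the flank-distance ratio, the dip (center value minus the mean of the
#' two flanking peak values), the peak separation, and the ratio of the
#' information at the peak-firing location to the mean information at the
#' two maximum-|slope| locations of the tuning curve. Peaks are local
#' maxima of the 3-point moving-averaged profile, the highest on each side
#' of the rate-profile center. A profile with no local maximum on one side
#' is flagged unimodal and falls back to the center value.
#'
#' @param info An [info_profile()].
#' @param rate The matching [rate_profile_set()] (its trial mean defines
#'   the field center and the slope locations).
#' @return List with `peak1`, `peak2`, `fwhm`, `d_ratio`, `dip`, `d`,
#'   `peak_over_slope`, `unimodal`, `t_peak1`, `t_peak2`, `t_center`.
#' @export
profile_metrics <- function(info, rate) {
  stopifnot(inherits(info, "info_profile"), length(info$values) >= 5)
  pos <- info$positions
  val <- info$values
  val[is.na(val)] <- 0
  sm <- stats::filter(val, rep(1 / 3, 3), sides = 2)
  sm[1] <- val[1]; sm[length(val)] <- val[length(val)]
  sm <- as.numeric(sm)

  m <- rowMeans(rate$rates)
  t_center <- rate$time[which.max(m)]
  i_center <- which.min(abs(pos - t_center))

  cand <- local_maxima(sm)
  left <- cand[pos[cand] < t_center]
  right <- cand[pos[cand] > t_center]
  unimodal <- (length(left) == 0 || length(right) == 0)
  if (unimodal) {
    peak1 <- peak2 <- val[i_center]
    t1 <- t2 <- pos[i_center]
    d <- 0; d_ratio <- 1; dip <- 0
  } else {
    i1 <- left[which.max(sm[left])]
    i2 <- right[which.max(sm[right])]
    peak1 <- val[i1]; peak2 <- val[i2]
    t1 <- pos[i1]; t2 <- pos[i2]
    d <- t2 - t1
    d_ratio <- (t_center - t1) / (t2 - t_center)
    dip <- val[i_center] - mean(c(peak1, peak2))
  }

  fwhm <- fwhm_of_profile(pos, val)

  # slope locations: max |dF/dt| of the trial-mean rate on each side
  slope <- diff(m) / diff(rate$time)
  mid_t <- (rate$time[-1] + rate$time[-length(rate$time)]) / 2
  sl_left <- mid_t[mid_t < t_center][which.max(abs(slope[mid_t < t_center]))]
  sl_right <- mid_t[mid_t > t_center][which.max(abs(slope[mid_t > t_center]))]
  if (!length(sl_left)) sl_left <- t_center
  if (!length(sl_right)) sl_right <- t_center
  v_slopes <- val[c(which.min(abs(pos - sl_left)),
                    which.min(abs(pos - sl_right)))]
  peak_over_slope <- val[i_center] / mean(v_slopes)

  list(peak1 = peak1, peak2 = peak2, fwhm = fwhm, d_ratio = d_ratio,
       dip = dip, d = d, peak_over_slope = peak_over_slope,
       unimodal = unimodal, t_peak1 = t1, t_peak2 = t2,
       t_center = t_center)
}
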