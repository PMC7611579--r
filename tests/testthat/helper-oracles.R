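# Independent brute-force oracles for the information metrics, written
# directly from the definitions and kept free of any package internals.

# Mutual information as the plain double sum
# sum_{s,f} p(s,f) log2( p(s,f) / (p(s) p(f)) ).
mi_bruteforce <- function(counts) {
  p <- counts / sum(counts)
  ps <- rowSums(p)
  pf <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (ps[i] * pf[j]))
      }
    }
  }
  total
}

# Specific information of response bin j from the definition
# H(S) - H(S|F_j), as an explicit sum.
isp_bruteforce <- function(counts, j) {
  p <- counts / sum(counts)
  ps <- rowSums(p)
  pf <- colSums(p)
  if (pf[j] == 0) return(NA_real_)
  hs <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  cond <- p[, j] / pf[j]
  hsf <- -sum(cond[cond > 0] * log2(cond[cond > 0]))
  hs - hsf
}

# Random joint histogram with occasional empty cells.
random_joint <- function(n_s = 4, n_r = 20, n = 200) {
  counts <- matrix(stats::rpois(n_s * n_r, 2), n_s, n_r)
  counts[sample(length(counts), length(counts) %/% 4)] <- 0
  if (sum(counts) == 0) counts[1, 1] <- 1
  counts
}

# Exact first-order (RC) response to an arbitrary current: exact
# discretization of C dV/dt = -(V - E)/R_MOhm * 1e-3-ish handled in
# consistent units (mV, nA, MOhm, nF, ms): tau = R * C.
rc_response <- function(i_nA, R_MOhm, tau_ms, dt_ms, E = 0) {
  a <- exp(-dt_ms / tau_ms)
  v <- numeric(length(i_nA))
  vc <- E
  for (k in seq_along(i_nA)) {
    vinf <- E + R_MOhm * i_nA[k]
    vc <- vinf + (vc - vinf) * a
    v[k] <- vc
  }
  v
}

# Analytic impedance of the surrogate's linear resonant membrane:
# Z(f) = 1 / (gL + i w C + gw / (1 + i w tau_w)), units uS/nF/ms -> MOhm.
resonator_impedance <- function(f_hz, gL, gw, C_nF, tau_w_ms) {
  w <- 2 * pi * f_hz
  1 / (gL + 1i * w * C_nF / 1000 + gw / (1 + 1i * w * tau_w_ms / 1000))
}
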