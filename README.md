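# placefieldinfo

Where within its place field does a hippocampal place cell transfer the
most spatial information — at the peak-firing location or on the
high-slope flanks of its tuning curve? `placefieldinfo` is a desk-scale
R pipeline for studying that question in simulation: it synthesizes
theta-modulated place-field drive with controllable trial-to-trial
variability, pushes it through GHK-based AMPAR/NMDAR synapses into a
single-compartment spiking surrogate, and quantifies the resulting rate
responses with location-resolved information metrics. It is written for
computational neuroscientists who want a tested, reproducible
implementation of these analyses without a full morphological
simulation stack.

## The metrics at its core

For a stimulus (location) `S` and firing-rate response `F`:

* **Piecewise mutual information** at location *i*:
  `I_i(F;S) = H_i(F) − H_i(F|S)`, computed in 20 locations, each with 4
  stimulus bins and 20 response bins.
* **Specific information** of a response bin:
  `I_sp(F_j) = H(S) − H(S|F_j)`, and the **stimulus-specific
  information** `SSI(S_i) = Σ_j p(F_j|S_i) I_sp(F_j)` over an 80 × 40
  stimulus-response histogram of the full traversal.
* **Treves–Panzeri bias correction**
  `C1 = (N_S−1)(N_R−1) / (2 N_SRP ln 2)`, subtracted from each plug-in
  `I_sp` estimate.

Both profiles are summarized by the standard scalar metrics (flanking
peak values, FWHM, dip at the field center, peak separation and
distance ratio, and the SSI_peak/SSI_slope ratio).

The afferent drive is a Gaussian- or reflected-Erlang-modulated
cosinusoid (8 Hz theta), perturbed by additive, multiplicative or pink
noise and sampled into per-synapse Bernoulli spike trains. The
surrogate neuron is a linear resonant membrane (leak + slow
negative-feedback conductance) with threshold-reset spiking,
spike-triggered adaptation, and calibrated unitary EPSPs (0.2 mV);
populations are drawn by uniform parameter sampling with
electrophysiological validation, then swept across noise conditions and
virtual ion-channel knockouts. See the methods vignette
(`vignettes/placefield-information.Rmd`) for the model equations and
every numerical decision.

## Worked example

```r
library(placefieldinfo)

params <- model_params()                   # base biophysical parameters
cal <- calibrate_unitary_epsp(params)      # synaptic-democracy calibration
cat(sprintf("unitary EPSP: %.3f mV\n", cal$epsp_mV))

im <- intrinsic_measurements(params)       # step + chirp protocols
cat(sprintf("R_in = %.1f MOhm, f_R = %.1f Hz, Q = %.2f, |Z|max = %.1f MOhm\n",
            im$R_in, im$f_R, im$Q, im$Z_max))

entry <- list(params = params, P_ampa = cal$P_ampa,
              P_nmda = cal$P_nmda, model_id = 1L)
sw <- run_variability_sweep(list(entry),
        data.frame(mode = "additive_white", sigma = c(5e-4, 5e-3)),
        n_trials = 10, seed = 7)
sw[, c("sigma_noise", "F_max", "SSI1", "SSI_dip", "MI1", "ssi_peak_over_slope")]
```

prints (about 20 s on one core):

```
unitary EPSP: 0.200 mV
R_in = 68.7 MOhm, f_R = 3.5 Hz, Q = 1.22, |Z|max = 85.5 MOhm
  sigma_noise     F_max     SSI1    SSI_dip       MI1 ssi_peak_over_slope
1       5e-04  84.95651 2.475228 -1.0976915 0.8220798           0.6304151
2       5e-03 103.99215 2.300343 -0.8934854 0.2059838           0.5755383
```

Reading it: the calibrated base model is a valid "cell" (input
resistance and resonance inside the electrophysiological bounds). At
low additive noise it transfers ~2.5 bits of stimulus-specific
information at the first flanking peak of the SSI profile; raising the
noise variance tenfold cuts the flanking MI by a factor of four and
lowers SSI, while the negative SSI dip and a peak/slope ratio below 1
say that maximal information transfer stays at the high-slope flanks of
the tuning curve, not at the firing peak.

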