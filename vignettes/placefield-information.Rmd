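---
title: "Methods: spatial information transfer in a simulated place field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial information transfer in a simulated place field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

A hippocampal place cell fires maximally at one location of a linear
arena and less on either side: its firing-rate profile within the place
field is a spatial tuning curve. This package asks where, within that
field, the cell transfers the most information about the animal's
location — at the peak-firing location or at the high-slope flanks of
the tuning curve — and how the answer depends on trial-to-trial
variability, on the symmetry of the field, and on the cell's biophysical
make-up. The pipeline is desk-scale: all inputs are synthesized, a
single-compartment spiking surrogate stands in for the neuron, and the
analysis layer computes location-resolved information metrics from the
simulated rate responses.

## Synthetic afferent drive

Each of 80 afferent synapses is driven by the same deterministic rate
envelope, a theta-modulated place-field profile. The symmetric form is a
Gaussian-modulated cosinusoid

$$F_{pre}(t) = F_{pre}^{max}\,\bigl(1 + \cos(2\pi f_0 (t - T))\bigr)\,
  e^{-(t-T)^2 / 2\sigma^2},$$

with theta frequency $f_0 = 8$ Hz, field center $T = 5$ s and width
$\sigma = 1$ s on a 10 s constant-velocity traversal (time and position
are interchangeable). The asymmetric form replaces the Gaussian factor
by a horizontally reflected Erlang density
$\lambda^k (T-t)^{k-1} e^{-\lambda (T-t)} / (k-1)!$ with $\lambda = 5$,
$k = 25$, zero for $t > T$. Two packaging decisions:

* **Erlang placement.** With the reflection point at 5 s the Erlang mode
  sits at $T - (k-1)/\lambda = 0.2$ s, i.e. at the very edge of the
  traversal, where the early flank of the field (and of any information
  profile) would be truncated. The default asymmetric drive therefore
  puts the reflection point at $5 + (k-1)/\lambda = 9.8$ s so that the
  mode lands at the window center: a slow-rising, steeply falling field
  fully contained in the window, which is the experience-dependent
  asymmetry being modeled.
* **Erlang amplitude.** The Gaussian factor peaks at 1 while the Erlang
  density peaks at $\approx 0.41$; `default_envelope("erlang")` rescales
  $F_{pre}^{max}$ by the reciprocal of the density's modal value so both
  envelope forms deliver the same peak drive and asymmetry — not drive
  strength — is the manipulated variable.

`F_pre^max` itself is not an empirical quantity; its default (60 Hz) was
calibrated once so that the base surrogate's noiseless field clears the
56 Hz tuning-sharpness gate with a comfortable margin.

### Trial-to-trial variability

Noise is injected into the per-synapse rate before spike sampling,
additively ($[F + \xi]_+$, activity-independent) or multiplicatively
($[F (1 + \xi)]_+$, activity-dependent), with rectification at zero; a
pink option low-pass filters white noise (first-order filter, default
cutoff 5 Hz, whose log-log spectral slope passes through $-1$ around the
cutoff) and rescales it to the requested variance. $\xi$ is sampled
i.i.d. on the 1 ms rate grid and held within the step.

The noise levels are configured as variances with nominal unit
Hz$^2$: additive $\{5\times10^{-4}, 10^{-3}, 5\times10^{-3}\}$ and
multiplicative $\{0.01, 0.1, 0.5\}$. A dimensional convention is
unavoidable here, because an additive rate perturbation and a
multiplicative gain perturbation cannot literally share a unit. The
package interprets each value as the variance of $\xi$ *in the units of
the quantity it perturbs, on the per-millisecond scale*: additive
$\xi$ has standard deviation $1000\sqrt{\sigma_{noise}}$ Hz (i.e. the
rate expressed in ms$^{-1}$, the natural unit of a simulation whose
per-step event probability is $F \cdot dt$), multiplicative $\xi$ is
dimensionless with standard deviation $\sqrt{\sigma_{noise}}$. Under the
alternative literal reading (additive sd $=\sqrt{\sigma_{noise}}$ Hz,
at most 0.07 Hz against a 120 Hz peak envelope) the configured levels
produce no measurable trial-to-trial variability at all, so no
noise-level comparison could be expressed. The chosen convention uses
the configured numbers verbatim and yields the expected phenomenology:
additive noise raises out-of-field drive and degrades information
monotonically across the three levels, while multiplicative noise —
which vanishes with the envelope — has a far smaller effect.
`noise_spec(value_is_std = TRUE)` flips the variance/sd reading.

### Spike sampling

Presynaptic events are Bernoulli samples: at each step an event occurs
with probability $dt \cdot F_{pre}(t)$, independently per synapse and
trial ([sample_spike_trains()]). Inside the compiled integrator the same
law is realized per rate-grid window by drawing the event count
Binomial$(m, p)$ and placing events on distinct steps — distributionally
identical, far fewer RNG calls. All randomness flows through R's RNG,
so every run is reproducible from the master seed.

## Synapse model

Colocalized AMPARs and NMDARs with Goldman–Hodgkin–Katz ionic fluxes:
for each ion, current $\propto z^2 v F^2/RT \cdot
( [X]_i - [X]_o e^{-zvF/RT} ) / ( 1 - e^{-zvF/RT} )$ with Na 18/140 mM,
K 140/5 mM, Ca $10^{-4}$/2 mM at 307.15 K. The removable singularity at
$v = 0$ is evaluated by the series $u/(1-e^{-u}) = 1 + u/2 + u^2/12$
for $|u| < 10^{-4}$ (avoiding catastrophic cancellation), and each flux
crosses zero exactly at its Nernst potential. NMDAR currents carry the
magnesium block $\bigl(1 + [Mg]_o e^{-0.062 v}/3.57\bigr)^{-1}$ with
$[Mg]_o = 2$ mM and relative permeabilities $P_{Ca} : P_{Na} : P_K =
10.6 : 1 : 1$; AMPARs pass Na and K equally. Receptor kinetics are
normalized double exponentials
$s(t) = a\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ with $\tau_r/\tau_d$ = 5/50
ms (NMDAR) and 2/10 ms (AMPAR), peaking at
$\tau_r\tau_d/(\tau_d-\tau_r)\,\ln(\tau_d/\tau_r)$; events superpose
linearly.

The permeability scale that converts flux to absolute current in a
point neuron is not a measurable constant; it is set by a calibration
routine (`calibrate_unitary_epsp()`) that tunes the AMPAR scale until a
single presynaptic event produces a 0.2 mV somatic EPSP at rest —
the synaptic-democracy normalization — and sets the NMDAR scale at 1.5
times the AMPAR scale.

## The spiking surrogate

The full morphological, ten-conductance model that motivates this
pipeline cannot be rebuilt from published equations alone (the channel
kinetics live in cited references), so the voltage substrate is an
explicitly labeled surrogate: a single compartment

$$C\,\dot V = -g_L (V - E_L) - g_w w - I_{adapt} - I_{syn}(V, t) + I_{inj},
\qquad \tau_w \dot w = (V - E_L) - w,$$

with threshold-reset spiking (threshold $-50$ mV, reset $-60$ mV,
refractory 2 ms, a stereotyped 1 ms waveform pasted into the trace for
downstream spike detection) and a spike-triggered adaptation current
(increment $b$, decay $\tau_a = 120$ ms). The slow negative-feedback
conductance $g_w$ makes the membrane a linear resonator with analytic
impedance $Z(\omega) = (g_L + i\omega C + g_w/(1 + i\omega\tau_w))^{-1}$,
so the standard chirp-based resonance measures ($f_R$, $|Z|_{max}$,
$Q$, $\Phi_L$) are all defined and testable against closed forms.

The 22 sampled biophysical parameters couple to this surrogate through
fixed, surrogate-specific mappings (they are design constants, not
measured biophysics):

| parameter family | surrogate coupling |
|---|---|
| $R_m$ profile, $R_a$ | leak: $g_L = 1/(0.936\sqrt{\bar R_m R_a})$, $\bar R_m$ = spatial mean of the sigmoidal profile over 0–350 µm |
| HCN ($h$) profile | resonant conductance $g_w \propto$ spatial mean of the $h$ density |
| KA profile | spike-threshold increment (KA dampens excitability) |
| NaF $\times$ dendritic flag | spike-threshold decrement; the *dendritic-NaF analogue* knockout zeroes it |
| KDR | reset deepening |
| KM, SK | adaptation increment; SK's share is multiplied by a weighted mean of the CaT/CaN/CaR/CaL densities (calcium-activated coupling) |

The coupling constants were calibrated once so that the base parameter
vector lands mid-range of the somatic validation bounds
($R_{in} \approx 68$ MΩ, $f_R \approx 3.5$ Hz, $Q \approx 1.2$); they
are fixed in `surrogate_constants()` and serialized with
`pipeline_config()`. Integration is exponential-Euler on the leak and
the slow variable with explicit synaptic/adaptation currents, default
$dt = 0.1$ ms (a 25 µs step is available; at default drive it changes
spike counts by well under the trial-to-trial spread).

What the surrogate does **not** capture: dendritic cable effects,
backpropagating action potentials, dendritic spikes and their
regenerative amplification, and depolarization-induced block. One
visible consequence: under strong additive noise the rectified noise
floor widens the simulated field, so the FWHM of the rate profile grows
at the highest noise level rather than shrinking; peak rate, ramp and
information trends are unaffected. A second consequence appears with
the asymmetric envelope: the expansive threshold nonlinearity sharpens
the steep (late) flank of the field more than a dendritically filtered
neuron would, which depresses the late SSI peak by a few percent
relative to the early one. The asymmetric field's substantive signature
survives intact — MI asymmetry is several-fold larger than SSI
asymmetry in relative terms — but a sign test across a 20-model fixture
does detect the small systematic SSI imbalance that a real neuron's
smoother output may not show. Population-level conclusions are
therefore checked at trend level (medians, sign tests), never as
reproductions of the original population counts or significance values.

## Information metrics

Rate profiles are estimated per trial by convolving spike times with a
unit-integral Gaussian kernel ($\sigma = 200$ ms) on a 10 ms grid.

**Piecewise MI.** The traversal is cut into 20 locations; within each,
4 stimulus bins against 20 response bins give
$I_i(F;S) = H_i(F) - H_i(F|S)$ with the $0\log 0 = 0$ convention.
**SSI.** Over the whole traversal, 80 stimulus bins against 40 response
bins; specific information $I_{sp}(F_j) = H(S) - H(S|F_j)$ and
$SSI(S_i) = \sum_j p(F_j|S_i)\,I_{sp}(F_j)$. The identities
$\sum_j p(F_j) I_{sp}(F_j) = I(S;F)$ and (uncorrected)
$\sum_i p(S_i)\,SSI(S_i) = I(S;F)$ are enforced to $10^{-12}$ against a
brute-force double-sum oracle in the test suite.
**Bias.** Each $I_{sp}$ (and, in the sweeps, each location's MI) is
corrected by the Treves–Panzeri constant
$C_1 = (N_S-1)(N_R-1) / (2 N_{SRP} \ln 2)$.

Numerical decisions, all exposed in `binning_config()`:

* **Response-bin edges** are global equal-width bins on
  $[0, \max \text{rate}]$, keeping locations comparable and the MI/SSI
  profiles interpretable side by side; a `per_location` mode exists (and
  is what makes a noiseless monotone map saturate at 2 bits per
  location).
* **Samples per bin.** The analysis grid is decimated to one sample per
  (stimulus bin, trial) — the rate at the bin center — so
  $N_{SRP} = N_S \times N_{trials}$ (2400 under defaults, giving
  $C_1 \approx 0.926$ bits); an `all_samples` mode is available but
  inflates the pair count with autocorrelated within-bin samples.
* **Peak finding** for the profile metrics: local maxima of the 3-point
  moving-averaged profile, the highest on each side of the rate-profile
  center; a profile with no flanking maximum on one side is flagged
  unimodal and falls back to the center value (dip 0, separation 0).
* **SSI$_{peak}$/SSI$_{slope}$** uses the operational definition: the
  profile value at the peak-firing location divided by the mean of the
  values at the two maximum-$|dF/dt|$ locations of the trial-mean rate —
  well-defined for any profile shape, unlike "the two SSI peaks".
* **Dip** is the profile value at the field center minus the mean of the
  two flanking peak values (negative for a bimodal profile).
* Empty response bins are excluded from SSI sums; out-of-range rates are
  clipped into the end bins.

## Population pipeline

`sample_parameters()` draws the 22 parameters independently and
uniformly from their published ranges (0.5–2$\times$ base, except the
axial resistivity whose published range is 100–250 Ω·cm).
`validate_model()` accepts a model only if all *somatic* measurements
pass: input resistance 40–100 MΩ, $|Z|_{max}$ 50–110 MΩ, $f_R$ 2–7 Hz,
$Q$ 1.01–1.5, $\Phi_L$ 0–0.3 rad·Hz, step-evoked rates within bounds at
100–250 pA, and tuning sharpness $F_{max} > 56$ Hz with FWHM < 2.5 s.
Dendritic and backpropagating-AP bounds are structurally unavailable in
a point surrogate and are excluded by design. Roughly one in five
sampled vectors validates, so heterogeneity survives the gate.

The regression baseline is a 20-model fixture at 30 trials per
condition — sizes chosen so a full sweep (three additive levels, the
asymmetric envelope, two multiplicative levels, two knockouts) completes
in minutes on a laptop while medians over models remain stable. Trend
checks use medians and sign tests; the 0.05 threshold is a test-suite
internal. Virtual knockouts set one component's strength to zero (the
conductance analogue, the dendritic-NaF analogue, or the NMDAR
permeability), rerun the identical seeds, and report percentage changes;
knocking out the spike generator (NaF/KDR) is refused because the
surrogate, like the original, cannot spike without it.

Per-trial seeds derive deterministically from (master seed, model,
condition, trial), which is what makes knockout reruns exactly paired
with their baselines; this bookkeeping is a reproducibility convention
of this package.

## What the tests do and do not show

The synthetic generator reproduces the *structure* of the study's
inputs — theta-modulated fields, independent per-synapse sampling,
additive/multiplicative/pink variability — not the statistics of real
afferent spike trains (no burstiness, no inter-synapse correlation, no
speed modulation). Passing the trend-level tests shows that the
analysis layer behaves lawfully and that the surrogate responds to
variability, asymmetry and knockouts in the established directions; it
does not certify quantitative agreement with any biological recording,
nor reproduce population counts, subpopulation splits or published
significance values, which depend on the full morphological model.
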