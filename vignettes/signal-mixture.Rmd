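---
title: "Fully-defined signal mixtures: models, decoders and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fully-defined signal mixtures: models, decoders and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(signalmix)
```

## The experimental idea

A patch-clamped neuron can be driven with a current waveform that is known
exactly, sample by sample. Two synthesis paradigms are implemented:

* **Signal immersed in noise.** The injected current is the sum of (i)
  Ornstein–Uhlenbeck (OU) noise `σ·η(t)` with zero mean, unit variance and
  correlation time `τ_I = 5` ms, mimicking ongoing synaptic bombardment;
  (ii) a train of artificial postsynaptic currents (aPSCs) of one fixed
  amplitude, the "signal"; and (iii) a DC offset that sets the firing
  rate. One experiment characterizes the encoding of that one signal.

* **Fully-defined signal mixture.** The current is the summed PSC activity
  of a large model presynaptic population (default 1024 neurons, 512
  excitatory and 512 inhibitory). Every presynaptic spike time and every
  PSC amplitude is known, so *any* input can be treated as "signal" and
  the sum of all others as "noise" — the detectability of inputs of 32
  different amplitudes and both signs is measured from a single
  recording.

The postsynaptic side can be a real recorded cell (the analysis half
accepts plain CSV spike and trigger tables) or the built-in
integrate-and-fire stand-in.

## Presynaptic population model

Each presynaptic neuron fires as a **gamma renewal process** with shape
`k = 2` and mean rate 5 Hz (equivalently, gamma scale
`(1000/rate)/k = 100` ms). Intervals below 10 ms are redrawn
(rejection resampling) so consecutive PSCs from one input do not overlap
strongly. Two consequences of the resampling floor are worth knowing:

* the realized mean rate is depressed by < 1% (4.977 Hz asymptotically at
  the defaults), and
* a maximum-likelihood gamma fit to the generated intervals returns a
  shape of about 2.077, not 2.000: removing the left tail makes firing
  look slightly more regular, and the ML shape estimate — which weights
  the log moment — is sensitive to exactly that tail. The package treats
  this as a property of the generator, not an estimation error; the
  truncated-gamma moments predict the fitted value to three decimals.

PSC peak amplitudes follow a **log-normal distribution** (`μ = 0.702`,
`σ = 0.9355` in natural-log pA), as reported for unitary connections in
paired cortical recordings, discretized onto 32 log-spaced levels
spanning `μ ± 3.5σ` in log space, with the tail mass folded into the
edge bins. The discretization recovers the target log-moments to well
within 1%; the span of 3.5 SDs was fixed once on that ground. Excitatory
and inhibitory amplitudes are drawn from the same distribution and
differ only in sign, which makes the summed current balanced *in law*.
Note that any single roster of 1024 amplitudes carries a residual E−I
imbalance (of order 15 pA in the summed current's mean at the defaults);
balance statements are therefore statements about expectations across
rosters.

Randomness is organized as one master seed from which per-neuron (and
per-episode) substreams are derived, so any neuron's train can be
regenerated individually and whole experiments replay bit-identically.

## Current synthesis

A PSC is a **difference of two exponentials**,
`w(t) ∝ exp(-t/τ_decay) − exp(-t/τ_rise)`, normalized to unit peak so
that "amplitude" always means peak current in pA. The two parameters are
the exponential time constants themselves (0.5/5 ms for the mixture
paradigm, 1/10 ms for signal-in-noise), not 10–90% times. Rendering runs
the amplitude-weighted spike delta train through two first-order
recursive filters — algebraically identical to convolving with the
untruncated kernel, exact at the sample grid, and linear in the
population by construction. Onsets are snapped to the 0.05 ms (20 kHz)
grid. The stored waveform template is truncated where it falls below
`1e-4` of peak (about nine decay constants); that template is only used
for inspection and export.

The OU noise uses the exact discretization
`x[n+1] = x[n]·e^(−dt/τ) + σ·sqrt(1−e^(−2dt/τ))·ξ[n]` from a stationary
start, so variance and autocorrelation are exact for any `dt`.

For the mixture, the zero-DC population sum is rescaled globally so its
SD equals `target_sd` (default 100 pA — in the slice experiment the
scale was set per cell to evoke 15–20 mV membrane fluctuations, and the
resulting current SDs were 70–110 pA). The DC offset is added **after**
scaling. The reported `scale_factor` converts roster amplitudes to
injected pA, and amplitudes are also reported in units of the current
SD, the natural axis for comparing across cells.

## The model neuron

The stand-in for the recorded layer-2/3 pyramidal cell is a **leaky
integrate-and-fire** neuron integrated by exponential Euler at the
stimulus sample step, with textbook cortical parameters
(`τ_m = 20` ms, `R_in = 140` MΩ, rest −70 mV, threshold −50 mV, reset
−60 mV, refractory 3 ms). With these values a 100 pA-SD mixture current
evokes subthreshold fluctuations of 15–20 mV (5th–95th percentile range,
spike samples removed), matching the calibration target of the
experiments. No quantitative equivalence to any real cell is claimed;
the published detection surfaces come from a real neuron and are
reproduced here qualitatively (directionally), not numerically.

Because a plain LIF never crosses 0 mV, a stylized 2 ms triangular spike
waveform (to +30 mV) is pasted into the voltage trace at each spike so
that the experimental spike-detection rule — positive zero crossings —
can be exercised end to end; the detector and the integrator's spike
registry agree exactly by construction. Threshold crossings are not
interpolated (timing error ≤ one 0.05 ms sample, far below all analysis
bins).

The protocol mirrors the recordings: 46 s episodes, the first 2 s
discarded from analysis, DC calibrated by bisection on a probe episode
until the measured rate is within 5% of target (at most 30 steps; an
unreachable target raises an error reporting the achieved bracket).
Because the DC is frozen after calibration, realized episode rates drift
around the target — e.g. a 1 Hz target realizes ~1.2–1.4 Hz, much as a
1 Hz target averaged 1.19 Hz in the reference recordings.

## The decoder

For every PSC onset (a *trigger*), the postsynaptic spike times within
±15 ms form one *sweep*; sweeps are grouped by sign and amplitude class.
Triggers inside the discard window or closer than `T_max` to an episode
edge are excluded, so all windows lie in the analyzed span. Overlapping
sweeps from different inputs are kept (the 10 ms ISI floor limits
same-input overlap). `P_pre(T)` and `P_post(T)` are the fractions of
sweeps with at least one spike in `[-T, 0)` and `[0, T)` ms; at these
rates and windows sweeps essentially never hold two spikes, so the
indicator- and count-based estimates coincide (both are computed).

**Parametric detection.** Population spike counts over `N` sweeps are
modeled as `B(N, P_pre)` and `B(N, P_post)`. An excitatory input is
detected when the post-onset count strictly exceeds the 95% quantile of
the pre-signal binomial; an inhibitory input when it falls strictly
below the 5% quantile. Quantiles use the "smallest k with CDF ≥ p"
convention, so detection at `P_post = P_pre` can never exceed the
nominal 5% (decoder false-positive calibration, exact for every N). The
excitatory tail is evaluated with the upper-tail CDF to keep tiny
probabilities accurate.

**Bootstrap detection.** Per repetition, `n_sets` (default 100) trial
sets of `N` sweeps are resampled with replacement; the empirical
distribution of the per-set pre-onset population counts provides the
threshold quantile (type-1 empirical quantile over the set sums); the
fraction of sets whose post-onset count passes it is one estimate; mean
and SD over `n_reps` repetitions are reported. A `pre_quantile =
"per_set"` flag instead tests each set against the binomial quantile
implied by its own pre-window rate.

The two estimators agree closely across amplitude, `T` and `N` (mean
absolute difference ~0.02 on the model-neuron data). They are *not*
identical cell by cell: where the detection surface is steep, the
empirical threshold flips between adjacent integer count atoms across
repetitions and the bootstrap mean can sit up to ~0.06 from the
exact-quantile parametric value. This is intrinsic to comparing an
empirical-quantile with an exact-quantile decoder and does not shrink
with more repetitions.

No multiple-testing correction is applied across amplitude classes
sharing one recording — each class is treated independently, as in the
per-class presentation of the reference experiments; users combining
classes inferentially should correct on their side.

## What the synthetic data does and does not emulate

The generator reproduces: independent gamma-renewal presynaptic firing,
log-normal amplitudes, balanced E/I drive, the 20 kHz stimulus grid, the
episode/discard protocol, and rate control via DC. It deliberately omits
correlations among inputs, heterogeneous rates, short-term plasticity,
conductance (dynamic-clamp) effects and dendritic filtering — all noted
extension points. Passing the model-neuron checks therefore shows the
*machinery* is correct and the phenomenology (amplitude-, T-, N- and
rate-dependence of detection; the transient E-over-I sensitivity at
short integration windows for moderate N) is qualitatively reproduced;
it does not certify quantitative detection values for real cells.

## Problem sizes and numerical choices in the shipped tests

The test suite runs desk-scale versions of the study conditions chosen
once for statistical adequacy: 200 trains × 200 s for renewal
statistics; 200 s of OU noise; 10^6 amplitude draws; five independent
1024-neuron populations for the balance/scaling check; and model-neuron
runs of 10 episodes × 46 s at the 5 Hz condition plus 6 episodes each at
1 and 10 Hz, with sweeps pooled into 8 amplitude bins (4 adjacent
log-levels each) so that per-bin window probabilities rest on thousands
to hundreds of thousands of sweeps. Bootstrap checks use 100 trial sets
× 50 repetitions. PSTH bins default to 0.5 ms; the decoder grid defaults
to `T` from 0.4 to 15 ms in 0.4 ms steps and `N ∈ {250, 500, 1000,
2000}`.

## Known limitations

* The LIF stand-in lacks adaptation, conductance noise and
  spike-initiation dynamics of real pyramidal cells; detection latencies
  and the exact decay of the E/I asymmetry with `T` differ from recorded
  neurons (at moderate `N` the model's asymmetry fades more slowly).
* The ML gamma shape of generated trains is 2.077, not 2, by
  construction (see above).
* Detection estimates for the rarest amplitude classes rest on few
  sweeps at desk scale; pool classes (the `class_of` argument of
  `collect_sweeps()`) or add episodes for stable estimates.
* ATF export is minimal (header + time/current columns); ABF binary is
  out of scope.
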