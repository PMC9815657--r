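---
title: "Models and conventions behind gammasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind gammasig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammasig)
```

Gamma motor neurons innervate the intrafusal fibers of muscle spindles and
tune proprioceptive sensitivity; alpha motor neurons drive the force-generating
extrafusal fibers. The two types differ in a reproducible intrinsic
electrophysiological *signature* — gamma motor neurons combine low rheobase,
high frequency–current (F–I) gain and high firing rates, alpha motor neurons
the opposite — and perturbing the gamma signature degrades gait and precision
movements without touching muscle force generation. gammasig implements the
quantitative analyses with which such a dissociation is established:
intrinsic-property extraction from current-clamp step protocols,
marker-intensity statistics, OSC-PLS discriminant modelling of gait tables
with permutation validation, muscle-spindle afferent ramp-and-hold metrics,
and precision-task miss scoring. Every stage is paired with a synthetic
generator whose ground truth is known analytically, so the whole pipeline is
testable without any recordings.

This vignette documents the models, the conventions where acquisition
protocols leave choices open, and the design decisions that were genuinely
ours to make.

## The neuron generator and its calibration

The generator is deliberately *phenomenological*, not conductance-based.
Subthreshold dynamics are a first-order RC response with input resistance
$R_\mathrm{in}$ and time constant $\tau = R_\mathrm{in} C_m$; discharge obeys
a piecewise-linear F–I law

$$ f(I) = \begin{cases} g\,(I - I_\mathrm{rh}) & I > I_\mathrm{rh} \\ 0 &
\text{otherwise,} \end{cases} $$

with gain $g$ (Hz/nA) and rheobase $I_\mathrm{rh}$ (pA, currents converted to
nA inside the law). Spikes are stereotyped 2 ms biphasic waveforms (peak
+40 mV) inserted at regular $1/f(I)$ intervals, each followed by a
single-exponential afterhyperpolarization (AHP). A conductance-based model
would look more biological but would bury the ground truth under free
parameters; the piecewise-linear law makes gain and rheobase recovery *exact*
on noiseless data, which is what the recovery tests need. The suprathreshold
membrane depolarization is capped at the rheobase level — a neuron at
threshold spikes rather than depolarizing further — which keeps the
subthreshold baseline below the spike-detection threshold for any injected
current.

Presets (`calibrate_preset()`) transcribe published cohort summaries for
Fluoro-Gold-high (gamma) and Fluoro-Gold-low (alpha) motor neurons in control
and ERR2/3 conditional-knockout mice: rheobase, gain, firing frequency, input
resistance and capacitance, with their SEMs. Two derived conventions matter:

* **Reference current.** A linear F–I law cannot simultaneously honor the
  calibrated gain, rheobase *and* an arbitrary pairing of firing frequency
  with current, because real F–I curves saturate and the linear law does not.
  Each preset therefore carries the current at which its law attains the
  calibrated firing frequency, $I_\mathrm{ref} = I_\mathrm{rh} + f_\mathrm{ref}/g$,
  quantized to the 20 pA grid (540 pA for the control gamma preset, 1540 pA
  for the control alpha preset). Reported firing frequencies of a cohort are
  measured at that step.
* **Population jitter.** Cohorts draw each neuron's parameters log-normally
  around the preset mean, mean-preserving, with coefficient of variation 0.15
  (`jitter_cv`), so population SEMs are nontrivial while each neuron's ground
  truth stays exact.

AHP amplitudes and decay constants are package defaults (the published
summary prints none); they respect the reported ordering — faster AHP decay
in gamma than alpha motor neurons. The knockout presets reuse the matching
control passive constants, as input resistance was reported unaltered.

The step protocol is 20 pA increments of 1 s square pulses with 0.25 s
baselines at 20 kHz sampling, up to a ceiling of 1 nA for gamma-range and
3 nA for alpha-range recordings. First-spike latency is
$\min(1/2f,\,100\ \mathrm{ms})$, so any positive rate produces at least one
spike within the pulse and rheobase recovery is within one 20 pA step by
construction.

## Feature extraction conventions

Acquisition software computes these quantities with unstated settings; the
package exposes every choice:

* **Spike detection** (`detection_config()`): upward crossing of 0 mV with
  dV/dt above 10 mV/ms and a 2 ms lockout. These are defaults, not facts
  about the original protocol.
* **Firing frequencies**: *instantaneous* = inverse of the first inter-spike
  interval; *steady-state* = mean of reciprocal intervals whose midpoints lie
  in 0.25–0.75 s of the pulse (robust for irregular trains, reduces to the
  obvious value for regular ones); *mean* = (count − 1)/(t_last − t_first)
  over the full pulse, 0 below two spikes by convention.
* **Gain**: ordinary least-squares slope of frequency (Hz) on current (nA)
  over suprathreshold sweeps with a *defined* frequency (≥ 2 spikes); sweeps
  with a single spike are excluded rather than entered as 0, which would bias
  the slope.
* **Passive properties**: $R_\mathrm{in}$ is the OLS slope of steady-state
  deflection on current over spike-free sweeps; $\tau$ comes from the area
  method on the largest subthreshold onset relaxation
  ($\tau = \int (\Delta V_{ss} - \Delta V(t))\,dt / \Delta V_{ss}$, exact for a
  single exponential and robust to additive noise — no iterative fit to
  diverge); $C_m = \tau / R_\mathrm{in}$.
* **AHP**: measured on the first spike of the lowest suprathreshold sweep,
  where spikes are hundreds of ms apart; amplitude is baseline minus trough,
  half-decay the time from trough to half recovery (equal to $\tau_\mathrm{AHP}
  \ln 2$ for an exponential AHP).

## OSC-PLS gait modelling

Automated treadmill gait analysis yields ~58 partially redundant variables on
8–9 animals per genotype at 3 trials each — more variables than observations,
strong collinearity. The package fits partial least squares (PLS1, NIPALS
with deflation) to the centered −1/+1 genotype response after an orthogonal
signal correction (OSC) step that removes, from the centered-scaled
predictors, `n_osc` directions of maximal variance whose score vectors are
orthogonalized against the response. Removed scores satisfy
$|t^\top y| \le 10^{-8}$ by construction; prediction on new rows applies the
stored OSC weights and loadings before the PLS regression vector.

Conventions and open choices, fixed as follows:

* `n_osc = 1` by default (the original component count is unstated); 2 PLS
  components form the reported model.
* Scaling uses the sample (n−1) SD, recorded in the scaling state;
  zero-variance columns are dropped with a warning.
* The permutation null permutes genotype labels across *animals* (the
  standard chemometrics null; jointly permuting predictor rows is available
  behind `permute = "rows"`).
* The 2/3–1/3 resampling is stratified *at animal level*: all trials of an
  animal stay in the same fold, preventing leakage between train and test via
  animal identity. The original analysis is silent on this; trial-level
  splitting would flatter Q2.
* Comparing one model's Q2 to a permuted *distribution* is not a two-sample
  test, so `oscpls_validate()` runs a matched non-permuted resampling in
  parallel and performs genuine two-sample t tests (Q2 and RMSEP), and
  additionally reports the full-data model's position in the permuted
  distribution as a z-score.
* Leave-one-out Q2 re-estimates scaling, OSC and PLS inside every fold; a
  fold whose training response is constant falls back to the mean predictor.
* Signed loadings are ranked by magnitude on component 1; the sign convention
  is "positive = increased in the second group level" (the mutant, with
  groups sorted alphabetically).

The gait generator plants a rank-`latent_rank` animal-level factor structure
(inducing the collinearity that motivates PLS), standardized mean shifts on a
known informative subset for the mutant group, and trial-level noise. It does
*not* emulate variable-specific units, scale heterogeneity, or real gait
covariance structure — passing tests show the machinery recovers planted
structure under collinearity, not that any particular biological gait
variable matters.

## Spindle afferent analysis

The stretch generator drives an afferent rate model
$r(t) = \mathrm{RD} + k_\mathrm{dyn} \max(\dot L, 0) + k_\mathrm{static}\,
\Delta L(t)$ with the standard ramp-and-hold protocol (2.5/5/7.5% of resting
length $L_o$ at 40% $L_o$/s; series of nine = three repeats per amplitude).
Spikes arise by deterministic integration of $r(t)$ with spikes at
half-integer crossings of the integral — so a constant rate $r$ yields
exactly $r$ spikes per second and the count over any window equals the
integral of $r$ within ±1 — or by an inhomogeneous Poisson process via
time rescaling. The tension channel is affine in length: tension is displayed
alongside recordings but not analyzed, so no cross-bridge model is warranted.

Metric conventions (`ramp_hold_metrics()`), chosen where the original custom
analysis code is unavailable and flagged prominently:

* **RD** — spike count over the full pre-ramp baseline (≥ 2 s) divided by its
  duration; afferents are classed above/below 2 Hz resting discharge.
* **DP** — maximum reciprocal-ISI rate among intervals overlapping the ramp.
  A binned peak would depend on bin width; the reciprocal-ISI peak's only
  error is rate quantization (about one ISI's worth of rate change,
  $\approx (dr/dt)/\mathrm{DP}$, for a linearly rising rate).
* **DI** — the classical dynamic index: DP minus the instantaneous rate 0.5 s
  after ramp end.
* **SR** — mean reciprocal ISI over a 1.0–2.0 s post-ramp plateau window.

Raw-signal spike detection (`detect_afferent_spikes_kmeans()`) thresholds at
4× the MAD-based noise SD, describes each candidate by peak, trough and
width, and 2-means-clusters the features; the higher-amplitude cluster is the
unit. Two guards handle degenerate cases: a homogeneous candidate set is
accepted only if its mean peak clearly exceeds the threshold (noise crossings
concentrate just above it), and a single candidate falls back to the
threshold decision with a warning. Which features the original detector
clustered is unstated; peak/trough/width is the minimal standard set.

## Behavior scoring

Per-trial miss counts are negative-binomial with the published group means
and a free dispersion parameter (`size` = 10 by default; the published
summaries give only means ± SEM, so inter-trial dispersion is genuinely
unidentified — the default reproduces SEMs of the right order). Aggregation
is trials → animal → group, because the published N counts animals; SEMs are
across animals. `steps` counts miss *opportunities* (paw placements, ~4 per
stride over the ~40 strides analyzed per trial): with ~40 strides the
published 79 misses/trial would violate `misses <= steps` if steps counted
strides. Fold changes divide the mutant group mean by the control group mean
and are therefore exactly the published 18/55/79 (beams) and 7.12 (ladder)
ratios when evaluated on the packaged fixture.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and uses it for all
randomness; identical inputs give bit-identical outputs. The shipped checks
simulate cohorts of 24 (gamma-range) and 22 (alpha-range) neurons at 20 kHz —
the published cohort sizes — and validation runs of 100 permutation repeats
on tables of 51 × 58 (9 + 8 animals × 3 trials), with smaller configurations
in unit tests. Null-Q2 calibration averages 100 generator seeds.

## Known limitations

* The neuron generator's F–I law does not saturate; firing frequencies far
  above the reference current overestimate those of real neurons. Published
  cohort means are reproduced at the calibration points, not across the whole
  F–I curve.
* Real intrinsic-property distributions (alpha subtypes form a continuum from
  slow to fast) are modelled as a single log-normal jitter around the preset
  mean.
* The gait generator's covariance is synthetic; loadings recovered from it
  validate the algebra, not gait biology.
* DP/DI depend on the stated window conventions; published numeric values of
  these metrics from other window definitions are not expected to match
  exactly.
* The k-means detector assumes one unit per recording.

## A compact worked example

```{r example, eval = FALSE}
library(gammasig)

# simulate and extract a small gamma-range cohort
cohort <- extract_cohort("gamma_control", n = 6, seed = 1)
mean(cohort$gain_hz_na)

# gait: planted effect, model, validation
tbl <- simulate_gait_table(gait_sim_config(n_informative = 5), seed = 1)
fit <- oscpls_fit(tbl)
glance(fit)
head(tidy(fit))
val <- oscpls_validate(tbl, n_repeats = 100, seed = 1)
glance(val)

# spindle metrics on a generated ramp-and-hold trial
trial <- simulate_stretch_trial(spindle_sim_config(), amplitude = 0.05)
ramp_hold_metrics(trial)

# behavior fold changes on the packaged published means
fold_change(behavior_means(), "beam_30mm", mutant = "err23cko")
```
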