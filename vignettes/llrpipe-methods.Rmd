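---
title: "Quantifying stretch-evoked long-latency reflexes during fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stretch-evoked long-latency reflexes during fMRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llrpipe)
```

## The measurement problem

A long-latency reflex (LLR) is the stereotyped burst of muscle activity that
appears 50–100 ms after a joint is rapidly stretched. Because LLR amplitude is
modulated by brainstem and cortical circuits, evoking LLRs with a robot while
recording blood-oxygenation (BOLD) signal is a way to image the neural
pathways behind them — if the muscle response can be measured reliably inside
the scanner. Surface EMG recorded in a static magnetic field is corrupted by
motion-induced artifacts: sub-millimeter electrode movement changes the flux
through the electrode leads and induces voltages 5–10× larger than the reflex
itself. Gradient and RF noise can be avoided by reading EMG only in a silent
window after each volume acquisition, but motion artifacts occur exactly when
the robot moves the hand, overlapping the reflex in both time and frequency.

`llrpipe` implements the computational chain for this paradigm:

1. a synthetic-data module that generates perturbation protocols, EMG with
   known clean signal and motion artifacts, and BOLD phantoms with known
   effect maps;
2. EMG processing that turns raw trial windows into normalized LLR
   amplitudes under three filtering pipelines (STD, SUB, ANC);
3. the ANC filter itself: an adaptive network-based fuzzy inference system
   (ANFIS) trained per trial to estimate the artifact from a co-located
   reference channel;
4. agreement statistics that validate in-scanner measurements against
   out-of-scanner references;
5. a voxelwise GLM of BOLD signal with muscle-specific,
   amplitude-modulated regressors; and
6. test–retest reliability metrics (Sørensen–Dice overlap and ICC(3,1)).

## Signal model and the three filtering pipelines

The measurement electrode sees `y = x + w`: clean EMG `x` plus a motion
artifact `w`. A reference electrode, co-located but insulated from the
muscle, sees only a transformed version `r` of the same interference. Because
the two channels do not have identical transfer characteristics, `w` and `r`
are related nonlinearly, so:

* **STD** ignores the artifact: `x̂ = y`;
* **SUB** assumes the channels match: `x̂ = y − r`;
* **ANC** learns the mapping: `x̂ = y − f̂(r, ṙ, θ)`, where `θ` is the robot
  encoder angle and `f̂` is trained per trial.

All three share the same surrounding pipeline: segment the 200 ms silent
window starting at perturbation onset; band-pass 20–250 Hz (4th-order
Butterworth); apply the filter; rectify and low-pass at 60 Hz to form the
envelope; normalize by the mean contraction envelope; and integrate the
envelope over 50–100 ms (time in ms), giving the LLR amplitude `H` in units
of normalized-EMG·ms.

Filters are applied zero-phase (forward–backward). The direction of that
choice matters: a causal 4th-order Butterworth delays a 20–250 Hz burst by
several milliseconds, which would shift activity across the hard [50, 100] ms
window boundary; zero-phase filtering preserves burst latency at the cost of
doubling the effective order. Trapezoidal integration is used for the
amplitude integral; on the 2 kHz default grid its `O(Δt²)` error is far below
every tolerance used in the tests. The [50, 100] ms window is treated as
closed at both ends, and sample `k` maps to time `k/fs` with the first sample
at perturbation onset.

The normalization constant is the mean STD-pipeline envelope over the central
3 s of each isometric contraction block in which the muscle is active
(flexion for FCR, extension for ECU), averaged across blocks. Contractions
are isometric — no robot motion, hence no appreciable artifact — so using the
STD pipeline there keeps the constant method-independent.

## The ANFIS noise canceller

`f̂` is a first-order Takagi–Sugeno fuzzy system on the three inputs
`(r, ṙ, θ)`. Each input is covered by generalized-bell membership functions
placed by grid partition over the observed range; every combination of
membership functions forms a rule whose consequent is linear in the inputs.
Training is hybrid: per epoch, the rule consequents are solved by linear
least squares given the current premises, then one normalized-gradient step
(analytic backpropagation of the squared error) updates the premise
parameters, with the classic adaptive step-size schedule (increase ×1.1
after four consecutive error drops, decrease ×0.9 on oscillation).
Overfitting is controlled by holding out one contiguous random interval
(default 20% of samples, redrawn each epoch) and finally restoring the
parameters from the epoch with minimum validation error.

Two numerical choices deserve note. First, the default grid is **2
membership functions per input** (8 rules, 32 consequent coefficients). A
200 ms trial at 2 kHz supplies ~320 training samples; a 3-MF grid (27 rules,
108 coefficients) leaves many rules nearly unfired, the least-squares system
ill-determined, and the fitted consequents free to explode on the held-out
interval — in our experiments the 27-rule model was reliably *worse* than no
filtering at all, while the 8-rule model removes most of the artifact. The
rule of thumb enforced by a training message is at least ten samples per
rule. Second, when the least-squares system is ill-conditioned (rules that
barely fire), consequents are solved by a column-scaled ridge fallback that
shrinks weakly determined coefficients toward zero rather than letting them
blow up between epochs.

When the artifact is affine in the inputs, the least-squares step alone is
exact: the trained filter matches ordinary least-squares regression to
machine precision, which the test suite uses as an oracle. One model is
trained per trial segment, since the artifact depends on the (changing)
position of the electrode leads in the static field.

## What the synthetic data emulate — and what they do not

The protocol generator reproduces the study design: 60 ramp-and-hold
perturbations per session (3 speeds × 2 directions × 10 repetitions,
seeded pseudo-random order), hold times uniform in 400–800 ms, rests of
7–10 s plus robot return and 4 s post-return rest, TR 1.225 s with a 225 ms
silent window, every onset snapped to 25 ms after a volume completes so the
200 ms analysis window fits inside the silent window, and ten interleaved
5 s isometric contractions (500 mNm) before the sequence.

Clean EMG is band-limited (20–250 Hz) Gaussian noise amplitude-modulated by
a burst envelope: tonic background (2% of the contraction level), a
short-latency burst in 25–50 ms, and an LLR burst in 50–100 ms whose area is
`llr_gain · |v| · (1 + ε)` with `ε ~ N(0, llr_cv²)`, `llr_gain = 0.5`
normalized-EMG·ms per deg/s and `llr_cv = 0.2` (a typical trial-to-trial
coefficient of variation for stretch reflexes). Shortening-side bursts are
attenuated to 20%. Because bursts, background and contraction blocks all ride
on the same carrier construction, the rectification constant cancels in
normalization and the ground-truth envelope area has a closed form.

Motion artifacts follow a physically motivated chain: a shared motion source
(low-pass-filtered encoder velocity of a minimum-jerk ramp, plus
motion-gated broadband jitter) passes through two *different* memoried
nonlinearities — `P_w(m) = m + 0.3 m³` smoothed at 50 Hz for the measurement
channel and `P_r(m) = 0.8 m + 0.2 m²` smoothed at 70 Hz for the reference —
so the channels correlate above 0.9 yet differ enough that subtraction
leaves a substantial residual. The artifact peak is five times the typical
LLR envelope peak, the middle of the 5–10× range observed with scanner
recordings. Setting `artifact_gain = 0` produces mock-scanner ("OUT")
sessions.

What the generator does **not** model: gradient/RF noise (excluded by design
through the silent window), electrode impedance drift, habituation,
task-dependent LLR gain modulation, and any dependence of the artifact on
absolute scanner-bore position. Passing the ranking tests on these synthetic
sessions therefore shows that the pipeline removes *this class* of
nonlinear, reference-observable artifact — it cannot certify performance on
every real-scanner artifact morphology.

BOLD phantoms place two disjoint spherical clusters (one per muscle) in a
small voxel grid; each voxel's series is the sum of the two
amplitude-modulated regressors (built exactly as in the analysis model),
a baseline, and AR(1) noise (lag-1 correlation 0.3 by default). The cluster
effect size is calibrated so the expected peak *t* under white noise is 8,
giving thresholded maps that are near-ceiling sensitive — deliberately, so
recovery failures indicate pipeline defects rather than power limits.

## GLM, thresholding and reliability

Regressors of interest are rectangular pulses (50 ms duration, 50 ms after
each perturbation onset, height equal to the trial's LLR amplitude) on a
5 ms microtime grid, convolved with a double-gamma HRF and sampled at volume
onsets. Two HRF parameter sets are provided: the standard cortical response
(peak delay 6 s, undershoot delay 16 s, ratio 6) and a faster brainstem
variant (4.5 s, 10 s, ratio 15); both use 1 s dispersions and a 32 s kernel,
normalized to unit peak. High-pass filtering is implemented as
discrete-cosine confound columns up to a 128 s cutoff
(order `floor(2T/128)`); session concatenation replaces the intercept with
per-session mean columns. Estimation is ordinary least squares; with AR(1)
phantom noise the residual autocorrelation is ignored, which mildly
miscalibrates degrees of freedom — acceptable here because the error-control
tests use white noise, and noted as a limitation for real data (where
prewhitening would be standard).

Thresholding supports uncorrected *p* and Bonferroni over the mask voxel
count, plus a 6-connected cluster-extent filter; random-field-theory FWE is
deliberately out of scope (for these data the two thresholds are nearly
identical). Reliability between two sessions is summarized by the
Sørensen–Dice overlap of thresholded maps, `S = 2V_o/(V_1+V_2)`, and by the
two-way mixed-effects consistency ICC, `ICC(3,1) = (BMS−EMS)/(BMS+EMS)`,
with voxels (participant level) or subjects (group level) as random targets
and session fixed. The consistency form ignores additive session effects by
construction; the tests verify its algebraic equivalence to the
ANOVA decomposition and to the two-column closed form
`BMS = 2·var(row means)`, `EMS = var(diff)/2`.

## Agreement statistics

Group-level agreement between an in-scanner table and the out-of-scanner
reference uses paired Bland–Altman analysis of per-cell mean amplitudes
(participant × muscle × velocity, stretch and shortening handled
separately): bias, 95% limits of agreement (`bias ± 1.96 sd`), and t-based
confidence intervals (`± t·sd/√n` for bias, `± t·sd·√(3/n)` for each
limit). Method effects on bias are tested by z-tests on the bias estimates
with Bonferroni correction. Because limits of agreement are intervals, their
concordance with the reference comparison is scored by the Jaccard index
(intersection over union), with a bootstrap that redraws every interval
endpoint from `Normal(estimate, SE)` independently — endpoint covariance is
not modeled, matching the interval-by-interval construction.

Perturbation-level deviations are standardized z-scores against the matched
reference cell (same participant, muscle, velocity; sample SD of the 10
reference trials), and variance homogeneity across filtering methods is
tested with Bartlett tests.

**A known small-sample property:** standardizing against a mean and SD
estimated from only `n = 10` reference trials inflates the z dispersion by
`√((1 + 1/n)·(n−1)/(n−3)) ≈ 1.19`; the z-scores behave like a scaled
`t`-variable, not a standard normal. Self-standardization is still exactly
mean 0 / SD 1 within each cell (an algebraic identity), but between-session
dispersions should be compared against ≈1.19, not 1, when reference cells
are this small. The package reports dispersions as computed and leaves the
interpretation to the analyst.

## Problem sizes and reproducibility

All stochastic stages draw from named substreams of a single root seed, so
every table, model and phantom regenerates bit-identically. The test suite
and acceptance script size their simulations to what the statistics need:
20 replicate sessions for the method-ranking property, ≥10⁵ pooled null
voxel tests for the false-positive calibration, 2000 replicates for the
Bartlett type-I check, and 4-participant studies for the end-to-end
agreement replica. Those sizes are choices of statistical resolution, not of
the phenomena being modeled; all scale up linearly through the same
functions.

## Known limitations

* The ANC filter is trained per trial with ~400 samples; models with more
  than ~10 membership functions per input cannot be identified from a single
  trial and are rejected in practice by the validation criterion.
* OLS estimation without prewhitening slightly mis-states *t* degrees of
  freedom under autocorrelated noise.
* The zero-artifact equivalence of the three filtering methods is exact for
  STD vs SUB; ANC can absorb up to ~1–2% of clean-signal variance through
  its encoder-angle input even when the reference channel is silent.
* Atlas-based ROI construction, spatial normalization and random-field
  corrections are out of scope; ROI masks are user-supplied label volumes.
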