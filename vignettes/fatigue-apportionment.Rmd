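---
title: "Apportioning performance fatigue from EMG and isokinetic power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apportioning performance fatigue from EMG and isokinetic power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpet)
```

## The problem and the model

During heavy constant-power cycling, the task becomes intolerable when the
maximal power a person can still produce falls toward the power the task
demands. `mcpet` implements the measurement model used to split that loss of
maximal power into two mechanistically different parts, using only surface
EMG and an instrumented isokinetic ergometer:

* **Performance fatigue (PF)** — the total drop in maximal evocable
  isokinetic power (single-leg W) from the fatigue-free baseline maximum to
  a ~5 s maximal effort at the limit of tolerance.
* **Activation fatigue (AF)** — the part of PF explained by a reduced
  maximal evocable muscle activity. At a fixed contraction velocity
  (70 rpm isokinetic), power is linear in EMG amplitude; a baseline session
  of eight variable-effort bouts (25/50/75/100% of maximum, each twice)
  establishes `P = slope * frEMG + intercept` by ordinary least squares.
  AF is the EMG drop mapped through that slope:
  `AF = slope * (frEMG_baseline_max - frEMG_end)`.
* **Muscle fatigue (MF)** — the residual deficit in power at the measured
  muscle activity: `MF = max(0, PF - AF)`. The clamp at 0 W is the only
  clamp in the decomposition; AF is reported unclamped (it can be negative
  if end-exercise EMG exceeds the baseline maximum, and that is worth
  seeing, not hiding).

Fractional EMG (`frEMG`) is a four-muscle composite (vastus lateralis,
rectus femoris, vastus medialis, lateral gastrocnemius): each muscle's
per-revolution peak of the 200-sample RMS envelope is normalized to that
muscle's **visit maximum**, and the four fractions are averaged. P_iso is
the left-crank power averaged over three consecutive well-constrained
isokinetic revolutions, paired with the mean of the same three revolutions'
EMG composites. Chainring (whole-body) power is reported as twice one-leg
power; PF/AF/MF are single-leg watts while the **power reserve**
(chainring P_iso at intolerance minus task power) uses chainring watts —
the two conventions are internally consistent with the group values the
method was designed around (342 W single-leg = 684 W chainring; a ~190 W
end power against a ~193 W task leaves a ~200 W reserve).

Alongside the neuromuscular decomposition, the package computes the
operating lung volumes that index **dynamic hyperinflation** under
expiratory loading: inspiratory capacity (IC, mean of duplicate
manoeuvres), the tidal volume matched to each manoeuvre (VT, the 20 s mean
preceding it), and the inspiratory reserve volume `IRV = IC - VT`.

## Signal-processing choices

* **Filter.** Fourth-order (prototype order) Butterworth band-pass,
  10–500 Hz at 2000 Hz sampling, designed by bilinear transform with
  pre-warping and applied forward–backward. Zero-phase filtering is a
  package choice: peak timing must stay aligned with crank angle, and the
  acquisition convention specifies only the filter family and order. The
  500 Hz edge sits at half Nyquist; if an upper edge at or above Nyquist is
  requested it is clipped to 0.99 × Nyquist with a warning. The sensors'
  own 20–450 Hz bandwidth makes the numerical position of that edge
  immaterial.
* **RMS window.** Exactly 200 samples, trailing (causal) alignment:
  element *i* is the RMS of the window ending at *i*. The alignment is not
  specified by the acquisition convention; trailing is the default and a
  centred option is provided (`rms_envelope(align = "center")`). The first
  199 elements use the partial window.
* **Revolution segmentation.** One revolution per contiguous 360° of
  cumulative crank angle from the first sample; trailing partial
  revolutions are dropped. Revolution power is energy over duration
  (equal-angle samples are not equal-time), which reduces to the plain mean
  of torque × angular velocity at constant cadence.
* **Revolution selection.** Three *consecutive* revolutions in isokinetic
  mode with mean cadence within ±5% of the 70 rpm target ("appropriately
  constrained" is not quantified upstream; 5% is the package default and
  configurable). Among qualifying runs the one with the highest mean
  left-crank power is used — the intent of the manoeuvre is a maximal
  effort — with ties going to the earliest run.
* **Visit maximum.** Per muscle, the maximum per-revolution RMS peak over
  *all* isokinetic bouts of the visit, baseline efforts and the
  end-exercise effort alike. This reconciles the two normalization
  statements in the acquisition conventions (baseline-phase maximum vs.
  visit maximum); they differ only when end-exercise EMG exceeds every
  baseline bout, in which case the visit maximum keeps fractions in (0, 1].

## The synthetic world

The generator states a world in which every downstream stage is testable
against known truth; its defaults are the group conditions the pipeline is
designed around, and they are not tuned per test.

* **EMG–power coupling.** Per participant, a true line
  `P = slope * frEMG + intercept` with `slope = p_iso_max` (intercept 0 by
  default) and `p_iso_max ~ Normal(342, 108) W` (single leg, floored at
  150 W). Per revolution, EMG amplitude is
  `(P - intercept)/slope * (1 + eps)`, `eps ~ Normal(0, baseline_r2_noise)`
  shared across the four muscles of that revolution. Crank torque is
  noise-free (the instrumented crank's <3% uncertainty is small against
  EMG variability and would only dilute the stated r² target).
* **Noise calibration.** The stated world requires the session-level fitted
  r² to average 0.96. With efforts `e = {0.25, 0.5, 0.75, 1}` twice and
  bout-level noise SD `s` (the per-revolution SD divided by √3, three
  revolutions per bout), the asymptotic squared correlation is
  `Var(e) / (Var(e) + s² E[e²])`, giving `s = 1/12` (per-revolution
  SD √3/12 ≈ 0.144). But an 8-point sample r² is upward-biased: the full
  generator + fit path then averages 0.970. The default
  `baseline_r2_noise = 0.167` was therefore calibrated numerically on the
  generator itself (5000 sessions; mean fitted r² = 0.960).
* **Fatigue kinetics.** Only endpoint fatigue is reported by the study
  design this emulates, so within-trial trajectories are generator choices,
  not physiological claims: the maximal evocable EMG fraction declines
  linearly (`1 - af_rate * t / slope`) and the muscle power deficit grows
  linearly (`mf_rate * t`). Defaults `af_rate = 0.21`, `mf_rate =
  0.057 W/s` reproduce the printed endpoint magnitudes (AF ≈ 102 W at
  487 s; MF ≈ 33 W at 575 s) for a mean-capacity participant. Rates scale
  with each participant's relative capacity so the EMG fraction trajectory
  is cohort-wide and power reserves stay positive and ~200 W in the mean.
* **Tolerance times.** Control ~ Normal(575, 137) s (floored at 60 s with
  logged redraws); the same participant's resistance trial lasts
  487/575 ≈ 0.847 of their control draw; the isotime-control trial is the
  control condition truncated at the resistance duration (ending by
  protocol, its cadence never shows the sub-60 rpm dwell). The expiratory
  load itself (7 cmH2O/L/s) enters the generator only through this time
  factor, the IRV decline rate, the tidal-volume plateau and the Borg
  growth rates — no airway mechanics are simulated.
* **Maximal-effort variability.** The delivered end-exercise maximal power
  varies by a 3% CV (`end_effort_noise`) around the true evocable power.
  Without it, paired PF and power-reserve differences between resistance
  and isotime-control would be *exactly* zero-variance (crank power being
  noiseless), and the paired t-test on them undefined — a degenerate, not
  conservative, world.
* **Lung volumes and symptoms.** IRV declines linearly from 2.6 L at
  0.0038 L/s (control) or 0.0049 L/s (resistance), floored at 0.05 L;
  tidal volume rises exponentially (τ = 120 s) to 2.9/3.2 L; the measured
  IC is `IRV_true + VT_true` plus Normal(0, 0.05 L) manoeuvre noise, in
  duplicate at baseline, isotime and the limit of tolerance. Borg CR-10
  ratings grow linearly and are rounded to 0.5.
* **Raw carriers.** Raw EMG is one burst per revolution (flat plateau of
  20% of the revolution — longer than the 200-sample RMS window — with
  raised-cosine tapers). The default carrier is band-limited (20–450 Hz)
  Gaussian noise, rescaled per burst so the trailing-RMS peak equals the
  requested amplitude exactly before filtering; the noise-free limit
  switches to a deterministic 150 Hz tone, for which 200 samples at
  2000 Hz cover an integer number of periods and the RMS peak equals the
  amplitude to discretization error. That is what makes the end-to-end
  noise-free recovery contract (< 1 W) meaningful. Within-revolution torque
  is a raised sinusoid with two peaks per revolution; only its revolution
  mean is contractually meaningful.

## What a green test does and does not establish

The generator emulates linear EMG–power coupling with multiplicative
scatter, endpoint-calibrated linear fatigue kinetics, and clean trial
structure. It does **not** emulate electrode artifacts, left–right
asymmetry, cadence drift inside bouts, breath-by-breath noise,
expiratory-flow limitation mechanics, or the coupling between a critical
IRV and the decision to stop. Two consequences worth knowing:

* **AF estimator bias.** With session scatter at r² = 0.96, the
  decomposition's AF estimate is biased upward by roughly
  `slope * sd_bout/√π` (the baseline maximum point is the larger of two
  noisy 100%-effort points) minus an errors-in-variables slope attenuation
  of ~(1 − r²) × AF — net ≈ +14 W on a ~120 W AF, with the opposite bias
  absorbed by MF. This is a property of the measurement model itself, not
  of this implementation: the noise-free suite recovers truth to < 1 W,
  and PF (built from measured powers only) stays unbiased to < 5 W. Paired
  *condition comparisons* of AF are unaffected in expectation because the
  bias is common to both visits.
* **Mean IRV at the resistance limit.** With fixed per-condition decline
  rates, between-participant tolerance spread puts the cohort mean IRV at
  the resistance limit near 0.4 L rather than the ~0.19 L group value the
  design targets; reproducing the latter would require participants to
  quit near a critical IRV (rate–time coupling), which the stated
  fixed-rate world deliberately excludes. Delta signs and condition
  ordering are unaffected.

As a printed-consistency observation (not a computed result): the paired
designs this mirrors report CIs whose midpoints match the mean differences
— e.g. a (52, 125) s interval about an 88 s tolerance-time difference —
which is the symmetry `paired_t()` guarantees by construction.

## Numerical and degenerate-input choices

* OLS by explicit normal equations; a non-positive fitted slope or zero
  EMG spread rejects the session. r² is the squared Pearson correlation.
* `IRV = IC - VT` is never clamped; negative values are flagged
  (`negative_irv`), as are single (`single_replicate`) and discordant
  (>10% of the mean) IC duplicates — the reconciliation rule (mean) is a
  package choice.
* The intolerance timestamp is the *start* of the first continuous sub-60
  rpm dwell of ≥ 5 s, scanned on a ≥ 1 Hz cadence series; a trial ending
  while still below threshold counts if the recorded dwell reaches 5 s.
* Zero-variance paired differences and zero-variance correlates raise
  validation errors rather than returning NaN; `study_report()` converts
  them (and comparisons with < 3 complete pairs) into per-endpoint notes
  with listwise deletion, always printing the per-comparison n.
* All tables are plain delimited text written at fixed precision (0.01 W,
  0.01 L, 0.1 s, 1e-4 mV) so diffs are reproducible; readers auto-detect
  comma vs. tab.

## Known limitations

Beyond the generator caveats above: no artifact/electrode-quality
diagnostics, no frequency-domain fatigue indices, no flow–volume loop or
expiratory-flow-limitation analysis, no absolute EELV/TLC estimation, no
multi-condition ANOVA (mirroring the two-condition paired design), and the
CLI handles the package's own table schemas, not device-native formats.
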