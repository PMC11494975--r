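---
title: "Models and design choices in neuromove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in neuromove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neuromove)
```

`neuromove` analyses synchronized brain–movement recordings from two
upper-limb functional tasks — paced reaching and circular steering — in
healthy and post-stroke cohorts, and ships a synthetic generator so the
whole pipeline can be validated against known ground truth. This vignette
explains the models, the tunable parameters and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Block design and time conventions

Both tasks alternate 20 s of task with 20 s of rest; reaching adds five
movement cues per task block at 4 s spacing ("go" 2 s, "stop" 2 s). The
protocol default is three blocks per (task, hand, condition) cell. Time
zero is the first task onset, so three blocks span 120 s; signal
generators start at `-pre_roll` (default 5 s) so that pre-onset baselines
exist for the first block, as they would in a real recording started
before the first cue.

## Kinematics

Trunk anterior flexion is the angle of the spine-base → shoulder-center
vector to the vertical, projected into the sagittal plane (0° upright,
positive forward). The elbow angle is the interior angle at the elbow
between the shoulder and wrist segments (180° = full extension). Ranges
are max − min within each 2 s outward-reach window — min/max rather than
percentile ranges, matching the "range of" definition of the construct —
averaged over reaches, then blocks. Because broadband sensor jitter
inflates min/max ranges and frame-to-frame velocities, `reach_metrics()`
first applies a zero-phase 2 Hz low-pass (`smooth_skeleton()`,
configurable, `NULL` disables): functional reaching lives below ~1.5 Hz,
so the signal is untouched while jitter extremes shrink by roughly the
square root of the retained bandwidth.

Arm use is the share of forward (anterior) hand displacement not produced
by the trunk: `AU = 100 · (Δz_hand − Δz_acromion) / Δz_hand` per outward
reach, and `PANU = AU_MAU − AU_SAU` per subject and hand. The construct —
what the arm could contribute versus what it spontaneously does — is
isolated behind `panu()` so an alternative operationalisation can be
swapped in. Reaches with non-positive forward hand displacement are
excluded from AU; negative PANU is allowed but flagged.

For steering, the cursor's polar coordinates about the circle center give
the mean radius `R`, radial dispersion `sigma`, effective width
`We = sqrt(2*pi*e)*sigma`, difficulty `IDe = 2*pi*R/We` (bits), and
performance `IPe = IDe/MT` (bits/s). `MT` is the time per lap: laps are
counted from the unwrapped angle, fractional laps included, because 20 s
trials rarely end on a lap boundary, and `IPe` in bits/s requires the
per-lap time (the trial-level speed variable is itself reported as time
per lap). Degenerate inputs follow explicit contracts: a numerically
perfect circle yields `We = 0` and undefined (`NA`, never infinite)
`IDe`/`IPe`; zero laps yield undefined `MT`. Clockwise is the negative
mathematical direction in the internal (y-up) frame.

## fNIRS

Concentration changes solve the modified Beer–Lambert system
`ΔOD(λ) = [ε_HbO2(λ) ΔHbO2 + ε_HbR(λ) ΔHbR] · d · DPF` per channel, with
wavelengths 760/850 nm, source–detector distance d = 30 mm and DPF = 6.0
for both wavelengths. Neither the extinction table nor the DPF is
instrument-specific here; both are standard compiled values and
config-overridable.

Channel QC rejects channels whose implied raw-intensity coefficient of
variation (`exp(-ΔOD)`) exceeds 15%. Motion-artifact spike interpolation
is off by default for synthetic data and available for imported
recordings. The event-related band-pass is a 3rd-order zero-phase
Butterworth at **0.01–0.08 Hz**. The upper corner was placed below the
Mayer-wave band (≈ 0.08–0.12 Hz) deliberately: with a 0.1 Hz corner about
half the Mayer power passes, and because the block summary is a *maximum*
(peak ΔHbO₂), any residual ripple biases it upward rather than averaging
out. The 40 s block-cycle fundamental (0.025 Hz) and its first harmonics
pass with gain ≈ 1 either way. Signals are demeaned before filtering so a
constant offset cannot leak through filtfilt edge transients at the very
low high-pass corner.

Block averages span −2…+20 s around task onsets with a −2…0 s baseline
subtraction (the analysis names a peak but no windows; these are the
natural choices for a 20 s block), and the summary is the maximum of the
averaged ΔHbO₂ in 0…20 s. Two properties of this convention matter when
comparing against injected amplitudes: the baseline window sits in the
undershoot of the previous block, so peak-minus-baseline slightly exceeds
the true peak (≈ +5% for the canonical response), and the maximum of a
noisy average is biased upward by the residual noise envelope (≈ +5–10%
at a 1 µM response under the default noise model). Both are inherent to
"peak relative to local baseline" and are documented rather than
corrected, and the recovery tests bound their combined size.

Hemisphere roles: the hemisphere opposite the moving hand is
*contralateral*; for stroke subjects the lesioned hemisphere is
*ipsilesional* (identical to contralateral when the paretic hand moves).

## fEEG

The spectral estimator is a sliding 1 s Hann short-time spectrum with 90%
overlap over 1–40 Hz — simpler than wavelets and adequate for band means;
the estimator sits behind `ersp_spec()` and is pluggable. The baseline is
the mean rest-period power per frequency and channel, taken from each
rest interval trimmed by 6 s at the start (so post-movement
synchronization cannot leak into it) and 2 s at the end.

Two averaging choices are deliberate and worth stating precisely, because
the naive alternatives are biased:

- The ERSP map averages epoch *powers* first and takes
  `10·log10(P/B)` second. The mean of per-epoch dB values lies below the
  true power ratio by `(psi(n) − log n)·10/log 10` for n epochs
  (≈ −0.76 dB at the protocol's three blocks) because `E[log X] < log E[X]`.
- Band ERD/ERS summaries likewise average map cells in the power domain
  and convert once. They also use only spectral frames whose full 1 s
  support lies inside the requested time window: frames straddling a
  window edge mix baseline and modulated power and dilute the estimate
  toward 0 dB.

Windows: movement is 0–2 s after each reach cue (the "go" phase) or the
whole 20 s steering interval; post-movement (ERS) is 2–4 s after each cue
for reaching and 0–4 s after task offset for steering. The analysis
definitions leave the ERS latency open (between-block rest versus fixed
post-movement latency); both windows are configurable in
`erd_ers_windows()` and the resolved choice is written into the pipeline
manifest. ERD is expected ≤ 0 and ERS ≥ 0 but signs are never clamped.

Preprocessing is a zero-phase 1–40 Hz band-pass, optional common-average
reference (the default; a ratio statistic like ERSP is insensitive to the
common-mode scale change), and block-level artifact rejection at 100 µV
with an error once more than half the blocks are lost.

## Synthetic data: what it emulates and what it does not

The generator realises the acquisition design at two levels.

*Signals level.* Every (task, hand, condition) cell of every subject
becomes full streams: a rigid-segment skeleton (trunk 500 mm, upper arm
300 mm, forearm 260 mm — adult-scale constants recorded in the profile)
executing minimum-jerk cued reaches with Gaussian joint jitter (1 mm
default); a cursor advancing clockwise at the injected lap rate with
Gaussian radial noise; optical densities built from a canonical
double-gamma HRF (peak 6 s, undershoot 16 s) convolved with the task
boxcar, plus sinusoidal cardiac (~1.1 Hz), respiratory (~0.3 Hz) and
Mayer (~0.1 Hz) components, linear drift and white noise, pushed through
the same extinction matrix the analysis inverts; and EEG as 1/f
background plus band-limited alpha/beta oscillators whose power is
multiplied by `10^(ERD/10)` in movement windows and `10^(ERS/10)` in
post-movement windows. Physiological component frequencies get a small
per-channel jitter because real rhythms are not phase-locked to the 40 s
block cycle — a fixed 0.1 Hz sine is exactly periodic in the block and
would never average out. Every session carries its injected parameters as
ground truth.

*Metrics level.* For simulation studies (calibration, power) the
per-subject metric table is drawn directly from the same generative
means, subject random effects and residual SDs. Two hundred full
multimodal 42-subject cohorts would be pointless signal synthesis; the
downstream statistics see an identical structure by construction, so the
metrics level is used for the 200-cohort calibration and power runs and
the signals level (50 sessions) for end-to-end recovery.

Stroke-like subjects carry a latent severity factor (mean 1, SD 0.25)
that scales the configured group effects — more trunk flexion, lower IPe
and paretic-hand velocity, larger ΔHbO₂ peak during paretic reaching,
attenuated beta ERD, lower post-paretic-steering beta ERS — and drives
synthetic clinical scores (FM-UE, WMFT, BBT ratio, BI). Effect directions
follow the qualitative clinical picture; magnitudes are configuration
(`group_effects()`), not empirical claims, and `zero_group_effects()`
yields exchangeable groups for null calibration. The generator does not
emulate volume conduction, lesion anatomy, muscle dynamics, or
hemisphere-asymmetric rhythm modulation at the signals level (hemispheric
contrasts exist at the metrics level only) — so passing recovery tests
demonstrate pipeline correctness under this model, not robustness to
every physiological artifact of real recordings.

## Statistics

The mixed ANOVA is the classical univariate repeated-measures
decomposition (`aov` with `Error(subject/within)` strata) with partial
`η² = SS_effect / (SS_effect + SS_error-of-stratum)` and the 0.02 / 0.13 /
0.26 small/medium/large conventions (lower-inclusive, with an
interpretation floor at 0.02). All within-subject factors have two
levels, where sphericity is moot; a guard refuses factors with more.
Subjects with incomplete within-subject cells are dropped listwise per
response; synthetic designs are balanced, so Type-I sums of squares
coincide with Type-III and no further unbalanced-design machinery is
included. Constant responses return F = 0, η² = 0, p = 1 by contract.

Post-hocs are paired or independent t-tests as the factor dictates, with
Benjamini–Hochberg step-up adjustment over the comparison family
(`bh_adjust()` wraps `p.adjust`). Note that BH-adjusted *values* are not
idempotent under re-application — re-adjusting inflates non-maximal
entries — so the tests assert monotonicity and exact agreement with a
step-up enumeration instead.

Rank correlations are Pearson correlations of average ranks; with
covariates, ranks of x and y are residualized on covariate ranks first.
p-values use the t approximation with `n − 2 − k` degrees of freedom.
Covariates default to empty — the analysis convention names partial
correlation but not its covariate set, so both variants are exposed and
the output's `method` column states which was run. Only correlations with
r² > 0.25 are flagged `reported`, mirroring the moderate-effect filter.

## Problem sizes and seeds

Validation runs use: 1000 random triples for steering-formula fidelity,
20-block runs for the ERSP identities, 50 noisy sessions for parameter
recovery, and 200 metrics-level cohorts each for null calibration and for
power at n = 21 per group. Every stochastic step takes an explicit
integer seed; identical configuration and seed reproduce every output
bit-identically, and the pipeline manifest records the configuration hash
and resolved parameters (filter bands, windows, estimator settings)
needed to reproduce any table.

## Known limitations

- XDF import is not implemented; the CSV-directory layout is the
  interchange format.
- The arm-use formula operationalises a construct whose published
  definition lives in the PANU literature; it is plausible but deliberately
  swappable.
- The peak-ΔHbO₂ convention carries the positive biases described above;
  comparisons *between* conditions and groups are unaffected because the
  bias is common to all cells.
- Hemisphere-specific effects are generated only at the metrics level.
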