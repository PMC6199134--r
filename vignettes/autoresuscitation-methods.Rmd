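---
title: "Methods: simulating and analysing neonatal autoresuscitation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing neonatal autoresuscitation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autoresus)
```

## The assay and its measures

Neonatal mammals survive apneas through autoresuscitation: severe hypoxia
triggers gasping, gasps re-oxygenate the blood, heart rate recovers, and
eupneic breathing resumes. The assay modelled here challenges a mouse pup
with four successive asphyxic exposures (97% N₂ / 3% CO₂) inside a head-out
plethysmograph, recording respiratory pressure, ECG-derived beat times,
expired-line O₂ fraction and chamber flow throughout: ~20 min of acclimation
in room air, an intraperitoneal injection of the intervention compound, a
~10 min settling window, then four bouts, each consisting of a 30-s pre-bout
baseline window, the asphyxic exposure, and a 330-s recovery recording.

Per pup and bout the pipeline computes:

* **Baseline measures.** *f* = 60 / mean interbreath interval; V_T = mean
  per-breath pressure integral × calibration (ml per V·s, from a 0.02-ml
  calibration pulse) ÷ body weight; V̇E = *f*·V_T (an identity, enforced by
  construction); HR = 60 / mean interbeat interval; V̇O₂ =
  Flow·(F_IO₂ − F_EO₂)/BW from the mean expired-line O₂ reading; and the
  ventilatory equivalents V̇E/V̇O₂.
* **Recovery latencies.** τ_f and τ_HR are the times from asphyxia end until
  the instantaneous rate (60/interval, assigned to its interval) stays at or
  above 63% of the *pre-bout* baseline for a run spanning ≥ 3 s. τ marks the
  *start* of that run, because the quantity is described as a time *to
  recover*; the source does not fix start-versus-end, and the start choice
  makes τ agree with the 63% crossing of the underlying rate curve.
  Breathing that never recovers within 330 s is censored at exactly 331 s;
  heart rate is instead flagged unrecovered. A fatal bout with a transient
  supra-63% heart-rate epoch is kept in τ_HR summaries (flagged), never in
  τ_f.
* **Gasp profile.** Apnea onset is the last breath followed by silence of
  ≥ 3× the pre-bout median interbreath interval (the cessation multiplier is
  a package decision — the criterion was only operational in the source — and
  is exposed as a parameter). Gasps are steeple-like deflections after onset
  exceeding an absolute 0.002 V threshold, gated on chamber O₂ (below), with
  first-gasp latency and body-weight-normalised size, inter-gasp intervals
  I–IV, and the mean heart rate inside each gasp-to-gasp span.

## The synthetic cohort: a stated world

No raw recordings were deposited, so the generator *is* the benchmark. Its
defaults are the published conditions and are not tuned to test outcomes:

| Parameter | Default | Why |
|---|---|---|
| Group sizes | 22 experimental / 15 control | published cohort |
| Baselines (BW, *f*, V_T, HR, V̇E/V̇O₂) | group normals, published means/SDs | printed baseline table |
| Apnea latency | 23.4 s (SD 4.1 exp / 4.9 ctrl) | published latency |
| Recovery window | 330 s, censor at 331 s | published protocol |
| Mortality model | log-odds = intercept + ln(1.399)·V̇E/V̇O₂ + ln(6.53)·[experimental] | published effect sizes; intercept tuned once so experimental mortality ≈ 7/22 at the mean predictor |
| Asphyxia duration | 30 s | not printed; chosen so the gas switches off shortly after the ~23-s apnea onset, putting the first gasp in the O₂-rising phase |
| Sampling rate | 1000 Hz (tests use 250 Hz) | not printed; configurable |
| Bradycardia floor | 40% of baseline HR | not printed; exposed parameter |
| Eupnea-resumption floor | 30% of baseline *f* | keeps resumed breaths (intervals < 1 s) separable from gasps (> 2.5 s) |
| Noise | breath amplitude / SNR, default SNR 20 | plausible plethysmograph SNR |

Two identities are enforced in the programmed truth rather than sampled
independently: V̇E = *f*·V_T and V̇O₂ = V̇E/(V̇E/V̇O₂). Drawing V̇O₂ from its own
printed marginal instead would give the derived ratio roughly twice the
printed spread (the ratio of independent normals is heavy-tailed), so the
ratio — the mortality predictor — is drawn directly from its published
distribution and V̇O₂ is implied. Consequently V̇O₂'s own SD is reproduced
only approximately.

**Units.** The instrument-report units are stored exactly as printed (V_T in
"ml·g⁻¹" with values ≈ 4.5, V̇O₂ ≈ 77 "ml·min⁻¹·g⁻¹"), even though a 140
ml·min⁻¹ flow cannot support ~385 ml·min⁻¹ of oxygen uptake — the printed
per-gram unit is internally inconsistent (a per-kg reading would be
consistent). The package does not silently rescale: the O₂ channel is
synthesized, and inverted at analysis, with a metadata constant
`o2_scale = 1e-3` applied to body weight in the gas equation, which makes the
round trip exact while preserving the printed numbers. `oxygen_consumption()`
itself implements the formula verbatim.

**Recovery curves.** After the gasp train, instantaneous breathing rate
follows baseline × (floor + (1 − floor)(1 − e^{−t/θ})) from asphyxia end;
heart rate analogously from its bradycardic floor. θ is calibrated per pup so
that the programmed τ is *exactly* the 63% crossing time,
θ = τ / −log(1 − (0.63 − floor)/(1 − floor)). This makes "programmed τ"
mean the same thing the analyser estimates, so parameter-recovery tests are
sharp rather than floor-dependent. Post-gasp heart-rate transients (additive
bumps scaled by a gasp-effectiveness parameter) fade linearly to zero at the
63% level so they can shape HR *between* gasps without ever advancing the
programmed crossing.

**Mortality realisation.** A dying pup's fatal bout has gasps but no eupneic
resumption; all channels fall silent at a death time ~45% into the recovery
window. Three in seven dying pups (the published fraction) first show a
transient heart-rate burst: the recovery curve crosses 63% at the programmed
τ_HR, climbs to 72% over 10 s, then declines terminally — deliberately ≥ 9
percentage points above the criterion so that physiologic interval jitter
(±2%) cannot erase a programmed transient. Dying pups also carry the
published disordered-gasp phenotype: smaller first gasp, longer first-gasp
latency, prolonged intervals, low gasp effectiveness.

## Numerical and algorithmic choices

* **Event detection** is prominence-thresholded local-maximum search. The
  threshold is 4× the robust noise SD (1.4826×MAD of the window), making
  detection invariant to uniform amplitude scaling; beats use half the
  impulse amplitude. The refractory period is 0.25× the expected inter-event
  interval, estimated from debounced threshold crossings (median spacing of
  raw maxima is corrupted by twin noise peaks on one deflection). Peak times
  are refined to sub-sample precision by a three-point parabola — without
  this, grid quantization of intervals (±1 sample) injects enough rate noise
  to delay the slow 63% crossing by several seconds.
* **Lobe integrals** integrate the raw baseline-centred signal between the
  nearest noise-floor crossings around each peak; integrating the raw rather
  than threshold-clipped signal keeps the estimate unbiased under additive
  noise.
* **Stable-window selection** scans for the earliest 30-s sub-window whose
  artifact score is zero; the artifact threshold is 8× the robust SD floored
  at 1.5× the 99th percentile of absolute deviations, so ordinary breath
  peaks (which dwarf the MAD-scale noise estimate) are never scored as
  artifacts while movement bursts (~20× breath amplitude) always are. Bursts
  below ~1.5× breath amplitude would be missed — a known limitation.
* **Gasp gating.** The source counts a gasp only "while chamber O₂ is
  rising", which literally applies near the first gasp; later gasps occur
  after the chamber has re-equilibrated. The gate therefore passes events
  where the smoothed O₂ slope (2-s lag) exceeds 1e-3 s⁻¹ *or* the level has
  recovered past halfway between the asphyxic floor and the room-air expired
  value. Detection noise floors are estimated from the apneic silence just
  after onset, with a 6× prominence multiplier (steeples are large; this
  keeps the false-discovery rate near zero at SNR 10). The train ends at the
  first gap below 1.5 s, the operational signature of resumed eupnea.
* **Mid-P.** The experimental death count under fixed margins is
  hypergeometric; the one-tailed mid-P adds half the observed table's mass to
  the mass of strictly more-extreme tables, by enumeration over the support.
  The tail direction must be stated; the default (excess experimental
  deaths) matches the prior hypothesis of the motivating design. Both the
  3-decimal and 2-decimal roundings of the headline value are reproduced.
* **Logistic models** are fitted by `stats::glm` (binomial IRLS — the exact
  algorithm specified) with Wald 95% CIs; separation is flagged (divergent
  coefficients/SEs or non-convergence) instead of silently reported.
* **Runs test** uses the exact conditional run-count distribution for
  n ≤ 20 and a continuity-corrected normal approximation beyond; the
  reported p is one-sided toward *too few* runs, the deviation-from-
  linearity direction a curvature check cares about.
* **Poincaré naming.** The source names "major and minor axes" and an
  "estimated area" without definitions; these are mapped to the standard
  SD2/SD1 and the fitted-ellipse area π·SD1·SD2, and the raw product
  SD1×SD2 is emitted alongside since the naming is ambiguous.

## What a green test establishes — and what it does not

The generator reproduces the *statistical structure* the analysis assumes:
event timing, exponential-approach recovery, logistic mortality, disordered
gasping, movement artifacts, additive Gaussian noise. It does not attempt
electrophysiological realism (only beat times matter; no P/QRS/T
morphology), waveform fidelity of real plethysmograph signals, thermal
dynamics (chamber and body temperature are constant metadata), or gas-law
corrections to volumes. Parameter-recovery results on synthetic traces
therefore validate the *estimators* under the stated world — they cannot
validate the stated world against real recordings, which were never
deposited. Cohort-level statistics on printed tables (odds ratio 6.5, mid-P
0.041, mortality percentages) are reproduced exactly from the published
counts and do not depend on the generator.

Scaled-down configurations (shorter quiet stretches, 250 Hz) are used in
tests and the demo purely for runtime; every analysed window keeps the
published geometry, and nothing in the algorithms depends on the scaling.

## Known limitations

* Interval jitter delays measured τ by a few seconds relative to the
  programmed crossing when the recovery curve is shallow; this mirrors how
  the operational sustain rule behaves on real noisy rhythms, and the sharp
  (noiseless) recovery guarantee is the tested claim.
* The pre-bout baseline is declared fully recovered at each next baseline
  window; very long programmed recoveries are therefore truncated at ~85% of
  the recovery window rather than allowed to bleed into the next bout's
  baseline.
* `group_compare` deliberately delegates t tests/ANOVA to base routines;
  the package re-derives only the bespoke statistics (mid-P, runs test,
  recovery latency, gasp logic).
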