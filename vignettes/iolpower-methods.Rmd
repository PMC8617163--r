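---
title: "Methods: vergence optics, the ensemble ELP model, and the synthetic benchmark"
author: "iolpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vergence optics, the ensemble ELP model, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iolpower)
```

## The optical model

The package treats the pseudophakic eye as a thin two-lens system (cornea
and IOL) observed through a spectacle plane.  All axial distances are kept
in millimetres, so every vergence term is written `1000·n` and powers come
out in diopters; the vertex distance `b` is stored in metres because it
multiplies diopters directly.  For an eye of axial length `AL`, corneal
power `Pc`, lens position `d` and target spectacle refraction `Rx`, the
required IOL power is

\[
P \;=\; \frac{1000\,n_{vit}}{AL - d} \;-\;
\frac{1000\,n_{aq}}{\dfrac{1000\,n_{aq}}{P_c + S} - d},
\qquad S = \frac{R_x}{1 - b\,R_x},
\]

with `S` the corneal-plane equivalent of the spectacle-plane target.  At
`Rx = 0` this reduces to the emmetropic vergence solution.  Three
closed-form companions complete the algebra: the inversion for `Rx` given
an implanted power (used for refraction prediction), and the inversion for
`d` given power and achieved refraction (a quadratic; used to build ELP
training targets from retrospective outcomes).  The quadratic's
anatomically admissible root is taken inside the pseudophakic window
(1.5, 8.0) mm; if both roots are admissible the one closer to 5.0 mm is
used and the eye is flagged, never silently accepted.  Round trips among
the three forms are exact to numerical precision, which the test suite
verifies against bracketed root-finding oracles.

Defaults `n_aq = n_vit = 1.336` and `b = 12` mm are the standard
pseudophakic conventions; they are parameters of `optical_constants()`,
not constants of the code.  The corneal power fed to the MM formula is the
unadjusted mean keratometry `K = (K1 + K2)/2`; each classical formula
instead uses its own published corneal convention (SRK/T and Holladay I
work from the corneal radius `337.5/K`; Haigis rescales by its 1.3315
corneal index; Hoffer Q uses `K` directly with its +0.05 mm lens-plane
offset).

## Classical comparators

SRK/T, Hoffer Q, Holladay I and Haigis are implemented from their original
publications (including the errata), because the benchmarked variants are
the industry-standard published forms: SRK/T with the long-eye axial
correction, corneal width/height chain with a clamped discriminant, and
retinal-thickness term; Hoffer Q with the degree-argument tangent terms,
its axial-length clamp to [18.5, 31] mm (a warning, never a failure, so
cross-validation folds survive extreme synthetic eyes) and chamber-depth
clamp to [2.5, 6.5] mm; Holladay I with the 13.5 mm corneal-width cap and
+0.2 mm retinal correction; Haigis with `d = a0 + a1·ACD + a2·AL`.  Each
formula's ELP estimator was cross-checked against an independent
step-by-step evaluation of the published chain, frozen into the tests.

Constant personalization follows the standard definitions: for the
single-constant formulae the constant is root-found (Brent) so that the
training-set mean prediction error is exactly zero; for Haigis the three
constants are the OLS solution of the back-calculated ELP (under Haigis's
own internal optics) on `(1, ACD, AL)`, with an `a0`-only mode that keeps
the manufacturer slopes 0.4/0.1.  Search intervals pACD ∈ [2, 8],
SF ∈ [−2, 4], A ∈ [110, 125] span published lens constants.

## The MM effective-lens-position ensemble

Training targets are per-eye ELP values back-calculated from the implanted
power and the achieved refraction; features are exactly the four
pre-operative predictors (K1, K2, ACD, AL).  One model is fitted per lens
model, never pooled across lenses.

The default ensemble is a bootstrap-aggregated set of 20 penalized
additive spline regressions (thin-plate shrinkage smooths in each
predictor, REML smoothness selection with an extra null-space penalty so
irrelevant predictors shrink out entirely; an ordinary least-squares
member replaces the smoother whenever the response is already linear to
numerical precision, or the smoother fails).  This family was chosen over
boosted trees after a direct bias–variance comparison at the realistic
problem scale: with roughly 200 training eyes and back-calculated targets
carrying ~0.3 mm of observation noise, tree ensembles of any depth or
regularization we tried paid 0.03–0.08 mm of held-out ELP error over a
plain linear fit, whereas the shrinkage-spline ensemble matches the linear
fit when the anatomy is linear and bends where the data demand it.
Gradient-boosted trees (`family = "gbt"`, 300 trees, depth 3, learning
rate 0.05, subsample 0.8) and bagged random forests (`family = "bagging"`)
remain available behind the same `mm_control()` interface for larger
cohorts.  Hyperparameters are fixed by configuration and are never tuned
inside a cross-validation fold, so the benchmark measures the formula, not
a tuner.

Predictions are clamped to the (1.5, 8.0) mm window (flagged), which
prevents optical singularities under extrapolation to extreme eyes.
Training is deterministic given `(control, seed, data)`; persisted models
reload bit-identically and refuse incompatible payload versions.

## The synthetic benchmark

No clinical data ship with the package.  The generator emulates three real
lens-model cohorts through their published summary statistics (sample
sizes, means, SDs, medians, observed ranges of age, AL, K1, K2, ACD, and
sex ratios).  Biometry is drawn from a truncated multivariate normal over
(AL, K1, K2, ACD); flat/steep pairs sampled in the wrong order are
swapped.  Because truncation to the observed ranges and the re-ordering
both bias sample means, the sampler applies an analytic fixed-point
correction to the pre-truncation means so that generated cohorts reproduce
the published marginal means (verified to 2 standard errors at the
published sample sizes).

The correlation structure is not published, so it is a calibration choice:
corr(AL, ACD) = 0.45, corr(AL, K) = −0.30, corr(ACD, K) = 0, and
corr(K1, K2) = 0.96.  The last value is forced by internal consistency:
the published flat/steep SDs (≈1.83/1.94 D) and mean gap (≈0.78 D) are
only attainable by an ordered bivariate normal pair if the two readings
are very highly correlated — the gap is the corneal astigmatism, here
0.78 ± 0.54 D, which is also the clinically plausible scale.  A lower
correlation (e.g. 0.85) would make the minimum achievable mean gap exceed
the published one.

Outcomes follow a known ground-truth ELP process.  The linear kind is
`d = 0.9 + 0.40·ACD + 0.08·AL` (a Haigis-like lens); the nonlinear kind
adds a saturating axial-length bend `0.25·tanh((AL − 23.5)/1.5)` and a
mild keratometry interaction `0.01·(K − 43.5)(AL − 23.5)` — the regime in
which a flexible ELP predictor has something to gain.  Per-eye ELP
variability is 0.15 mm (surgical placement noise).  The implanted power is
the vergence solution at the true ELP rounded to the 0.5 D manufacturing
step; the achieved refraction is the vergence prediction at that power
plus 0.35 D of measurement noise, quantized to the clinical 0.125 D step.
These noise scales were fixed once so that all-eyes prediction-error SDs
land near 0.5 D, the scale reported for real cohorts.  The generator's
forward optics exposes the same corneal-power transform as the formulae,
so a "Haigis-generated" cohort (linear truth + Haigis corneal convention)
is exactly self-consistent: with noise switched off, constant optimization
recovers the generating `(a0, a1, a2)` to 1e−6, which the acceptance tests
assert.

What passing on synthetic data does and does not show: the generator
reproduces marginal biometry distributions, a plausible correlation
structure, quantized outcomes and a controllable ELP process, but not
device-specific measurement error models, surgical complications, IOL
tilt/decentration, or the unknown true ELP physiology.  Results on it
validate the machinery (optics, optimization, CV bookkeeping, statistics)
and the relative behaviour of the formulae under a known truth — not
clinical performance.

## The benchmark and statistics layer

Monte-Carlo cross-validation draws `k` independent random 80/20 splits
(the split fraction is configurable; 80/20 is the conventional holdout).
Within every repetition all four classical constant sets are re-optimized
and the MM ensemble re-fitted on the same training split — no leakage —
and all five formulae predict the held-out eyes.  Held-out records
accumulate across repetitions (an eye may be tested in several
repetitions, at most once per repetition); a last-repetition-only mode is
available.  Failed folds are skipped with an audit trail; more than 10%
failures aborts the run.  Metrics follow the standard reporting layout:
MPE ± SD, median PE, PE range, MAE ± SD, MedAE, and the percentage of eyes
within ±0.5/1.0/1.5 D, stratified by axial length (short < 22 mm ≤ medium
≤ 24.5 mm < long-medium ≤ 26 mm < long) with closed band edges (an error
exactly at a boundary counts as within).

The comparison battery is non-parametric throughout (prediction errors are
routinely non-normal, which the Shapiro–Wilk screen documents): Wilcoxon
signed-rank for zero medians (zeros dropped, exact distribution for n ≤ 25
without tied magnitudes, otherwise the tie-corrected normal
approximation), Friedman across the five formulae with paired Wilcoxon
follow-ups, and Cochran's Q across the five within-band indicator columns
with McNemar follow-ups (exact binomial below 25 discordant pairs — small
axial-length strata make the exact test necessary — otherwise chi-square
with continuity correction).  Degenerate inputs (identical columns, no
discordance) report statistic 0 and p = 1 rather than NaN.  Pairwise
p-values are unadjusted by default, matching common practice in this
literature; Holm adjustment is available by flag.  Each pairwise accuracy
verdict is labelled no-difference / outperformed / underperformed by the
sign of the discordant counts.

## Numerical choices and problem sizes

Tolerances: vergence round trips are exact to 1e−9 or better; constant
root-finding to 1e−10; degenerate geometry (denominators below 1e−9 mm)
raises a diagnostic error naming the failing stage.  The test suite and
the acceptance script use the published cohort size (n = 265) with k = 20
cross-validation repetitions and ten-seed replicate properties — sizes at
which every quantity of interest is stable to well under its assertion
tolerance while the full suite runs in a couple of minutes on one CPU.

## Known limitations

Spherical equivalent only (no toric/astigmatic decomposition); thin-lens
optics (no ray tracing); the four-predictor feature set is fixed (the
upstream feature-selection question is out of scope); newer unpublished
formulae (Barrett Universal II, Holladay II, Olsen) are not comparators;
and classical-formula internals follow one published variant each —
other circulating variants differ in details.
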