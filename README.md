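# iolpower

Personalized intraocular lens (IOL) power calculation with an ensemble
effective-lens-position model.

## The problem

After cataract removal, the power of the implanted IOL must be chosen
pre-operatively so the eye ends up at (or near) the target refraction.
Modern formulae solve the thin-lens vergence equation for the pseudophakic
eye,

```
P = 1000·n_vit / (AL − d)  −  1000·n_aq / (1000·n_aq / (Pc + S) − d),
S = Rx / (1 − b·Rx)
```

with `AL` the axial length (mm), `Pc` the corneal power (D), `Rx` the
target spectacle refraction, `b` the vertex distance, and `d` the
*effective lens position* (ELP) — the post-operative depth of the lens
optic behind the cornea.  `d` cannot be measured pre-operatively, and the
four classical formulae (Haigis, Hoffer Q, Holladay I, SRK/T) differ
essentially only in the ad hoc regression each uses to predict it, each
personalized by one lens constant (pACD, SF, A-constant) or three (Haigis
a0/a1/a2).

This package implements those four classical formulae (with per-lens
constant optimization), and the **MM formula**: the ELP is predicted by a
bootstrap-aggregated ensemble of penalized additive spline regressions on
the four pre-operative predictors — flat keratometry K1, steep keratometry
K2, pre-operative anterior chamber depth ACD, and axial length AL — fitted
to ELP values back-calculated from retrospective outcomes via the same
vergence equation, then plugged back into the optics for power selection
and refraction prediction.  A Monte-Carlo cross-validation harness,
axial-length-stratified error metrics (MPE, MAE, MedAE, % of eyes within
±0.5/1.0/1.5 D), the non-parametric comparison battery used in
refractive-outcome studies (Shapiro–Wilk, Wilcoxon signed-rank, Friedman,
Cochran's Q, McNemar), and a calibrated synthetic cohort generator make the
whole pipeline testable end to end without clinical data.

## Worked example

```r
library(iolpower)

# a synthetic monofocal cohort calibrated to a published 265-eye cohort
cohort <- generate_cohort("SN60WF", n = 265, seed = 1)

# fit the MM ensemble and predict for the first eye
fit <- fit_mm(cohort, seed = 1)
fit
#> MM effective-lens-position ensemble (spline)
#>   lens model: SN60WF
#>   trained on 265 eyes ( 0 dropped in back-calculation )
#>   ELP target: 4.167 +/- 0.534 mm

predict(fit, cohort[1, ], type = "elp")
#> [1] 3.775761
predict(fit, cohort[1, ], type = "power", target_rx = 0)
#> [1] 24      (exact pre-rounding value 23.78046 in attr "raw")

# benchmark all five formulae by Monte-Carlo cross-validation
cv <- mc_crossval(cohort, k = 20, test_fraction = 0.2, seed = 1)
m  <- compute_metrics(cv)
subset(m, stratum == "all",
       select = c(formula_id, n, mae, medae, pct_within_1.0))
#>    formula_id    n       mae     medae pct_within_1.0
#> 21       SRKT 1060 0.5320876 0.4496872       85.56604
#> 22    HOFFERQ 1060 0.3925376 0.3176222       95.47170
#> 23  HOLLADAY1 1060 0.4470421 0.3764051       92.26415
#> 24     HAIGIS 1060 0.3602613 0.2998523       97.26415
#> 25         MM 1060 0.3242093 0.2738535       97.73585
```

Each row is one formula over the eyes accumulated across the 20 held-out
splits: `mae`/`medae` are the mean/median absolute difference between the
achieved and the predicted spherical-equivalent refraction (D), and
`pct_within_1.0` is the share of eyes whose prediction error is within
±1.0 D — the usual clinical benchmark is 85%.  On this cohort the MM
formula attains the lowest mean and median absolute error; SRK/T, whose
ELP-versus-AL shape differs most from the simulated truth, sits near the
benchmark.  `run_test_battery(cv)` adds the Friedman / Wilcoxon /
Cochran's Q / McNemar comparisons, and `run_report(cv, "results")` writes
the full bundle.

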