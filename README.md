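# ogttfda

Functional data analysis of oral glucose tolerance test (OGTT) curves.

An OGTT records venous glucose (mmol/l) at 0, 30, 60, 90 and 120
minutes after a standardized 75 g glucose load. The usual scalar
summaries — fasting value, 2-h value, area under the curve (AUC), or a
rule-based shape index — discard the trajectory: different curves can
share identical summaries. `ogttfda` analyses the curves themselves.
It is aimed at biostatisticians working with repeated glucose sampling
in cohort studies, particularly pregnancy cohorts where a later 2-h
value ≥ 7.8 mmol/l defines gestational diabetes (WHO criterion).

## What it does

1. **Curve fitting.** Each subject's five measurements
   $y_i(t_j) = x_i(t_j) + \epsilon_{ij}$ are smoothed into a continuous
   curve by penalized B-spline least squares,
   $\min_C \|Y-\Phi C\|^2 + \lambda\,\mathrm{tr}(C^T R C)$ with
   $R = \int D^2\phi\, D^2\phi^T$, cubic splines with a knot at each
   sampling time ($K = 7$), and a single smoothing parameter
   $\lambda$ shared by all subjects, chosen by pooled generalized
   cross-validation.
2. **Functional PCA.** Eigenfunctions $\xi_\kappa(t)$ maximise the
   variance of the centred scores
   $z_{\kappa i} = \int \xi_\kappa (x_i - \mu)\,dt$ subject to
   orthonormality, solved exactly in coefficient space. On OGTT-like
   samples the first three components — general level, time-to-peak,
   oscillation — carry ~99% of between-curve variance.
3. **Simple summaries.** Trapezoid AUC on the raw five points, and a
   threshold-based (0.25 mmol/l) classification of curves as
   monophasic / biphasic / triphasic / unclassified with the
   corresponding shape index; Pearson correlation tables against the
   FPC scores; one-way ANOVA with Bonferroni post hoc across BMI
   categories.
4. **Functional ANOVA.** Group mean-curve contrasts
   $x_{lg}(t) = \beta_{ref}(t) + \beta_g(t) + \epsilon_{lg}(t)$ with a
   point-wise F statistic, permutation p(t) curves and an overall
   max-F permutation p (B = 1000 by default), and point-wise 95%
   confidence bands.
5. **Outcome regression.** The later 2-h value is categorized into
   seven half-open intervals (reference [3.89, 6.39)) and related to
   early curve features by multinomial logistic regression (five
   models: FPC scores / fasting / 2-h / AUC / shape index, each with
   BMI), with Wald odds ratios and between-category comparisons.
6. **Synthetic cohorts.** `simulate_ogtt_cohort()` generates cohorts
   with known ground truth: a smooth population mean through
   (4.0, 5.7, 5.0, 4.5, 4.1) mmol/l, three orthonormal modes with
   score SDs (6.0, 1.87, 0.99), measurement noise, BMI level shifts,
   a linked later outcome, and a fixed fraction of incomplete tests.

## Worked example

```r
library(ogttfda)

cohort <- simulate_ogtt_cohort(1000, seed = 42)
flt    <- filter_complete(cohort)
#> $n_input [1] 1000   $n_retained [1] 945   $n_excluded [1] 55
#> $pct_excluded [1] 5.5

Y      <- cohort_matrix(flt$cohort)
basis  <- ogtt_basis()
lambda <- select_lambda_gcv(Y, basis)$lambda
fit    <- fit_ogtt_curves(Y, basis, lambda)
fit
#> Penalized B-spline fit: 945 curves, K = 7
#> lambda = 66.7439, effective df = 4.914, pooled GCV = 593.305

pca <- ogtt_fpca(fit)
pca
#> Functional PCA of 945 curves ( 3 components retained )
#>   FPC1:  88.0% of variance (cumulative  88.0%)
#>   FPC2:   8.1% of variance (cumulative  96.1%)
#>   FPC3:   2.8% of variance (cumulative  98.8%)

summ <- ogtt_summaries(flt$cohort)
table(summ$shape_label)
#>     biphasic   monophasic    triphasic unclassified
#>           14          929            1            1
cor(summ$auc, pca$scores[, 1])
#> [1] 0.9998

fv <- ogtt_fanova(fit, flt$cohort$bmi_category,
                  reference = "normal", B = 199, seed = 43)
fv
#> Functional ANOVA: 4 categories, reference = normal
#> group sizes: normal=577, obese=89, overweight=257, underweight=13
#> 9 subject(s) dropped (missing label)
#> overall permutation p = 0.005 (B = 199, max-F statistic)
```

Reading the numbers: 5.5% of simulated subjects have an incomplete
five-point test and are excluded. The pooled-GCV smoother uses ~4.9
effective degrees of freedom per curve. The first component (a level
shift) explains 88% of between-curve variance and correlates 0.9998
with the trapezoid AUC — the AUC is essentially a level-score proxy —
while the second and third components carry shape information the
simple summaries miss. The BMI groups' mean curves differ
significantly (permutation p = 0.005), driven by the generator's
additive shifts for overweight/obese categories.

`run_ogtt_pipeline()` chains all stages (filtering → smoothing → FPCA →
summaries → FANOVA → regression) from one master seed, and
`export_figure_data()` writes plot-ready CSVs (fitted curves, mode-of-
variation curves, score quartile panels, FANOVA bands and p curves,
outcome-category mean curves) plus a JSON run manifest.

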