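# fmpjoint

Bayesian joint latent-class modelling of longitudinal follicle stimulating
hormone (FSH) and age at final menstrual period (FMP).

## What problem this solves

Women approaching menopause differ in when their FSH starts to rise: a
minority show an early rise shortly after age 40, most only in their
mid-40s. Those trajectory patterns — the latent class, the fitted FSH level
and rate of change at reference ages 40/45, and a woman's short-term FSH
variability — are candidate predictors of her age at final menstrual
period. Exploiting them is statistically awkward: FSH is measured
irregularly and noisily, the trajectory features are estimates rather than
data, and many women are censored before reaching FMP.

`fmpjoint` fits the two pieces **jointly** by MCMC:

* **Longitudinal submodel** — a generalized growth mixture model (GGMM):
  latent trajectory classes with class-mean penalized cubic splines
  (truncated-power basis, shrinkage on the hinge coefficients), a subject
  random intercept and slope, Student-t(4) residuals via the Gamma(2,2)
  scale mixture, and lognormal subject-specific within-subject variances
  `log σ²ᵢ ~ N(η_class, τ²)`.
* **Outcome submodel** — a lognormal accelerated failure time (AFT)
  regression on years past age 40,

  `log(Tᵢ − 40) = α₀ + α₁Dᵢ + α₂ωᵢ + α₃μᵢ(40)(1−Dᵢ) + α₄μᵢ(45)Dᵢ + xᵢᵀθ + εᵢ`

  (model M2; designs M0–M4 and a simplified prediction model "Mfinal" are
  available), with truncated-normal data augmentation for censored FMP
  ages. `exp(α₁)` is the time ratio: the multiplicative factor on years
  past 40 for the late-rise class versus the early-rise class.

The package also provides DIC-based selection of the number of classes,
10-fold cross-validated root prediction error of FMP age, local-polynomial
median adjustment of AMH/BMI to age 40, Cox–Snell residual diagnostics,
and a synthetic-cohort generator with known ground truth that emulates the
structure of a longitudinal ovarian-aging study (363 women, baseline ages
35–48, visits every 9 months then annually, ~50% observed FMP events, ~7%
hysterectomy censorings).

## Worked example

```r
library(fmpjoint)

coh <- simulate_cohort(seed = 11)          # synthetic study-scale cohort
fit <- fmp_joint(coh, model = "M1", K = 2,
                 control = fmp_control(n_burnin = 1000, n_draws = 2000,
                                       seed = 5))
summary(fit)
```

```
Lognormal AFT model M1 jointly fit with a 2-class GGMM
  219 subjects (118 FMP events), 2000 posterior draws
  class weights: 0.13 / 0.87
                           Value  95% CI          
(Intercept)                1.036  0.002, 2.097   *
Class 2 vs 1               0.698  0.500, 0.875   *
Within-subject variability -0.073 -0.279, 0.150   
Adj log BMI                0.149  -0.110, 0.410   
AMH Q2                     0.169  0.007, 0.319   *
AMH Q3                     0.237  0.077, 0.401   *
AMH Q4                     0.268  0.122, 0.412   *
Smoker                     -0.190 -0.301, -0.083 *
Race                       0.033  -0.079, 0.142   
  AFT residual SD: 0.319
```

The starred rows are coefficients whose 95% credible interval excludes 0.
The class contrast of 0.698 is a time ratio of `time_ratio(0.698)` ≈ 2.01:
late-rise women take about twice as many years past age 40 to reach FMP as
early risers with the same covariates (the generator's implied truth for
this contrast is `exp(0.725)` ≈ 2.07). Class recovery against the
generator's truth:

```r
truth_report(coh$truth, fit)$class_accuracy
#> [1] 0.9634703
```

Model comparison and prediction:

```r
select_classes(coh, K_values = 1:3, model = "M1",
               control = fmp_control(n_burnin = 300, n_draws = 500))
cv_root_pmse(coh, model = "M2", K = 2, folds = 10,
             control = fmp_control(n_burnin = 300, n_draws = 500))
predict(fit, data.frame(class = c(1, 2), fsh = 10, amh = 0.5, smoker = 0))
#>    fit lower upper
#> 1 44.6  42.6  48.3
#> 2 49.3  45.6  55.9
```

A woman with an FSH level of 10 mIU/mL at her class reference age is
predicted to reach FMP at 44.6 years (95% CI 42.6-48.3) if she is an early
riser, 49.3 years (45.6-55.9) if a late riser.

A config-driven pipeline (`run_simulate`, `run_fit`, `run_select`,
`run_cv`, `run_predict` plus the thin CLI at `inst/cli/fmpjoint.R`) wires
the same steps to delimited files and YAML configuration for scripted use.

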