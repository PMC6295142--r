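# bmikin

Predicting a child's body mass index (BMI, kg/m²) from the BMI of parents
and all four grandparents, when most of the grandparental values are
missing. `bmikin` is aimed at biostatisticians studying cross-generation
adiposity transmission in cohort data with heavy, missing-completely-at-
random (MCAR) missingness, and at methodologists comparing imputation
strategies and prediction rules under a known ground truth.

The package implements, as one tested pipeline:

* a **synthetic family-BMI generator** emulating a three-generation cohort
  (567 families by default; per-role missing fractions 0, 0.012, 0.579,
  0.561, 0.716, 0.679, 0.774 for child, mother, father, mgm, mgf, pgm,
  pgf), with configurable linear, smooth-nonlinear and interaction effects
  and a held-back truth sheet for scoring;
* **multiple imputation** (m = 10 datasets) by three engines: iterative
  (regularized) PCA completion, and chained equations with Bayesian linear
  regression (NORM: σ*² = RSS/χ²(nz−k), β* ~ MVN(β̂, σ*²(XᵀX)⁻¹),
  posterior-predictive imputation) or predictive mean matching (PMM:
  impute the observed value of one of the q = 3 donors minimizing
  |β̂x_h − β*x_i|);
* **prediction rules**: ordinary least squares; a sigmoidal feed-forward
  network with hidden layers (2, 1) trained by full-batch backpropagation
  (C++ core); and an additive backfitting smoother (cubic smoothing
  splines, 4 effective df per covariate) as a nonlinearity diagnostic;
* **evaluation**: leave-one-out cross-validation with the minimum squared
  error over 3 stochastic repetitions per observation for the network,
  pooled over imputed datasets to mse (sd) and R² = 100(1 − mse/Var(y));
  Rubin's-rules pooling of linear coefficients (T = W + (1 + 1/m)B,
  Satterthwaite df);
* the **reduction method** gold standard: one model per observed
  missingness pattern (at most 2⁶ = 64 with the child always observed),
  fitted on an 80/20 split of all rows complete on that pattern's
  covariates, with strict pattern routing for new rows — no imputation.

## Worked example

```r
library(bmikin)

gen <- generator_config(seed = 1, n_families = 150)
families <- simulate_family_data(gen)
print(families)
#> family_table: 150 families x 7 roles
#> missing fraction per role:
#>  child mother father    mgm    mgf    pgm    pgf
#>  0.000  0.007  0.520  0.540  0.660  0.687  0.773

cfg <- run_config(gen, methods = "mice_pmm", models = c("nn", "linear"),
                  m = 3, reps = 3, seed = 2, include_reduction = FALSE)
report <- run_experiment(cfg)
print(report)
#> experiment_report (seed 2 , 150 families)
#>
#>     method  model      mse     mse_sd r2_percent
#>   mice_pmm     nn 2.094337 0.05194798   36.26336
#>   mice_pmm linear 2.308315 0.07737079   29.75142
```

Each `mse` is the leave-one-out mean squared prediction error of child BMI
(BMI² units), averaged over the 3 PMM-imputed datasets; `mse_sd` is its
spread across datasets and `r2_percent` the percent of child-BMI variance
explained. Here the network improves on the linear model (2.09 vs 2.31,
R² 36% vs 30%) because the generator's child model contains a
mother-by-father interaction and smooth nonlinear terms that a linear fit
cannot capture. The pooled coefficient table shows the Rubin-combined
linear estimates:

```r
subset(report$table_coefficients, method == "mice_pmm")
#>         term estimate     se    df p_value   method
#>  (intercept)   2.0119 2.6424  6.18  0.4745 mice_pmm
#>       mother   0.0982 0.0419 16.22  0.0322 mice_pmm
#>       father   0.0917 0.0878  3.13  0.3704 mice_pmm
#>          mgm   0.1021 0.0421 10.99  0.0337 mice_pmm
#>          mgf   0.0482 0.1437  2.44  0.7639 mice_pmm
#>          pgm   0.0456 0.0649  2.84  0.5352 mice_pmm
#>          pgf   0.1163 0.0514 14.23  0.0400 mice_pmm
```

Note the small Satterthwaite df (and hence wide intervals) for the
heavily-missing roles — between-imputation variance dominates there.
`run_experiment()` with the defaults (all three methods, m = 10, reps = 3,
reduction included, n = 567) reproduces the full published-style grid;
`write_experiment_report()` dumps everything as plain-text CSVs. A thin
command-line wrapper lives in `inst/scripts/run_experiment.R`.

## Scientific account

See the methods vignette (`vignettes/family-bmi-imputation.Rmd`) for the
model and procedure details, the generator's calibration (why
Var(child BMI) ≈ 3.0 and noise_sd = 1.27), every numerical choice and
tie-break, what the synthetic data do and do not emulate, and known
limitations.
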