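# strokexplain

Comparing explainable predictive models for dichotomized 90-day stroke
outcome.

## What this package is for

After an acute ischemic stroke, outcome at three months is commonly
recorded on the modified Rankin Scale (mRS, 0–6) and dichotomized into
*good* (mRS 0–2) and *bad* (mRS 3–6).  Given seven admission covariates
— age, sex, initial NIHSS, cardiac history, diabetes,
hypercholesterolemia, thrombolysis — the question is not only how well
different model families predict the binary outcome, but whether the
*feature-importance rankings* their tailored explainability methods
produce agree with each other and with clinical domain knowledge (age
and stroke severity should dominate).

The package implements the full comparison for five families with the
attribution method native to each:

- **GLM** — logistic regression by maximum likelihood,
  `P(O=1|x) = 1 / (1 + exp(-(b0 + Σ βj xj)))`; importance = coefficients β.
- **Lasso** — the L1-penalized objective `J(β) + (1/C)·‖β‖₁`
  (inverse strength *C*); importance = coefficients.
- **Elastic net** — `J(β) + α(l1·‖β‖₁ + (1−l1)/2·‖β‖₂²)`;
  importance = coefficients.
- **GBDT** — gradient-boosted decision trees on the logistic loss with
  regularizer `γT + (λ/2)‖w‖²`, written from scratch (Newton leaf
  estimates, bagging-temperature Bayesian bootstrap); importance =
  **exact Shapley values** `φi = Σ_{S⊆F\{i}} |S|!(|F|−|S|−1)!/|F|! ·
  [f(S∪{i}) − f(S)]` by full coalition enumeration with an
  interventional value function.
- **MLP** — one hidden rectifier layer, 2-way softmax, BCE + L1 +
  dropout; importance = **deep Taylor decomposition** (LRP α=1/β=0
  rule, `rj = Σk [aj w⁺jk / Σj aj w⁺jk] rk`), aggregated with
  confidence weights `θi = yi·Pi + (1−yi)(1−Pi)`.

The training protocol is the repeated-shuffle design used in this
literature: random 4:1 split → train-derived mean/mode imputation and
zero-mean/unit-variance scaling → random undersampling to class balance
→ 10-fold cross-validated grid tuning → fit → test AUC → attribution,
repeated (50 shuffles by default) with medians/IQRs for AUC and
mean ± SD unit-sum normalized ratings for importance.

Because registry data of this kind are access-restricted, the package
includes a first-class synthetic cohort generator: a latent Gaussian
copula with the study's marginals (median age 72, IQR 15; median NIHSS
3, IQR 5; the five binary prevalences; ~28% bad outcomes; VIFs well
below 1.91) and a planted logistic ground truth whose age and NIHSS
coefficients dominate — so parameter recovery, ranking recovery and
performance ceilings are all checkable.  See the methods vignette
(`vignettes/explainable-stroke-models.Rmd`) for every modeling choice.

## Worked example

```r
library(strokexplain)

spec   <- cohort_spec(n_subjects = 314, seed = 1)   # study-scale cohort
cohort <- generate_cohort(spec)
head(validate_marginals(cohort, spec), 4)
#> # A tibble: 4 × 6
#>   feature statistic  target tolerance observed pass
#>   <chr>   <chr>       <dbl>     <dbl>    <dbl> <lgl>
#> 1 age     median     72          1      71.8   TRUE
#> 2 nihss   median      3          1       3     TRUE
#> 3 sex     prevalence  0.376      0.03    0.384 TRUE
#> 4 cardiac prevalence  0.268      0.03    0.284 TRUE

grid <- structure(list(          # reduced grids for a quick demonstration
  lasso = list(C = c(0.1, 1, 10, 100)),
  elastic_net = list(l1_ratio = c(0, 0.5, 0.95), alpha = c(1e-4, 0.0025, 0.63)),
  gbdt = list(depth = 2, learning_rate = 0.1, bagging_temperature = 1,
              l2_leaf_reg = 3, leaf_estimation_iterations = 1, n_trees = 100),
  mlp = list(hidden_units = 10, learning_rate = 0.01, batch_size = 16,
             dropout_rate = 0.1, l1_ratio = 1e-4, epochs = 200)),
  class = "hyper_grid")

report <- run_experiment(experiment_config(cohort = spec, n_shuffles = 5,
                                           grid = grid, seed = 42))
report
#> <experiment_report> 5 shuffles; 0 failed
#>
#> Performance (median AUC / IQR):
#> # A tibble: 10 × 5
#>    model       partition median_auc    iqr n_shuffles
#>  1 elastic_net test           0.782 0.0238          5
#>  2 elastic_net train          0.811 0.0113          5
#>  3 gbdt        test           0.775 0.0539          5
#>  4 gbdt        train          0.923 0.0106          5
#>  5 glm         test           0.781 0.0238          5
#>  6 glm         train          0.811 0.0118          5
#>  7 lasso       test           0.776 0.0138          5
#>  8 lasso       train          0.802 0.0160          5
#>  9 mlp         test           0.774 0.0248          5
#> 10 mlp         train          0.817 0.0247          5
#>
#> Top-rated features per model:
#>  1 elastic_net coefficients age                0.341    0.0649          5
#>  2 elastic_net coefficients nihss              0.262    0.0328          5
#>  3 gbdt        shap         age                0.400    0.248           5
#>  4 gbdt        shap         nihss              0.333    0.167           5
#>  5 glm         coefficients age                0.339    0.0655          5
#>  6 glm         coefficients nihss              0.261    0.0316          5
#>  7 lasso       coefficients age                0.384    0.0805          5
#>  8 lasso       coefficients nihss              0.308    0.120           5
#>  9 mlp         deep_taylor  sex                0.199    0.0582          5
#> 10 mlp         deep_taylor  thrombolysis       0.190    0.0947          5
```

Reading the output: every model reaches a similar test AUC (~0.78 here;
the planted-truth Monte-Carlo ceiling for this cohort is ≈ 0.82), the
tree ensemble shows the largest train–test gap, and the coefficient- and
Shapley-based rankings put age and NIHSS on top.  At n = 314 with 5
shuffles the MLP's deep-Taylor rating is still noisy (its top features
vary shuffle to shuffle); on larger cohorts — e.g. n = 5,000 with 10
shuffles, as the test suite runs — all five models rank age and NIHSS
as the two most important features.

`plot_performance(report)` and `plot_importance(report)` (or
`autoplot(report, type = ...)`) draw the median ± IQR AUC chart and the
mean ± SD rating bars.  `tidy()`/`glance()` methods cover fitted models
and reports.  A thin CLI over the same functions lives at
`inst/cli/strokexplain.R` (`simulate`, `run`, `report` subcommands).

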