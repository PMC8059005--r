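# mixgain

Benchmarking missing-data imputation on mixed-type clinical tables, with a
generative adversarial imputation network (GAIN) at the core.

Large clinical registers routinely lose cells to non-collection: skewed
laboratory values, imbalanced treatment indicators, and demographic fields
all go missing while the outcome variables of the underlying cohort study
stay complete. mixgain is for biostatisticians who want to *measure* how well
an imputation method would recover such data before trusting it: it takes a
complete table, deliberately amputes it missing-at-random (MAR), imputes it
back with several methods, and scores each method per variable.

## What it implements

* **GAIN for mixed types** — a generator `G` proposing values for every cell
  from the mean-filled, min–max/one-hot encoded data `x̃` and mask `m`
  (1 = observed), and a discriminator `D` trying to tell observed from
  imputed entries given a hint matrix `H` that reveals each mask entry with
  probability `p_hint`. The generator minimizes

  `−mean_{m=0} log D(x̂, H) + α·MSE_obs,cont + β·CE_obs,cat`

  (reconstruction weighted separately for continuous and categorical
  variables), the discriminator its cross-entropy against `m`; training
  alternates `k` discriminator steps with one generator step on minibatches,
  with batch-normalized generator hidden layers. Imputation is
  `x̂ = m⊙x + (1−m)⊙G(x̃, m)`, decoded, observed cells copied through
  verbatim.
* **Calibrated MAR amputation** — per-cell Bernoulli missingness on
  independent variables with probability `logit⁻¹(c_j + w_jᵀz_i)` in the
  standardized encoded outcomes `z`, weights randomized per replicate,
  intercepts bisected so the realized rate matches the nominal 20%/50%.
* **Metrics and comparison** — per-variable NRMSE
  (`sqrt(mean((x̂−x)²))/mean(x)` over amputed cells) and PFC (fraction of
  amputed categorical cells imputed to the wrong category), averaged over
  repeated imputations, with Shapiro–Wilk-gated ANOVA/Kruskal–Wallis and
  pairwise method tests.
* **Baselines** — mean/mode, and an iterative chained imputer (20-tree
  forests, `sqrt(d)` variables per split, ≤ 10 sweeps with the standard
  difference-based stop; a deterministic linear family for closed-form
  tests).
* **Greedy hyperparameter search** over a validation holdout, a
  Gaussian-copula **synthetic cohort generator** (presets `dm_like`,
  `ht_like`) with dial-controlled skewness and class imbalance, and an
  end-to-end **benchmark pipeline** with a byte-reproducible manifest.

See `vignettes/mixgain-methods.Rmd` for the models, assumptions and design
decisions.

## Worked example

```r
library(mixgain)

spec       <- cohort_preset("ht_like", n = 2000, seed = 42)  # 5 continuous + 5 categorical predictors, 2 outcomes
truth      <- generate_cohort(spec)
schema     <- spec$schema
mech       <- draw_mar_mechanism(truth, schema, rate = 0.2, seed = 1)
incomplete <- ampute(truth, mech, seed = 2)
mask       <- mask_from_data(incomplete)

cfg <- gain_config(n_iterations = 2000, optimizer = "adam",
                   learning_rate = 0.001, alpha = 100, beta = 100, seed = 3)
fit <- gain(incomplete, schema, cfg)
fit
#> <gain_fit> 20 encoded columns, 2000 iterations (adam, lr 0.001)
#>   final losses: discriminator 0.0309, generator 5.9698

imputed <- impute_gain(fit, incomplete)
report <- dplyr::bind_rows(
  evaluate_imputations(list(imputed), truth, mask, schema, method = "gain"),
  evaluate_imputations(list(impute_mean_mode(incomplete, schema)),
                       truth, mask, schema, method = "mean")
)
dplyr::arrange(report, variable, method)
#> # A tibble: 20 × 7
#>    method variable         metric   mean    sd     m n_cells
#>    <chr>  <chr>            <chr>   <dbl> <dbl> <int>   <int>
#>  1 gain   age              nrmse  0.162      0     1     406
#>  2 mean   age              nrmse  0.193      0     1     406
#>  3 gain   antihypertensive pfc    0.0754     0     1     398
#>  4 mean   antihypertensive pfc    0.0754     0     1     398
#>  5 gain   bmi              nrmse  0.160      0     1     377
#>  6 mean   bmi              nrmse  0.175      0     1     377
#>  ...
```

Each row is one variable: `mean` is the error of a single imputation
(NRMSE for continuous, PFC for categorical variables) over the 400-odd
amputed cells of that variable, `sd` its spread over repeated imputations
(one repeat here, hence 0). GAIN clearly beats the mean baseline on the
correlated continuous variables; on a near-independent, imbalanced
indicator like `antihypertensive` both methods fall back on the majority
class and tie — imputation can only recover what the other variables
predict. `autoplot(fit)` shows the loss trace; the low final
discriminator loss reflects the high hint rate (`p_hint = 0.9` reveals
most of the mask). For a full comparison, `run_benchmark()` loops rates ×
replicates × methods × repeats and writes reports, comparison tables and
a rerunnable manifest.

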