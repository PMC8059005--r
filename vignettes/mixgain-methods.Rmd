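---
title: "Adversarial imputation of mixed-type clinical tables: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial imputation of mixed-type clinical tables: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mixgain is a benchmarking harness for missing-data imputation on the kind of
table that comes out of large clinical registers: tens of thousands of
subjects, a mix of continuous laboratory values (often strongly right-skewed)
and categorical history/treatment indicators (often imbalanced), together
with fully observed binary outcome variables. Its centrepiece is a
generative adversarial imputation network (GAIN) adapted for mixed variable
types; around it sit a calibrated missing-at-random (MAR) amputation
simulator, reference imputers, NRMSE/PFC error metrics with a method
comparison layer, a greedy hyperparameter search, and a synthetic cohort
generator so the whole pipeline runs without access to any restricted data.

This vignette records the models, the tunable parameters, and the design
choices that were genuinely open, in the order the pipeline uses them.

## Data model

A `mixed_schema()` declares each variable `continuous` or `categorical`
(with an ordered category list) and assigns a role: **independent**
variables are the imputation targets, **dependent** variables (clinical
outcomes) are fully observed by design and drive the MAR mechanism.
Missingness is carried by `NA` in tibbles and by 0 entries of a
positional 0/1 mask matrix `M` (1 = observed); on disk, missing cells are
empty CSV fields, and continuous values are serialized with 17
significant digits so a write/read round-trip is bit-exact. Row order is
significant — masks are positional — and repeated-measure layouts are out
of scope.

## MAR amputation

Given a complete table, missingness is introduced cell-wise into each
independent variable $j$ of row $i$ as

$$\Pr(\text{missing}_{ij}) = \operatorname{logit}^{-1}(c_j + w_j^\top z_i),$$

where $z_i$ collects the encoded, per-column standardized dependent
variables. The text this reproduces specifies Bernoulli missingness driven
by a linear combination of fully observed outcomes but no link function;
the logistic link is the canonical choice and makes the calibration below
monotone. Weights $w_j$ are drawn i.i.d. standard normal per (target,
driver) pair, freshly for each replicate, so each of the (default 10)
replicate incomplete datasets carries a different randomized mechanism.
Standardizing the encoded drivers keeps weight magnitudes comparable
across continuous and one-hot driver columns; note the standardized
one-hot block of a binary outcome is collinear, so the identifiable
signal per outcome is the contrast of its two weights.

The intercept $c_j$ is calibrated by bisection so that the mean
missingness probability over the rows of the table equals the nominal
rate (0.2 or 0.5 in the benchmark design) to within $10^{-6}$; the mean
is strictly increasing in $c_j$, so the root is unique. Mechanism drawing
and mask sampling use separate derived RNG streams, making replicate sets
exactly reproducible. Missingness is sampled independently across target
variables given the drivers — cross-variable missingness correlation is
deliberately not modelled. Dependent variables are never amputed.

## Encoding

GAIN trains on an $n \times D$ matrix in $[0,1]$: continuous variables are
min–max scaled by their observed range (not z-scored, so that bounded
generator outputs decode directly; out-of-range imputations are clipped to
the observed range), categorical variables are one-hot encoded in schema
order. A constant continuous column has no usable scale and is an error.
Decoding inverts the affine map and takes the arg-max of each categorical
block, ties broken by the lowest category index for reproducibility.
Masks and hints live at variable granularity and are replicated across
one-hot blocks: a categorical value is observed or missing as a whole.

The generator's noise input is replaced by the **mean fill**: each missing
encoded entry is set to the observed mean of its column, which for a
one-hot block is the observed class frequency vector. This is one of the
three modifications to the basic GAIN construction the package
implements, the others being batch normalization and the mixed-type loss
below.

## The adversarial model

The generator $G$ is a fully connected network from the $2D$-vector
$[\tilde x \,\|\, m]$ (mean-filled data, variable mask) to $D$ outputs —
sigmoid on continuous columns, softmax within each categorical block, so
softmax blocks sum to 1 by construction. The discriminator takes
$[\hat x \,\|\, h]$, where $\hat x = m \odot x + (1-m) \odot G(\cdot)$ and
$h$ is the hint matrix, and emits per-column observedness probabilities.
The hint reveals each variable's true mask value with probability
$p_{hint}$ and is 0.5 otherwise; without a sufficiently informative hint
the adversarial game is not identifiable, hence the high default
$p_{hint} = 0.9$.

Losses, with $\varepsilon = 10^{-8}$ clipping inside all logarithms:

* discriminator: mean binary cross-entropy between its probabilities and
  the mask over **all** entries. (Restricting to unrevealed entries is the
  theoretically cleaner variant; the all-entries form follows the widely
  used reference implementation and is the documented choice here.)
* generator:
  $-\frac{1}{|1-m|}\sum_{m_{ij}=0} \log p_{ij}
  \;+\; \alpha \cdot \mathrm{MSE}_{\text{obs, cont}}
  \;+\; \beta \cdot \mathrm{CE}_{\text{obs, cat}}$,
  the mixed-type combination with separate continuous ($\alpha$) and
  categorical ($\beta$) reconstruction weights. Normalizers are counts of
  observed entries/blocks, not $nD$, so $\alpha$ and $\beta$ keep their
  meaning as the missingness rate changes.

Each training iteration draws a fresh uniform minibatch, performs `k`
discriminator steps (interpreting `k` as the standard
discriminator-steps-per-generator-step GAN knob; default 1) and one
generator step. Batch normalization is applied to generator hidden layers
only — discriminator BN is known to destabilize adversarial training and
is off by default, though exposed as a switch. Parameters initialize from
a fan-in-scaled uniform distribution drawn from the seeded stream;
training, hint sampling and minibatching all consume one seeded RNG, so a
config and dataset determine the fitted model bit-exactly. All of it is
plain base-R matrix algebra; at these layer widths (tens of encoded
columns) there is nothing for a GPU to win.

Hyperparameter defaults, all overridable through `gain_config()`:
2 hidden layers of width $D$, ReLU, SGD at learning rate 0.01
(batch normalization is what permits a rate this large), batch 128,
$\alpha = \beta = 10$, 5,000 iterations. "Gradient-descent optimizer" in
the source description is ambiguous, so plain SGD, momentum and Adam are
all available rather than guessed between.

**Experiment configuration.** The package's own comparative experiments
(the sanity-ordering test and the acceptance script) train with Adam at
learning rate $10^{-3}$ and $\alpha = \beta = 100$ for 2,000 iterations.
With reconstruction weights of order 10 the adversarial term dominates
early training and convergence at desk scale is slow; weights of order
100 — the regime the original GAIN reference construction uses — make the
reconstruction signal dominant and reliably place GAIN below the
mean/mode baseline on both metrics within 2,000 iterations. This is a
configuration of the experiments, not a change to the library defaults.

Imputation computes $\hat x$ once with BN in inference mode (running
statistics), decodes, and then copies every observed cell from the input
verbatim — observed data are never round-tripped through the encoding.
Repeated imputation (`gain_multiple_impute()`, default $m = 100$ in the
benchmark design) derives independent training seeds from the config
seed.

## Hyperparameter search

The tuning objective of the source description is unstated, so the
package constructs one: hide an additional fraction (default 0.1) of the
observed independent cells uniformly at random, train on the reduced
table, and score the held-out cells by mean per-variable NRMSE
(continuous) plus mean per-variable PFC (categorical). `greedy_search`
sweeps one hyperparameter at a time — structure first
(`n_iterations`, `hidden_layers`, `neurons_per_layer`), then
optimization (`learning_rate`, `optimizer`, `activation`), then loss
weights (`alpha`, `beta`), then adversarial knobs (`p_hint`, `k`) —
keeping the arg-min of each sweep (ties to the first candidate), one full
pass by default. A single holdout split is used; cross-validated scoring
is out of scope.

## Baselines

`impute_mean_mode()` is the null baseline (modal ties resolve in schema
order). `impute_iterative()` is a chained-model imputer in the missForest
mould: initialize by mean/mode, visit variables in increasing-missingness
order, re-fit a per-variable predictor on the currently completed data and
re-predict missing cells, and stop at 10 sweeps or as soon as the
standard difference criterion (normalized squared change of continuous
imputations plus changed-proportion of categorical ones) first increases,
returning the previous iterate. The forest family uses 20 trees and
$\sqrt{d}$ candidate variables per split, the printed reference settings.
The `linear` family — least squares on a hand-built dummy design, with a
linear probability model and arg-max classification for categorical
targets — is a transparent, deterministic stand-in useful for closed-form
tests; it is explicitly **not** a reimplementation of predictive mean
matching, and externally produced imputations can be scored through the
CSV contract instead.

## Evaluation

For one variable, over its **masked cells only** (observed cells are
preserved by construction, so scoring them would dilute every error
toward zero):

$$\mathrm{NRMSE} = \frac{\sqrt{\tfrac1N \sum_i (\hat x_i - x_i)^2}}{\tfrac1N \sum_i x_i},
\qquad \mathrm{PFC} = 1 - \frac{N_{\text{correct}}}{N}.$$

The NRMSE denominator is the mean of the *true* values over the masked
cells — the literal reading of the displayed formula — so a zero-mean
target is an error rather than a silent rescale. PFC is in $[0,1]$ by
construction. Per-variable metrics are averaged over the $m$ repeated
imputations with their SD. Method comparison per variable: Shapiro–Wilk
on pooled within-method residuals gates one-way ANOVA (normal) versus
Kruskal–Wallis; pairwise Welch t-tests (or rank-sum tests) run only when
the omnibus test is significant at 0.05; p-values are reported raw, with
no multiplicity correction applied.

## Synthetic cohorts

`generate_cohort()` draws a latent multivariate normal with a specified
correlation matrix (a Gaussian copula) and pushes each margin through its
target distribution: affine for normal margins, exponential for lognormal
ones — the lognormal $\sigma$ solves
$(e^{\sigma^2}+2)\sqrt{e^{\sigma^2}-1} = \text{skewness}$, so skewness is
a direct dial — and quantile thresholds for categorical margins, giving
exact control of class imbalance. Binary outcomes are Bernoulli with
logistic means in the latent predictor scores; using the latent scores
(rather than the transformed margins) keeps each coefficient's sign
interpretable for every margin type, since all transforms are monotone.
The `dm_like` preset (15 continuous + 6 categorical predictors, 7
outcomes, default n = 50,000) and `ht_like` preset (5 + 5 predictors, 2
outcomes, default n = 10,000) match the benchmark's cohort shapes, with
margins spanning near-symmetric to skewness ≈ 11 and minority
proportions down to 8.5%; an AR(1)-style latent correlation
($\rho = 0.5$) guarantees positive definiteness while giving neighbours
realistic dependence. All preset magnitudes are implementer-chosen,
plausible clinical values, documented as synthetic — they estimate no
real cohort.

What the generator deliberately does not emulate: longitudinal structure,
MNAR mechanisms, missingness in outcomes, interactions or non-monotone
dependence, measurement error, and the true joint distribution of any
restricted register. Tests passing on these cohorts therefore demonstrate
the machinery is correct and the methods behave sensibly under controlled
MAR — not that the same error levels would be observed on real data.

## Numerical choices and degenerate inputs

Probabilities are clipped at $10^{-8}$ inside logarithms; categorical
arg-max ties take the lowest index; constant continuous columns, fully
missing columns, and zero-mean NRMSE targets raise errors naming the
offending variable; non-finite losses abort training with the iteration
number. Every stochastic step takes an explicit seed, derived seeds stay
below $2^{31}$, and the caller's RNG state is always restored.

## Problem sizes in the shipped checks

The test-suite experiments run at deliberately modest scale, chosen so
the full suite completes in a few minutes while each property still has
power: metric oracles on 1,000 random instances; amputation calibration
on a dm_like table of n = 10,000 over 10 mechanism draws per rate; the
GAIN-versus-baseline ordering on n = 2,000 with 2,000 training iterations
and 3 seeds; the byte-determinism pipeline on n = 300. The acceptance
script mirrors this desk scale (n = 5,000 calibration, n = 2,000
benchmark, m = 3 repeats). The full-scale design — n up to 50,000, 10
replicates, m = 100 — runs through the identical code paths via
`benchmark_profile("paper")`.

## Known limitations

Single imputations are evaluated for accuracy only; multiple-imputation
pooling (Rubin's rules) and post-imputation inference validity are out of
scope. The networks are fully connected feed-forward only. The iterative
baseline's linear family is not predictive mean matching. NRMSE is
undefined for zero-mean targets by the formula implemented, and PFC
cannot exceed 1 by construction.
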