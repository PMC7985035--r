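---
title: "Neural-network Cox models and two-stage multi-modal fusion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network Cox models and two-stage multi-modal fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survnnet)
```

# The model

`coxnnet()` fits a two-layer network whose output node is a Cox
proportional-hazards regression. For a sample with feature vector $x$,

$$\eta = \beta^\top g(W^\top x + b), \qquad g = \tanh,$$

where $W$ is $p \times h$, $h = \lfloor\sqrt{p}\rfloor$ (minimum 1), and
$\beta$ has no intercept: the partial likelihood is invariant to adding a
constant to all $\eta$, so an output bias would be unidentifiable. The
training objective is the Breslow-tie Cox partial log-likelihood divided by
the number of events, minus an L2 penalty $\lambda(\|W\|_2^2 +
\|\beta\|_2^2)$ (biases unpenalized):

$$\frac{1}{D}\sum_{i:\,d_i=1}\Big[\eta_i - \log\!\!\sum_{j:\,T_j \ge T_i}\!\! e^{\eta_j}\Big] \;-\; \lambda\big(\|W\|^2+\|\beta\|^2\big).$$

Dividing by the event count $D$ makes the fixed gradient-ascent step usable
across sample sizes; it rescales the objective, not the optimum.

Assumptions are those of any Cox model: proportional hazards (the feature
effect multiplies a common baseline hazard and does not change over time)
and censoring independent of the event process given the features. The
network relaxes only the *linearity* of the log hazard in the features.

## Training

Optimization is plain full-batch gradient ascent with a fixed step,
deliberately free of momentum or adaptive schedules so a run is exactly
reproducible from its seed. Each epoch an independent inverted-dropout mask
switches hidden nodes off with probability `dropout` and rescales the
survivors by $1/(1-\text{dropout})$; inference therefore needs no
rescaling, and prediction is deterministic. A mask that would silence every
node is redrawn. Weights are initialized Glorot-style (uniform on
$\pm\sqrt{6/(\text{fan-in}+\text{fan-out})}$), biases at zero. All
randomness — initialization and the per-epoch masks — flows from the `seed`
argument, and the caller's RNG state is saved and restored, so two fits
with the same inputs and seed are bit-identical.

Features are z-scored column-wise with training-split statistics (stored in
the fit and re-applied by `predict`); constant columns are centred and left
unscaled. Mixed-unit inputs such as morphometric image features make a
fixed-step optimizer unstable without this.

If the objective or any weight becomes non-finite the fit aborts with a
diagnostic rather than returning garbage; the practical trigger is an L2
penalty large enough that the decay factor $1 - 2\,\mathrm{lr}\,\lambda$
leaves $[-1, 1]$, i.e. $\lambda \gtrsim 50$ at the default step.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden` | $\lfloor\sqrt{p}\rfloor$, min 1 | hidden-layer width; the square-root rule keeps the parameter count sub-linear in $p$ |
| `dropout` | 0.7 | per-epoch probability a hidden node is silenced (dimensionless) |
| `lambda` | 0 (CV-selected) | L2 penalty weight on $W$ and $\beta$ |
| `learning_rate` | 0.01 | gradient-ascent step (per unit of per-event log-likelihood) |
| `epochs` | 500 | full-batch passes |
| `lambda_grid` | $10^{-4} \dots 1$, 5 points log-spaced | candidates for grid-search CV |
| `folds` | 5 | cross-validation folds |
| `train_fraction` | 0.8 | holdout training share |
| `repetitions` | 20 | random holdout splits |

The dropout rate, learning rate, epoch count, fold count, holdout fraction
and repetition count are the standard operating point for this model family
on cohorts of a few hundred samples; the L2 grid and its selection
criterion are this package's choices (see below).

## Choices the method leaves open, and what this package does

* **Hidden activation.** Fixed to `tanh` by default (bounded, zero-centred,
  the historical choice for this architecture); `identity` is available,
  and with `hidden = p`, `dropout = 0` the model class then contains linear
  Cox regression — a property the tests exploit as an oracle.
* **CV selection criterion.** The mean *validation partial log-likelihood
  per event*, not the validation C-index: it is the training objective,
  smooth in the penalty, and defined even when a fold has few comparable
  pairs. The validation C-index is reported alongside in the score table.
* **Tied event times.** Breslow approximation (tied events share one
  risk-set denominator). The Efron variant could be swapped into
  `cox_pll()`/`cox_pll_grad()` without touching the training loop.
* **Ties in the C-index.** The pair-counting form is implemented literally:
  $1\{\eta_i < \eta_j\}$, so tied risk scores count as discordant. Most
  survival software (e.g. `survival::concordance`) awards ties 1/2; expect
  third-decimal differences on data with tied predictions. Pairs with tied
  times fire neither indicator and drop out of both numerator and
  denominator.
* **Median dichotomization.** `eta <= median` is low risk. When heavy ties
  at the median would empty a group, a rank-based split at
  $\lfloor n/2\rfloor$ is used instead. On a held-out set the threshold is
  the *training*-set median PI (`coxnnet_holdout()` does this
  automatically): a median learned on test labels is leakage and visibly
  shifts log-rank p-values.
* **Two-stage scope.** The entire two-stage procedure — both first-stage
  fits, their hyperparameter searches, and the second-stage fit — runs
  inside each training split of a holdout repetition. Re-searching
  hyperparameters per repetition costs a constant factor
  (`(m+1) * (|grid| * folds + 1)` fits per repetition) but is the only
  leakage-free reading. Fused activations are re-standardized by the
  stage-two fit's own z-scoring, since tanh outputs are bounded but not
  centred.
* **Feature importance split.** The substitution mean should be the
  training mean; `feature_importance()` defaults to the column means of the
  matrix it is given, so pass training data (or training means via
  `means=`).
* **Tile density.** "Density" as a literal summed-RGB score ranks bright
  tiles first, which on H&E images favours background over tissue
  (hematoxylin/eosin-stained tissue is darker than the white slide
  background). The literal sum is the default; `mode = "inverted-sum"`
  scores `sum(255 - value)` for tissue-dense selection. Partial tiles at
  the right/bottom margins are discarded — a partial tile's density is not
  comparable to a full tile's. Channel normalization is applied to the
  selected tiles (selection first, then normalization, following the
  processing order of the pipeline this mirrors); scaled intensities are
  clipped to $[0, 255]$ and kept in floating point.
* **Association thresholds.** "Correlation above 0.1" is read as
  $|r| > 0.1$ — protective (negative) associations are as meaningful as
  harmful ones. No multiple-testing correction is applied to the pairwise
  filter, matching classical practice for this analysis; a
  Benjamini-Hochberg column is emitted alongside, clearly an extension, for
  the user's judgment. Under a global null the 500 raw tests at
  $\alpha = 0.05$ would admit roughly 25 false edges, which is why the
  planted-structure test in this package uses a stricter $|r|$ cut.
* **Univariate hazard signs** come from `survival::coxph`. Under a
  monotone partial likelihood (perfect separation) the MLE is infinite and
  `coxph` returns `NA`; the sign is then taken from the score statistic at
  $\beta = 0$, which determines the direction of the maximizer. Signs with
  $|z| < 1$ are flagged unstable.

# The simulators

`simulate_survival()` draws standard-normal features (the informative block
equicorrelated at `rho = 0.2` through a shared latent factor), builds a
linear true log hazard `eta`, draws event times exponentially with rate
$\lambda_0 e^{\eta}$ ($\lambda_0 = 10^{-3}$ per day, so median survival is
around 700 days at $\eta = 0$; a Weibull `shape` flag is available), and
censors with an independent exponential time whose rate is calibrated by
bisection so the realized censoring fraction hits the target (default 30%,
typical of retrospective cancer cohorts) within a few percent. The true
`eta` is returned so oracle concordances can be computed.

`simulate_modalities()` gives two feature matrices with disjoint informative
sets and `eta = eta_A + eta_B`: neither modality alone can reach the fused
oracle, the cleanest possible testbed for the claim that second-stage
fusion beats single-modality models. Defaults (n = 300, p = 40 per
modality, 5 informative features of effect 0.7 each, 30% censoring) put the
single-modality oracles near C = 0.7 and the fused oracle near 0.83 —
the regime the method targets.

What the simulators do *not* emulate: the heavy-tailed, mixed-unit
distributions of real morphometric features; correlation between the two
modalities (real image and expression features of one tumour are not
independent); informative censoring; and any spatial structure in the
synthetic images beyond planted bright blocks. Passing tests therefore
demonstrate correctness of the algorithms and the expected qualitative
behaviour under the proportional-hazards data-generating model — not
clinical-grade performance on real cohorts.

# Numerical notes

* The partial likelihood and its gradient are computed on sorted times with
  reverse cumulative sums; `exp(eta)` is centred at `max(eta)` before
  exponentiation, which cancels exactly in both value and gradient.
* Tie groups read the risk-set sum at the *first* index of the group (for
  the likelihood) and the cumulative hazard at the *last* index (for the
  gradient) — the two places tied times must be treated asymmetrically.
* The analytic gradient is verified against central finite differences
  (relative error $< 10^{-5}$ over random small instances) in the test
  suite; the C-index and partial likelihood are verified against explicit
  $O(n^2)$ pair enumeration and risk-set construction.
* Cross-validation folds, holdout splits and dropout masks are drawn in
  locally seeded RNG scopes, so any result is reconstructible from the
  data, the configuration and one integer.
* Problem sizes in the test suite (n of a few hundred, p up to 100, 10
  seeds per experiment) were chosen as the smallest that keep the
  qualitative contrasts (signal vs noise, fused vs single-modality) well
  away from sampling noise.

# Known limitations

* One hidden layer only; no mini-batching, momentum, or early stopping.
  These are out of scope by design — the model's appeal is that it is
  barely more complex than ridge Cox regression while capturing
  non-linearity.
* No competing risks, time-varying covariates, stratification, or interval
  censoring.
* Complete-case multi-modal analysis: samples must be present in every
  modality.
* The C-index tie convention (ties discordant) makes values from this
  package conservative relative to software that awards 1/2 per tie.
* Mean-substitution importance measures marginal, model-mediated effect;
  correlated informative features share credit and no conservation
  property links the scores to any total.
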