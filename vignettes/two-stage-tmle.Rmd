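---
title: "Two-Stage TMLE for cluster randomized trials with missing individual-level outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-Stage TMLE for cluster randomized trials with missing individual-level outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtmle)
library(dplyr)
```

## The problem

Cluster randomized trials (CRTs) assign an intervention to whole groups —
clinics, schools, communities — and measure outcomes on individuals within
them. Two features routinely threaten their analysis. First, individual
outcomes are missing for a subset of participants, and the probability of
being measured often depends on post-baseline variables (say, engagement in
care) that the intervention itself changes and that also predict the
outcome. A complete-case comparison of arms is then biased, and adjustment
strategies that condition on such a variable in a single pooled regression
fail, because the same variable mediates the treatment effect and confounds
the missingness–outcome relationship. Second, CRTs randomize few units
(tens of clusters), so chance imbalance on predictive baseline covariates
is the rule, and the analyst must commit to an adjustment strategy before
seeing outcomes or forfeit Type-I error control.

`crtmle` implements a two-stage targeted minimum loss-based estimator
(TMLE) that addresses both problems separately, an approach developed for
and applied in large community-randomized HIV trials.

## Stage 1: cluster endpoints under complete measurement

Within each cluster separately — so the missingness mechanism may differ
freely across clusters — the target is

$$Y^c = E\left[ E(Y \mid \Delta = 1, W, M) \right],$$

the mean outcome had every individual been measured, identified under the
assumption that measurement $\Delta$ is ignorable given baseline covariates
$W$ and post-baseline covariates $M$, with positivity. The TMLE:

1. fits the outcome regression $\bar Q(W,M) = E(Y \mid \Delta=1, W, M)$ on
   measured individuals with a discrete super learner (cross-validated
   selection among an intercept-only model, a main-terms logistic model,
   and optionally a smooth additive model);
2. fits the measurement mechanism $g(W,M) = P(\Delta = 1 \mid W, M)$ on all
   individuals the same way, truncating below at `g_min`;
3. updates $\bar Q$ through a weighted intercept-only logistic submodel
   (offset $\mathrm{logit}\,\bar Q$, weights $\Delta/\hat g$), which solves
   the efficient-influence-function estimating equation
   $\tfrac{1}{S^c}\sum_j \tfrac{\Delta_j}{\hat g_j}(Y_j - \bar Q^*_j) = 0$;
4. averages the targeted predictions over all $S^c$ individuals.

The estimator is doubly robust: consistent if either nuisance fit is
consistent. Degenerate situations are handled explicitly: a cluster with no
measured individuals is an error (the endpoint is unidentifiable), a
constant outcome returns the bounded constant predictor, and predicted
probabilities are kept inside $[10^{-4}, 1-10^{-4}]$ so logits stay finite.
The weighted form of the fluctuation was chosen over the unweighted
clever-covariate submodel for numerical stability when some $\hat g$ are
small; both solve the same estimating equation, which is what the tests
assert. The fluctuation coefficient is found by a safeguarded Newton solver
on the one-dimensional score (the submodel is a scalar family), capped at
$\pm 40$ on the logit scale; residuals of the solved equation below
$10^{-8}$ are enforced by test.

Two endpoint variants cover other designs: a Kaplan–Meier cumulative risk
at a horizon for survival endpoints with nondifferential censoring (via the
`survival` package), and a ratio endpoint for cross-sectional designs —
e.g. the joint probability of being infected and virally suppressed divided
by prevalence — estimated by applying the same TMLE to numerator and
denominator indicators and taking the ratio.

Key Stage-1 parameters:

* `g_min` (default 0.025): lower truncation for measurement probabilities.
  The default caps individual weights at 40; it protects against practical
  positivity violations at cluster sizes of 100–200 at the cost of a small
  bias when truncation binds.
* `sl_spec()` (default library `mean` + `glm`, 5 folds, discrete
  selection): candidate learners for both nuisance regressions. Folds are
  stratified on the outcome so small clusters do not yield single-class
  training folds; the additive learner (`gam`) reverts to a linear term for
  covariates with fewer than ten distinct values, where smoothing is
  unstable. Discrete selection was preferred to convex weighting because
  per-cluster samples are small and a single selected fit is easier to
  audit; the convex combination remains available.

## Stage 2: the intervention effect

With cluster endpoints $\hat Y^c$ in hand, the data reduce to one record
per cluster, $(E^c, W^c, A^c, \hat Y^c)$, where $W^c$ are summary measures
(by default within-cluster means) of individual baseline covariates. Every
cluster carries equal weight regardless of its size. A cluster-level TMLE
fits a working logistic outcome regression of $\hat Y^c$ on $A^c$ and at
most one adjustment covariate, fluctuates it with the two clever covariates
$H(1)=A^c/\hat g^c$ and $H(0)=(1-A^c)/(1-\hat g^c)$, and averages targeted
predictions under each arm over all clusters. The propensity score is the
known randomization probability when unadjusted, or a logistic working
model bounded to $[0.1, 0.9]$ when a covariate is named: with so few
clusters an unbounded fit can pin a cluster near 0 or 1 and destabilize the
clever covariate. With no adjustment covariate the working model is
saturated and the estimator reduces — exactly, by construction — to the
difference (or ratio) of arm means.

### Adaptive Prespecification

Which single covariate, if any, should enter the outcome regression, and
which the propensity score? The procedure selects, from a prespecified
candidate set always containing "none", the combination whose TMLE has the
lowest cross-validated variance of the estimated influence curve. The
search is sequential — outcome-regression candidate first (with the known
propensity score), then the propensity-score candidate given that choice —
matching the original description of the procedure; an exhaustive search
over pairs is available behind a flag. Ties break toward no adjustment,
then candidate order. Fewer than four clusters, or any degenerate
leave-one-out fold, falls back to the unadjusted estimator with a warning.

Three design choices deserve explanation, because the cross-validation
scheme is only loosely constrained by the method's published description:

* *Folds.* Leave-one-out over clusters; when the analysis keeps matched
  pairs, leave-one-pair-out, because the pair is the independent unit. The
  held-out unit's influence-curve value is evaluated at the training-fold
  nuisance fits and the full-data point estimates, so candidates are
  compared on a common centering.
* *The loss for estimated propensity scores.* A TMLE that *estimates* the
  known randomization probability from a predictive covariate is more
  efficient than one that plugs in the known value — a classical result:
  its influence curve is the residual of the known-probability influence
  curve after projecting onto the score space of the propensity working
  model. The selection loss therefore uses that projected influence curve
  (rescaled by $\sqrt{n/(n-2)}$ for the two fitted score terms). Without
  the projection the squared-influence-curve loss literally cannot see the
  gain from propensity-score estimation, and the procedure would almost
  never adjust. The propensity model itself is evaluated at its full-data
  fit inside the loss: it never touches the outcome, so holding it out
  protects against nothing, while leave-one-out refits occasionally pin
  the held-out cluster at a bound and let a single inflated value dominate
  the variance estimate.
* *Reported uncertainty stays conservative.* Standard errors and intervals
  from [inference()] always use the unprojected influence curve displayed
  in the estimator's definition. When the selector picks an estimated
  propensity score this overstates the variance somewhat; in the
  benchmark the resulting intervals run at or above nominal coverage
  (conservative when breaking the matches, close to nominal when keeping
  them), which we prefer at $N = 30$ clusters.

### Inference

The variance estimate is the sample variance of the estimated influence
curve divided by the number of independent units: $N$ clusters (Student's
t with $N-2$ degrees of freedom) when breaking the matches, or $J = N/2$
pair-averaged contributions (t with $J-1$) when keeping them. Risk-ratio
inference is on the log scale via the Delta method,
$IC_{\log} = IC(1)/\hat\psi_1 - IC(0)/\hat\psi_0$, with the interval
exponentiated. The pair-level influence curve is the mean of the two member
clusters' contributions; the published account of the matched-pair
construction lives in supplementary material we treat as unavailable, so
this follows the standard pair-matched inference literature and is
validated through the benchmark's matched power gain.

## The simulator

`dgp_config()` encodes the data-generating process of the simulation study
the package reproduces: 30 clusters of 100–200 individuals; two latent
cluster-level variables setting the means of individual baseline covariates
`W1`, `W2` (their within-cluster empirical means are the observed
cluster-level covariates `E1c`, `E2c`); a third latent variable `U3c`
shifting mediator and outcome and driving pair-matching; a binary mediator
`M` strongly increased by treatment; a binary outcome depending on
treatment, mediator, covariates, and `U3c`; and a measurement indicator
depending on arm, mediator, and covariates in opposite directions — so
missingness is strongly differential (roughly 62% of outcomes measured
under treatment, 33% under control, in long-run averages over the printed
equations) and driven by a post-baseline mediator. Counterfactuals under
both arms are drawn from shared uniforms, making individual-level
counterfactuals exact; the truth is computed from a population of 5000
clusters. Under the default process the true risk difference is about
−9.1 percentage points (risk ratio 0.88), and the average between-cluster
coefficient of variation of true outcomes is about 0.25 in the intervention
arm and 0.17 in the control arm.

What the generator does *not* emulate: real trials have non-exchangeable
cluster sizes, covariate-dependent cluster sizes, informative pair-matching
on observed (not latent) characteristics, and measurement mechanisms that
are not logistic in a handful of covariates. Passing the benchmark
therefore demonstrates correctness of the estimators under a controlled,
adversarial missingness process, not performance guarantees on any
particular real trial.

Pair-matching is implemented as rank-adjacent pairing on `U3c` (the stated
matching variable, with no algorithm prescribed; adjacent-rank is the
canonical choice and is recorded in the output). The null variant zeroes
every treatment term in the mediator and outcome equations while leaving
measurement differential, so the true risk difference is exactly zero
against a still-hostile missingness process.

## The benchmark

`run_benchmark()` replicates the full study: by default 500 simulated
trials, each analyzed by two-stage TMLE (both scales, keeping and breaking
the matches), the unadjusted complete-case t-test, and CARE (the
covariate-adjusted-residuals estimator: pooled logistic regression of the
outcome on baseline covariates excluding treatment, cluster-level
residuals, t-test on residuals; predictions are averaged over measured
individuals, matching the complete-case endpoint). Reported metrics follow
the study's table: mean point estimate, bias, SD of estimates and mean SE
(log scale for the risk ratio), 95% CI coverage, and power, each with a
Monte-Carlo half-width. Problem sizes used throughout the package's tests
and acceptance script are the study's own: 500 replicates, 5000-cluster
truth populations, 200-trial measurement summaries. Mixed models, GEE and
doubly robust GEE are not reimplemented; they are off-the-shelf fits in the
original study, and the benchmark exposes per-replicate results so external
estimates can be scored alongside.

A small run (for illustration only — metrics at this size carry wide
Monte-Carlo bands):

```{r benchmark-small}
bm <- run_benchmark(dgp_config(), n_reps = 20, seed = 1)
tidy(bm) |> select(estimator, scale, matched, pt, bias, coverage, power)
```

## Worked example on one trial

```{r example}
trial <- simulate_trial(dgp_config(), matched = TRUE, seed = 42)
set.seed(42) # super-learner fold assignment
fits <- estimate_endpoints(trial)
summaries <- summarize_clusters(trial, fits)
spec <- adaptive_prespecification(summaries, candidates = c("e1c", "e2c"),
                                  scale = "rd", matched = TRUE)
est <- tmle_effect(summaries, spec, scale = "rd", matched = TRUE)
est
tidy(est)
```

## Known limitations

* Stage-1 adjustment happens within each cluster separately; with very
  small clusters or rare outcomes the nuisance fits degrade toward the
  complete-case mean, and a pooled (single-stage) TMLE would be more
  appropriate — that estimator is out of scope here.
* Survival endpoints support only nondifferential censoring (Kaplan–
  Meier); a TMLE for differential censoring is not implemented.
* Two arms only, cluster-level randomization probability 0.5 by default
  (configurable), population-level effects only.
* The asymptotic remainder conditions (Stage-1 rates, within-cluster
  dependence weak enough for a CLT in cluster size, clusters large relative
  to their number) are assumptions documented here, not quantities the
  package verifies.
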