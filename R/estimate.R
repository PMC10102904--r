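#' Estimate an intervention effect from an individual-level trial
#'
#' One-call interface running the full pipeline: Stage-1 endpoint
#' estimation per cluster, aggregation to cluster summaries, and Stage-2
#' effect estimation (with Adaptive Prespecification for the two-stage
#' TMLE). Comparator estimators are available through the same interface.
#'
#' @param trial A `crt_trial` tibble (from [read_trial()] or
#'   [simulate_trial()]).
#' @param estimator `"tmle2stage"` (default), `"ttest"` (complete-case
#'   cluster means, unadjusted t-test), or `"care"` (covariate-adjusted
#'   residuals).
#' @param scale `"rd"` or `"rr"` (two-stage TMLE only; comparators report
#'   the risk difference).
#' @param matched Keep the matches during analysis? Defaults to the trial's
#'   matched flag.
#' @param candidates Cluster-level covariates offered to Adaptive
#'   Prespecification (default `c("e1c", "e2c")`).
#' @param stage1 Stage-1 endpoint estimator for the TMLE pipeline:
#'   `"tmle"` (default) or `"mean"`.
#' @param stage1_learners Super-learner library for the Stage-1 nuisance
#'   fits (default empirical mean + main-terms logistic; add `"gam"` for
#'   the additive smooth learner).
#' @param g_min Truncation bound for measurement probabilities.
#' @param randomization_prob Known treatment probability (default 0.5).
#' @param seed Optional seed (cross-validation fold assignment is random).
#' @return A `crt_effect` object; use [generics::tidy()] for a one-row
#'   summary.
#' @export
#' @examples
#' trial <- simulate_trial(dgp_config(n_clusters = 10, cluster_sizes = 50),
#'                         seed = 1)
#' est <- crt_estimate(trial, estimator = "ttest")
#' generics::tidy(est)
crt_estimate <- function(trial,
                         estimator = c("tmle2stage", "ttest", "care"),
                         scale = c("rd", "rr"), matched = NULL,
                         candidates = c("e1c", "e2c"),
                         stage1 = c("tmle", "mean"),
                         stage1_learners = c("mean", "glm"),
                         g_min = 0.025, randomization_prob = 0.5,
                         seed = NULL) {
  estimator <- match.arg(estimator)
  scale <- match.arg(scale)
  stage1 <- match.arg(stage1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(matched)) matched <- is_matched(trial)

  if (estimator == "care") {
    return(care_estimate(trial, matched = matched))
  }
  if (estimator == "ttest") {
    fits <- estimate_endpoints(trial, method = "mean")
    summaries <- summarize_clusters(trial, fits)
    return(ttest_unadjusted(summaries, matched = matched))
  }
  spec <- sl_spec(stage1_learners)
  fits <- estimate_endpoints(trial, method = stage1, or_spec = spec,
                             g_spec = spec, g_min = g_min)
  summaries <- summarize_clusters(trial, fits)
  adj <- adaptive_prespecification(summaries, candidates = candidates,
                                   scale = scale, matched = matched,
                                   randomization_prob = randomization_prob)
  tmle_effect(summaries, spec = adj, scale = scale, matched = matched,
              randomization_prob = randomization_prob)
}
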