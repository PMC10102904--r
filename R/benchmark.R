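#' Benchmark CRT estimators over repeated simulated trials
#'
#' Replicates the full simulation study: trials are generated from the
#' configured process with pair-matched randomization, each estimator is
#' applied both keeping and breaking the matches (two-stage TMLE on the
#' risk-difference and risk-ratio scales; comparators on the risk
#' difference), and performance is aggregated against the true effects from
#' [compute_truth()]. Reported metrics per estimator/scale/analysis: the
#' mean point estimate, bias (mean estimate minus truth), the SD of the
#' point estimates and the mean standard-error estimate (both on the log
#' scale for the risk ratio), 95% CI coverage, and power (the proportion of
#' two-sided 0.05-level rejections of the null), each with a Monte-Carlo
#' half-width so scaled-down runs stay interpretable.
#'
#' @param config A [dgp_config()].
#' @param estimators Subset of `c("tmle2stage", "ttest", "care")`.
#' @param n_reps Number of simulated trials (default 500).
#' @param seed Master seed; per-replicate streams are derived from it so
#'   results are reproducible and replicates independent.
#' @param truth_population Number of clusters used to compute the true
#'   effects (default 5000).
#' @param candidates Adjustment candidates for Adaptive Prespecification.
#' @param stage1_learners Stage-1 super-learner library (default empirical
#'   mean + main-terms logistic; add `"gam"` for the smooth learner).
#' @return A `crt_benchmark` object: `metrics` (tidy tibble), `truth`,
#'   `replicates` (per-trial estimates), and the run settings. `tidy()`
#'   returns the metrics; `autoplot()` displays them.
#' @export
run_benchmark <- function(config = dgp_config(),
                          estimators = c("tmle2stage", "ttest", "care"),
                          n_reps = 500, seed = 1,
                          truth_population = 5000,
                          candidates = c("e1c", "e2c"),
                          stage1_learners = c("mean", "glm")) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  stopifnot(n_reps >= 1)
  seeds <- derive_seeds(seed, n_reps + 1)
  truth <- compute_truth(config, n_population = truth_population,
                         seed = seeds[1])

  sl <- sl_spec(stage1_learners)
  one_rep <- function(rep) {
    set.seed(seeds[rep + 1])
    trial <- simulate_trial(config, matched = TRUE)
    rows <- list()
    add <- function(est, estimator, scale, matched) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        rep = rep, estimator = estimator, scale = scale, matched = matched,
        estimate = est$estimate, se = est$se,
        ci_lo = est$ci_lo, ci_hi = est$ci_hi, p_value = est$p_value
      )
    }
    if ("tmle2stage" %in% estimators) {
      fits <- tryCatch(
        estimate_endpoints(trial, method = "tmle", or_spec = sl, g_spec = sl),
        error = function(e) NULL
      )
      if (!is.null(fits)) {
        summ <- summarize_clusters(trial, fits)
        for (scale in c("rd", "rr")) {
          for (m in c(TRUE, FALSE)) {
            est <- tryCatch({
              adj <- adaptive_prespecification(summ, candidates = candidates,
                                               scale = scale, matched = m)
              tmle_effect(summ, spec = adj, scale = scale, matched = m)
            }, error = function(e) NULL)
            if (!is.null(est)) add(est, "tmle2stage", scale, m)
          }
        }
      }
    }
    if (any(c("ttest", "care") %in% estimators)) {
      summ_cc <- tryCatch(
        summarize_clusters(trial, estimate_endpoints(trial, method = "mean")),
        error = function(e) NULL
      )
      for (m in c(TRUE, FALSE)) {
        if ("ttest" %in% estimators && !is.null(summ_cc)) {
          est <- tryCatch(ttest_unadjusted(summ_cc, matched = m),
                          error = function(e) NULL)
          if (!is.null(est)) add(est, "ttest", "rd", m)
        }
        if ("care" %in% estimators) {
          est <- tryCatch(care_estimate(trial, matched = m),
                          error = function(e) NULL)
          if (!is.null(est)) add(est, "care", "rd", m)
        }
      }
    }
    dplyr::bind_rows(rows)
  }
  replicates <- dplyr::bind_rows(lapply(seq_len(n_reps), one_rep))

  metrics <- replicates |>
    dplyr::mutate(
      true_value = ifelse(.data$scale == "rd", truth$rd, truth$rr),
      null_value = ifelse(.data$scale == "rd", 0, 1),
      est_t = ifelse(.data$scale == "rr", log(abs(.data$estimate)),
                     .data$estimate),
      covered = .data$ci_lo <= .data$true_value &
        .data$true_value <= .data$ci_hi,
      rejected = .data$p_value < 0.05
    ) |>
    dplyr::group_by(.data$estimator, .data$scale, .data$matched) |>
    dplyr::summarise(
      n_ok = dplyr::n(),
      pt = mean(.data$estimate),
      bias = mean(.data$estimate) - .data$true_value[1],
      bias_mc_half_width = 1.96 * stats::sd(.data$estimate) /
        sqrt(dplyr::n()),
      sd_est = stats::sd(.data$est_t),
      mean_se = mean(.data$se),
      coverage = 100 * mean(.data$covered),
      coverage_mc_half_width = 196 * sqrt(mean(.data$covered) *
        (1 - mean(.data$covered)) / dplyr::n()),
      power = 100 * mean(.data$rejected),
      power_mc_half_width = 196 * sqrt(mean(.data$rejected) *
        (1 - mean(.data$rejected)) / dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_failed = n_reps - .data$n_ok)

  structure(
    list(metrics = metrics, truth = truth, replicates = replicates,
         n_reps = n_reps, seed = seed, config = config,
         estimators = estimators),
    class = "crt_benchmark"
  )
}
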