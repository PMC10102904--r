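new_stage1_fit <- function(y_c_hat, method, n, n_measured, details = list()) {
  structure(
    c(list(y_c_hat = y_c_hat, method = method, n = n,
           n_measured = n_measured), details),
    class = "stage1_fit"
  )
}

#' Per-cluster TMLE for the endpoint under complete measurement
#'
#' Estimates a single cluster's endpoint \eqn{E[E(Y | \Delta = 1, W, M)]} —
#' the mean outcome had every individual been measured — by targeted
#' minimum loss-based estimation, fully stratified on the cluster:
#' \enumerate{
#'   \item fit the outcome regression \eqn{\bar{Q}^0(W, M) = E(Y | \Delta=1, W, M)}
#'     on measured individuals with a super learner;
#'   \item fit the measurement mechanism \eqn{g(W, M) = P(\Delta = 1 | W, M)}
#'     on all individuals and truncate it below at `g_min`;
#'   \item fluctuate \eqn{\bar{Q}^0} through a weighted intercept-only
#'     logistic submodel (offset \eqn{logit\,\bar{Q}^0}, weights
#'     \eqn{\Delta/\hat g}) fit on measured individuals;
#'   \item average the targeted predictions \eqn{\bar{Q}^*} over all
#'     individuals in the cluster.
#' }
#' The weighted fluctuation solves the efficient-influence-function
#' estimating equation \eqn{\frac{1}{S^c}\sum_j \frac{\Delta_j}{\hat g_j}(Y_j - \bar{Q}^*_j) = 0};
#' its residual is recorded for diagnostics. The estimator is doubly
#' robust: consistent if either the outcome regression or the measurement
#' mechanism is estimated consistently. Continuous outcomes are linearly
#' rescaled to \[0, 1\] before the logistic fluctuation and back-transformed.
#'
#' @param data Data frame for one cluster with a `delta` column, a `y`
#'   column (`NA` when `delta == 0`), and the covariate columns.
#' @param covariates Character vector of covariate columns used for both
#'   nuisance regressions (default: all of `w1`, `w2`, `m` that are
#'   present).
#' @param or_spec,g_spec [sl_spec()]s for the outcome regression and the
#'   measurement mechanism (default: empirical mean + main-terms logistic).
#' @param g_min Lower truncation bound for the estimated measurement
#'   probabilities (default 0.025).
#' @return A `stage1_fit` list: `y_c_hat`, per-individual targeted
#'   predictions `qstar`, measurement probabilities `g` with the number
#'   truncated, fluctuation coefficient `eps`, and `eif_residual`.
#' @export
#' @examples
#' cl <- data.frame(w1 = rnorm(80), w2 = rnorm(80), m = rbinom(80, 1, 0.5))
#' cl$delta <- rbinom(80, 1, plogis(cl$w1))
#' cl$y <- ifelse(cl$delta == 1, rbinom(80, 1, plogis(cl$w1 + cl$m)), NA)
#' fit <- estimate_endpoint_tmle(cl)
#' fit$y_c_hat
estimate_endpoint_tmle <- function(data,
                                   covariates = intersect(c("w1", "w2", "m"),
                                                          names(data)),
                                   or_spec = sl_spec(c("mean", "glm")),
                                   g_spec = or_spec,
                                   g_min = 0.025) {
  stopifnot(nrow(data) >= 1, all(covariates %in% names(data)))
  delta <- data$delta
  if (sum(delta) == 0) {
    stop("no measured individuals in cluster; endpoint unidentifiable")
  }
  x <- data[covariates]
  y <- data$y
  meas <- delta == 1

  # Rescale continuous outcomes to [0,1] for the logistic fluctuation.
  y_obs <- y[meas]
  lo <- min(y_obs); hi <- max(y_obs)
  rescaled <- lo < 0 || hi > 1
  if (rescaled) {
    if (hi == lo) { hi <- lo + 1 }
    y_obs <- (y_obs - lo) / (hi - lo)
  }

  q_fit <- fit_super_learner(x[meas, , drop = FALSE], y_obs, or_spec)
  q0 <- bound(q_fit$predict(x))

  g_fit <- tryCatch(fit_super_learner(x, as.numeric(delta), g_spec),
                    error = function(e) NULL)
  if (is.null(g_fit)) {
    warning("measurement-mechanism fit failed; using empirical measured fraction")
    g <- rep(mean(delta), nrow(data))
  } else {
    g <- g_fit$predict(x)
  }
  n_truncated <- sum(g < g_min)
  g <- pmin(pmax(g, g_min), 1)

  eps <- solve_fluctuation(y_obs, offset = logit(q0[meas]),
                           w = 1 / g[meas])
  qstar <- expit(logit(q0) + eps)
  eif_residual <- sum((y_obs - qstar[meas]) / g[meas]) / nrow(data)
  y_c_hat <- mean(qstar)
  if (rescaled) {
    y_c_hat <- y_c_hat * (hi - lo) + lo
    qstar <- qstar * (hi - lo) + lo
  }
  new_stage1_fit(
    y_c_hat, "tmle", nrow(data), sum(meas),
    list(qstar = qstar, g = g, eps = eps, eif_residual = eif_residual,
         n_truncated = n_truncated, g_min = g_min,
         q_selected = q_fit$selected,
         g_selected = if (is.null(g_fit)) "empirical" else g_fit$selected,
         rescaled = rescaled)
  )
}

#' Complete-case empirical-mean endpoint for one cluster
#'
#' The unadjusted Stage-1 estimator: the mean outcome among measured
#' individuals. Unbiased only under measurement completely at random
#' (MCAR) within the cluster; the fit is flagged accordingly.
#'
#' @inheritParams estimate_endpoint_tmle
#' @return A `stage1_fit` with `y_c_hat` the complete-case mean and
#'   `assumption = "MCAR"`.
#' @export
estimate_endpoint_mean <- function(data) {
  meas <- data$delta == 1
  if (sum(meas) == 0) stop("no measured individuals in cluster")
  new_stage1_fit(mean(data$y[meas]), "mean", nrow(data), sum(meas),
                 list(assumption = "MCAR"))
}

#' Kaplan-Meier cumulative-risk endpoint for one cluster
#'
#' For survival-type endpoints with nondifferential right-censoring, the
#' cluster endpoint is the Kaplan-Meier cumulative risk at a horizon:
#' \eqn{1 - \prod_{t \le h}(1 - d_t / n_t)}.
#'
#' @param data Data frame with columns `time` (non-negative) and `event`
#'   (1 = failure, 0 = right-censored).
#' @param horizon Time at which the cumulative risk is evaluated.
#' @return A `stage1_fit` with `y_c_hat` the cumulative risk at `horizon`.
#' @export
estimate_endpoint_km <- function(data, horizon) {
  stopifnot(all(data$time >= 0), all(data$event %in% c(0, 1)),
            horizon >= 0)
  if (nrow(data) == 0) stop("no survival records")
  if (min(data$time) > horizon) {
    stop("no individuals at risk before the horizon")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  times <- fit$time
  surv <- fit$surv
  keep <- times <= horizon
  s_h <- if (any(keep)) surv[max(which(keep))] else 1
  new_stage1_fit(1 - s_h, "km", nrow(data), nrow(data),
                 list(horizon = horizon))
}

#' Ratio-type endpoint for one cluster (cross-sectional designs)
#'
#' For endpoints of the form \eqn{P(\text{joint event}) / P(\text{conditioning event})}
#' — e.g. viral suppression among the HIV-infected, estimated as the joint
#' probability of infection and suppression divided by prevalence — both
#' components are estimated with the per-cluster TMLE of
#' [estimate_endpoint_tmle()] and then ratioed.
#'
#' @param data Data frame with `delta`, joint-event indicator `y_num`,
#'   conditioning-event indicator `y_den` (both observed iff `delta == 1`,
#'   with `y_num <= y_den` individual by individual), and covariates.
#' @inheritParams estimate_endpoint_tmle
#' @return A `stage1_fit` with `y_c_hat` the ratio and both component fits
#'   under `numerator` and `denominator`.
#' @export
estimate_endpoint_ratio <- function(data,
                                    covariates = intersect(c("w1", "w2", "m"),
                                                           names(data)),
                                    or_spec = sl_spec(c("mean", "glm")),
                                    g_spec = or_spec,
                                    g_min = 0.025) {
  meas <- data$delta == 1
  if (any(data$y_num[meas] > data$y_den[meas])) {
    stop("joint-event indicator exceeds conditioning-event indicator")
  }
  num_dat <- data
  num_dat$y <- data$y_num
  den_dat <- data
  den_dat$y <- data$y_den
  num <- estimate_endpoint_tmle(num_dat, covariates, or_spec, g_spec, g_min)
  den <- estimate_endpoint_tmle(den_dat, covariates, or_spec, g_spec, g_min)
  if (den$y_c_hat <= 0) stop("denominator endpoint estimated as zero; ratio unidentifiable")
  new_stage1_fit(num$y_c_hat / den$y_c_hat, "ratio", nrow(data), sum(meas),
                 list(numerator = num, denominator = den))
}

#' Estimate every cluster's endpoint in a trial
#'
#' Maps a Stage-1 estimator over the clusters of a trial and returns a tidy
#' per-cluster table, ready for [summarize_clusters()] and Stage-2 effect
#' estimation.
#'
#' @param trial A `crt_trial` tibble.
#' @param method `"tmle"` (default) or `"mean"` (complete-case mean).
#' @inheritParams estimate_endpoint_tmle
#' @return A `stage1_fits` tibble with one row per cluster: `cluster_id`,
#'   `y_c_hat`, and for TMLE the diagnostics `eps`, `eif_residual`,
#'   `n_truncated`, `g_range_lo`, `g_range_hi`.
#' @export
estimate_endpoints <- function(trial, method = c("tmle", "mean"),
                               covariates = intersect(c("w1", "w2", "m"),
                                                      names(trial)),
                               or_spec = sl_spec(c("mean", "glm")),
                               g_spec = or_spec,
                               g_min = 0.025) {
  method <- match.arg(method)
  ids <- sort(unique(trial$cluster_id))
  rows <- lapply(ids, function(id) {
    cl <- trial[trial$cluster_id == id, , drop = FALSE]
    if (method == "tmle") {
      fit <- estimate_endpoint_tmle(cl, covariates, or_spec, g_spec, g_min)
      tibble::tibble(cluster_id = id, y_c_hat = fit$y_c_hat, eps = fit$eps,
                     eif_residual = fit$eif_residual,
                     n_truncated = fit$n_truncated,
                     g_range_lo = min(fit$g), g_range_hi = max(fit$g))
    } else {
      fit <- estimate_endpoint_mean(cl)
      tibble::tibble(cluster_id = id, y_c_hat = fit$y_c_hat,
                     eps = NA_real_, eif_residual = NA_real_,
                     n_truncated = NA_integer_,
                     g_range_lo = NA_real_, g_range_hi = NA_real_)
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("stage1_fits", class(tibble::tibble())),
            method = method)
}
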