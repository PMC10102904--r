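new_comparator_result <- function(estimator, estimate, se, df, ci, p_value,
                                  matched, extra = list()) {
  structure(
    c(list(estimator = estimator, scale = "rd", estimate = estimate,
           se = se, df = df, ci_lo = ci[1], ci_hi = ci[2],
           p_value = p_value, matched = matched), extra),
    class = c("crt_comparator", "crt_effect")
  )
}

#' Unadjusted t-test on complete-case cluster means
#'
#' The classic CRT analysis: aggregate outcomes to cluster-level
#' complete-case means and contrast arms with a t-test — pooled-variance
#' two-sample with `N - 2` degrees of freedom when breaking the matches, or
#' paired on within-pair differences with `N/2 - 1` degrees of freedom when
#' keeping them. Valid only when outcomes are missing completely at random
#' within arms.
#'
#' @param summaries A `cluster_summaries` tibble whose `y_c_hat` column
#'   holds complete-case cluster means (see [estimate_endpoints()] with
#'   `method = "mean"`).
#' @param matched Paired analysis? Defaults to the summaries' matched flag.
#' @param conf_level Confidence level (default 0.95).
#' @return A `crt_comparator` result (risk-difference scale).
#' @export
ttest_unadjusted <- function(summaries, matched = NULL, conf_level = 0.95) {
  if (is.null(matched)) matched <- isTRUE(attr(summaries, "matched"))
  y <- summaries$y_c_hat
  a <- summaries$a
  if (length(unique(a)) < 2) stop("both treatment arms must be present")
  if (matched) {
    wide <- data.frame(pair = summaries$pair_id, a = a, y = y)
    d <- tapply(wide$y * ifelse(wide$a == 1, 1, -1), wide$pair, sum)
    n_pairs <- length(d)
    est <- mean(d)
    se <- stats::sd(d) / sqrt(n_pairs)
    df <- n_pairs - 1
  } else {
    y1 <- y[a == 1]; y0 <- y[a == 0]
    est <- mean(y1) - mean(y0)
    n1 <- length(y1); n0 <- length(y0)
    sp2 <- ((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) /
      (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  tstat <- if (se > 0) est / se else ifelse(est == 0, 0, Inf * sign(est))
  new_comparator_result(
    "ttest", est, se, df, est + c(-1, 1) * tq * se,
    2 * stats::pt(-abs(tstat), df), matched
  )
}

#' Covariate-adjusted residuals estimator (CARE)
#'
#' Pools measured individuals across clusters, fits a logistic regression
#' of the outcome on baseline covariates (never the treatment), forms each
#' cluster's residual — the complete-case mean outcome minus the mean model
#' prediction over that cluster's measured individuals — and contrasts the
#' residuals by arm with a t-test (pooled-variance unmatched, paired when
#' keeping the matches). Adjusting for baseline predictors reduces, but
#' with post-baseline causes of missingness does not remove, complete-case
#' bias.
#'
#' @param trial A `crt_trial` tibble.
#' @param covariates Baseline covariate columns for the pooled regression
#'   (default `w1`, `w2`, `e1c`, `e2c`); must exclude the treatment.
#' @param matched Paired analysis? Defaults to the trial's matched flag.
#' @param conf_level Confidence level (default 0.95).
#' @param ridge Ridge penalty used only as a fallback when the pooled
#'   logistic regression fails to converge (separation); default 1e-4.
#' @return A `crt_comparator` result (risk-difference scale) with the
#'   per-cluster residuals attached.
#' @export
care_estimate <- function(trial, covariates = c("w1", "w2", "e1c", "e2c"),
                          matched = NULL, conf_level = 0.95, ridge = 1e-4) {
  if (is.null(matched)) matched <- is_matched(trial)
  stopifnot(all(covariates %in% names(trial)))
  meas <- trial$delta == 1
  dat <- trial[meas, , drop = FALSE]
  x <- cbind(1, as.matrix(dat[covariates]))
  fit <- fast_logit_fit(x, dat$y)
  if (!fit$converged) {
    warning("pooled logistic regression did not converge; refitting with a small ridge penalty")
    xtx <- crossprod(x) + diag(ridge, ncol(x))
    # one-step ridge-stabilized IRLS from the unpenalized coefficients
    eta <- drop(x %*% fit$coefficients)
    mu <- expit(eta)
    w <- mu * (1 - mu)
    z <- eta + (dat$y - mu) / pmax(w, 1e-8)
    fit$coefficients <- solve(crossprod(x * sqrt(w)) + diag(ridge, ncol(x)),
                              crossprod(x * w, z))
  }
  pred <- logit_predict(fit$coefficients, x)
  resid_tbl <- dat |>
    dplyr::mutate(.pred = pred) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      pair_id = .data$pair_id[1], a = .data$a[1],
      residual = mean(.data$y) - mean(.data$.pred), .groups = "drop"
    )
  if (length(unique(resid_tbl$a)) < 2) stop("both treatment arms must be present")
  if (matched) {
    d <- tapply(resid_tbl$residual * ifelse(resid_tbl$a == 1, 1, -1),
                resid_tbl$pair_id, sum)
    est <- mean(d)
    se <- stats::sd(d) / sqrt(length(d))
    df <- length(d) - 1
  } else {
    r1 <- resid_tbl$residual[resid_tbl$a == 1]
    r0 <- resid_tbl$residual[resid_tbl$a == 0]
    est <- mean(r1) - mean(r0)
    n1 <- length(r1); n0 <- length(r0)
    sp2 <- ((n1 - 1) * stats::var(r1) + (n0 - 1) * stats::var(r0)) /
      (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
  }
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  tstat <- if (se > 0) est / se else ifelse(est == 0, 0, Inf * sign(est))
  new_comparator_result(
    "care", est, se, df, est + c(-1, 1) * tq * se,
    2 * stats::pt(-abs(tstat), df), matched,
    extra = list(residuals = resid_tbl)
  )
}
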