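test_that("the unadjusted t-test matches closed-form two-sample algebra", {
  summ <- make_summaries(y = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                         a = c(1, 1, 1, 0, 0, 0))
  est <- ttest_unadjusted(summ, matched = FALSE)
  expect_equal(est$estimate, -0.3, tolerance = 1e-12)
  # pooled SD 0.1 across arms, SE = 0.1 * sqrt(2/3)
  expect_equal(est$se, 0.1 * sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(est$estimate / est$se, -3.674, tolerance = 1e-3)
  expect_equal(est$df, 4)

  ref <- t.test(summ$y_c_hat[summ$a == 1], summ$y_c_hat[summ$a == 0],
                var.equal = TRUE)
  expect_equal(est$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(c(est$ci_lo, est$ci_hi), as.numeric(ref$conf.int),
               tolerance = 1e-12)
})

test_that("identical arm means give a null estimate with p = 1", {
  summ <- make_summaries(y = c(0.4, 0.5, 0.6, 0.6, 0.5, 0.4),
                         a = c(1, 1, 1, 0, 0, 0))
  est <- ttest_unadjusted(summ, matched = FALSE)
  expect_equal(est$estimate, 0)
  expect_equal(est$p_value, 1)
})

test_that("matched t-test uses within-pair differences", {
  summ <- make_summaries(y = c(0.5, 0.6, 0.7, 0.4, 0.5, 0.6),
                         a = c(1, 1, 1, 0, 0, 0),
                         pair_id = c(1, 2, 3, 1, 2, 3), matched = TRUE)
  est <- ttest_unadjusted(summ, matched = TRUE)
  # constant within-pair difference: SE collapses to zero
  expect_equal(est$estimate, 0.1, tolerance = 1e-12)
  expect_equal(est$se, 0, tolerance = 1e-12)
  expect_equal(est$df, 2)
  expect_lt(est$p_value, 1e-10)

  varied <- make_summaries(y = c(0.5, 0.65, 0.7, 0.4, 0.5, 0.6),
                           a = c(1, 1, 1, 0, 0, 0),
                           pair_id = c(1, 2, 3, 1, 2, 3), matched = TRUE)
  est2 <- ttest_unadjusted(varied, matched = TRUE)
  ref <- t.test(c(0.5, 0.65, 0.7), c(0.4, 0.5, 0.6), paired = TRUE)
  expect_equal(est2$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(est2$se, unname(ref$stderr), tolerance = 1e-12)
  expect_equal(est2$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("CARE with an empty covariate set equals the unadjusted t-test", {
  trial <- make_complete_trial(
    y_by_cluster = list(c(1, 0, 1, 1), c(0, 0, 1, 0), c(1, 1, 1, 0),
                        c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 1, 1, 1)),
    a_by_cluster = c(1, 1, 1, 0, 0, 0)
  )
  care <- care_estimate(trial, covariates = character(0), matched = FALSE)
  fits <- estimate_endpoints(trial, method = "mean")
  tt <- ttest_unadjusted(summarize_clusters(trial, fits), matched = FALSE)
  expect_equal(care$estimate, tt$estimate, tolerance = 1e-10)
  expect_equal(care$se, tt$se, tolerance = 1e-10)
  expect_equal(care$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("CARE removes confounding through covariates that the raw t-test absorbs", {
  # outcome depends only on w1; arms differ in w1 prevalence; no treatment
  # effect. The raw contrast is large; the residual contrast vanishes.
  make_cluster <- function(id, a, n_w1, n_w0, pair) {
    w1 <- c(rep(1, n_w1), rep(0, n_w0))
    y <- c(rep(1, round(0.9 * n_w1)), rep(0, n_w1 - round(0.9 * n_w1)),
           rep(1, round(0.1 * n_w0)), rep(0, n_w0 - round(0.1 * n_w0)))
    tibble::tibble(cluster_id = id, pair_id = pair, a = a, e1c = mean(w1),
                   e2c = 0, w1 = w1, w2 = 0, m = 0L, delta = 1L, y = y)
  }
  rows <- list()
  for (i in 1:4) rows[[i]] <- make_cluster(i, 1, 20, 10, i)
  for (i in 5:8) rows[[i]] <- make_cluster(i, 0, 10, 20, i - 4)
  trial <- dplyr::bind_rows(rows)
  class(trial) <- c("crt_trial", class(tibble::tibble()))

  care <- care_estimate(trial, covariates = "w1", matched = FALSE)
  fits <- estimate_endpoints(trial, method = "mean")
  tt <- ttest_unadjusted(summarize_clusters(trial, fits), matched = FALSE)
  expect_equal(tt$estimate, 8 / 30, tolerance = 1e-12)
  expect_lt(abs(care$estimate), 1e-6)
})

test_that("comparators are invariant to cluster ordering in unmatched analyses", {
  trial <- simulate_trial(dgp_config(n_clusters = 8, cluster_sizes = 80),
                          matched = TRUE, seed = 17)
  shuffled <- trial[rev(seq_len(nrow(trial))), ]
  attr(shuffled, "matched") <- attr(trial, "matched")
  care1 <- care_estimate(trial, matched = FALSE)
  care2 <- care_estimate(shuffled, matched = FALSE)
  expect_equal(care1$estimate, care2$estimate, tolerance = 1e-10)

  fits1 <- estimate_endpoints(trial, method = "mean")
  fits2 <- estimate_endpoints(shuffled, method = "mean")
  t1 <- ttest_unadjusted(summarize_clusters(trial, fits1), matched = FALSE)
  t2 <- ttest_unadjusted(summarize_clusters(shuffled, fits2),
                         matched = FALSE)
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-12)
  expect_equal(t1$se, t2$se, tolerance = 1e-12)
})
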