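test_that("with complete measurement the TMLE endpoint is exactly the empirical mean", {
  set.seed(41)
  n <- 60
  cl <- data.frame(w1 = rnorm(n), w2 = rnorm(n), m = rbinom(n, 1, 0.5))
  cl$delta <- 1L
  cl$y <- rbinom(n, 1, plogis(cl$w1 + cl$m))
  tmle <- estimate_endpoint_tmle(cl)
  cc <- estimate_endpoint_mean(cl)
  expect_equal(tmle$y_c_hat, mean(cl$y), tolerance = 1e-12)
  expect_equal(tmle$y_c_hat, cc$y_c_hat, tolerance = 1e-12)
  expect_lt(abs(tmle$eif_residual), 1e-8)
})

test_that("the TMLE matches the stratified G-computation oracle on a binary covariate", {
  cl <- make_stratified_cluster()
  oracle <- gcomp_oracle(cl)
  # main-terms logistic with one binary covariate is saturated, so the TMLE
  # must reproduce the stratified estimate essentially exactly
  fit <- estimate_endpoint_tmle(cl, covariates = "w1",
                                or_spec = sl_spec("glm"),
                                g_spec = sl_spec("glm"), g_min = 0.01)
  expect_equal(fit$y_c_hat, oracle, tolerance = 1e-10)
  expect_lt(abs(fit$eif_residual), 1e-8)
})

test_that("complete-case means behave on edge cases", {
  cl <- data.frame(delta = c(1, 1, 1, 1), y = c(1, 0, 0, 1))
  expect_equal(estimate_endpoint_mean(cl)$y_c_hat, 0.5)
  one <- data.frame(delta = c(0, 1), y = c(NA, 1))
  expect_equal(estimate_endpoint_mean(one)$y_c_hat, 1)
  none <- data.frame(delta = c(0, 0), y = c(NA, NA))
  expect_error(estimate_endpoint_mean(none), "no measured")
  expect_error(estimate_endpoint_tmle(cbind(none, w1 = c(0, 1), m = 0)),
               "no measured")
})

test_that("endpoint estimates and measurement probabilities respect their bounds", {
  trial <- simulate_trial(dgp_config(n_clusters = 10, cluster_sizes = 60),
                          matched = TRUE, seed = 13)
  set.seed(13)
  fits <- estimate_endpoints(trial)
  expect_true(all(fits$y_c_hat >= 0 & fits$y_c_hat <= 1))
  expect_true(all(fits$g_range_lo >= 0.025 - 1e-12))
  expect_true(all(fits$g_range_hi <= 1 + 1e-12))
  expect_true(all(abs(fits$eif_residual) < 1e-8))
})

test_that("the per-cluster TMLE is doubly robust in large clusters", {
  s <- 5000
  run_case <- function(seed, p_y_fun, p_d_fun) {
    set.seed(seed)
    w <- runif(s, -2, 2)
    p_y <- p_y_fun(w)
    p_d <- p_d_fun(w)
    y_full <- rbinom(s, 1, p_y)
    delta <- rbinom(s, 1, p_d)
    cl <- data.frame(w1 = w, delta = delta,
                     y = ifelse(delta == 1, y_full, NA))
    fit <- estimate_endpoint_tmle(cl, covariates = "w1",
                                  or_spec = sl_spec("glm"),
                                  g_spec = sl_spec("glm"))
    c(tmle = fit$y_c_hat - mean(p_y),
      cc = mean(cl$y[delta == 1]) - mean(p_y))
  }
  # outcome regression misspecified for a main-terms logistic, measurement
  # mechanism correctly specified
  a <- vapply(1:25, function(r) run_case(
    900 + r,
    function(w) plogis(w + 1.5 * sin(2 * w)),
    function(w) plogis(0.8 * w)
  ), numeric(2))
  # outcome regression correctly specified, measurement misspecified
  b <- vapply(1:25, function(r) run_case(
    950 + r,
    function(w) plogis(-0.5 + w),
    function(w) plogis(0.3 - w + 1.5 * sin(2 * w))
  ), numeric(2))
  expect_lt(abs(mean(a["tmle", ])), 0.015)
  expect_lt(abs(mean(b["tmle", ])), 0.015)
  # the complete-case mean stays biased in both scenarios
  expect_gt(abs(mean(a["cc", ])), 0.04)
  expect_gt(abs(mean(b["cc", ])), 0.04)
})

test_that("the Kaplan-Meier endpoint matches a hand product-limit calculation", {
  # no censoring before the horizon: reduces to the empirical proportion
  nocens <- data.frame(time = c(1, 9, 2, 9), event = c(1, 0, 1, 0))
  expect_equal(estimate_endpoint_km(nocens, horizon = 5)$y_c_hat, 0.5)

  simple <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 1, 0))
  # by hand: t=1 S=3/4; t=3 at-risk 2, S=(3/4)(1/2)=3/8
  expect_equal(estimate_endpoint_km(simple, horizon = 4)$y_c_hat, 1 - 3 / 8)

  three <- data.frame(time = c(2, 4, 6), event = c(1, 0, 1))
  # by hand: t=2 S=2/3; censored at 4; t=6 at-risk 1, S=0 -> risk 1
  expect_equal(estimate_endpoint_km(three, horizon = 6)$y_c_hat, 1)
  expect_equal(estimate_endpoint_km(three, horizon = 5)$y_c_hat, 1 / 3)

  censored <- data.frame(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_equal(estimate_endpoint_km(censored, horizon = 5)$y_c_hat, 0)
  expect_error(estimate_endpoint_km(censored, horizon = 0.5), "at risk")
})

test_that("ratio endpoints divide component TMLEs and respect logical bounds", {
  n <- 20
  cl <- data.frame(
    w1 = rep(c(0, 1), each = 10), m = 0, delta = 1,
    y_num = rep(c(1, 0), times = c(6, 14)),
    y_den = rep(c(1, 0), times = c(8, 12))
  )
  fit <- estimate_endpoint_ratio(cl, covariates = "w1",
                                 or_spec = sl_spec("glm"))
  expect_equal(fit$y_c_hat, 0.75, tolerance = 1e-8)

  same <- cl
  same$y_num <- same$y_den
  expect_equal(estimate_endpoint_ratio(same, covariates = "w1",
                                       or_spec = sl_spec("glm"))$y_c_hat,
               1, tolerance = 1e-10)

  bad <- cl
  bad$y_num[10] <- 1
  bad$y_den[10] <- 0
  expect_error(estimate_endpoint_ratio(bad), "exceeds")
})

test_that("ratio endpoints under missingness match the stratified oracle applied twice", {
  base <- make_stratified_cluster()
  cl <- base
  cl$y_den <- cl$y
  cl$y_num <- ifelse(is.na(cl$y), NA, as.integer(cl$y == 1 & cl$w1 == 1))
  fit <- estimate_endpoint_ratio(cl, covariates = "w1",
                                 or_spec = sl_spec("glm"), g_min = 0.01)
  num_oracle <- gcomp_oracle(transform(base, y = cl$y_num))
  den_oracle <- gcomp_oracle(base)
  expect_equal(fit$y_c_hat, num_oracle / den_oracle, tolerance = 1e-8)
})
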