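test_that("the unadjusted TMLE reduces exactly to the difference in arm means", {
  summ <- make_summaries(matched = TRUE)
  est_u <- tmle_effect(summ, adjustment_spec(), scale = "rd",
                       matched = FALSE)
  est_m <- tmle_effect(summ, adjustment_spec(), scale = "rd", matched = TRUE)
  arm_means <- tapply(summ$y_c_hat, summ$a, mean)
  expect_identical(est_u$psi1, unname(arm_means["1"]))
  expect_identical(est_u$psi0, unname(arm_means["0"]))
  expect_identical(est_u$estimate, unname(arm_means["1"] - arm_means["0"]))
  # matched and unmatched analyses share the point estimate exactly
  expect_identical(est_m$estimate, est_u$estimate)
  expect_false(est_m$se == est_u$se && est_m$df == est_u$df)
})

test_that("the targeted estimator's influence curve is mean-zero", {
  set.seed(61)
  for (r in 1:10) {
    y <- runif(12)
    summ <- make_summaries(y = y, a = rep(c(1, 0), 6),
                           e1c = rnorm(12), pair_id = rep(1:6, each = 2))
    for (spec in list(adjustment_spec("e1c", NULL),
                      adjustment_spec(NULL, "e1c"),
                      adjustment_spec("e1c", "e2c"))) {
      est <- tmle_effect(summ, spec, scale = "rd", matched = FALSE)
      expect_lt(abs(mean(est$ic1 - est$ic0)), 1e-8)
      expect_lt(abs(mean(est$ic1)), 1e-8)
      expect_lt(abs(mean(est$ic0)), 1e-8)
    }
  }
})

test_that("covariate-adjusted targeting matches a root-finding oracle on a toy trial", {
  summ <- make_summaries(y = c(0.30, 0.55, 0.42, 0.60, 0.35, 0.68),
                         a = c(1, 1, 1, 0, 0, 0),
                         e1c = c(0, 1, 0, 1, 0, 1))
  est <- tmle_effect(summ, adjustment_spec("e1c", NULL), scale = "rd",
                     matched = FALSE)

  # oracle: independent logistic fit plus one-dimensional root finding for
  # each arm's fluctuation (clever covariates are disjoint across arms)
  or_fit <- suppressWarnings(glm(
    y_c_hat ~ a + e1c, data = summ, family = quasibinomial(),
    control = glm.control(epsilon = 1e-14, maxit = 100)
  ))
  q1 <- predict(or_fit, newdata = transform(summ, a = 1), type = "response")
  q0 <- predict(or_fit, newdata = transform(summ, a = 0), type = "response")
  g <- 0.5
  treated <- summ$a == 1
  f1 <- function(e) sum((summ$y_c_hat[treated] -
                           plogis(qlogis(q1[treated]) + e / g)) / g)
  f0 <- function(e) sum((summ$y_c_hat[!treated] -
                           plogis(qlogis(q0[!treated]) + e / (1 - g))) / (1 - g))
  e1 <- uniroot(f1, c(-5, 5), tol = 1e-14)$root
  e0 <- uniroot(f0, c(-5, 5), tol = 1e-14)$root
  psi1_oracle <- mean(plogis(qlogis(q1) + e1 / g))
  psi0_oracle <- mean(plogis(qlogis(q0) + e0 / (1 - g)))

  expect_equal(est$psi1, unname(psi1_oracle), tolerance = 1e-8)
  expect_equal(est$psi0, unname(psi0_oracle), tolerance = 1e-8)
})

test_that("adaptive prespecification returns the unadjusted spec for an empty candidate set", {
  summ <- make_summaries()
  spec <- adaptive_prespecification(summ, candidates = character(0))
  expect_null(spec$or_covariate)
  expect_null(spec$ps_covariate)
})

test_that("adaptive prespecification finds the strongly predictive covariate", {
  hits <- 0
  for (r in 1:40) {
    set.seed(700 + r)
    e1 <- runif(30, 0.1, 0.9)
    e2 <- runif(30)
    a <- sample(rep(c(0, 1), 15))
    y <- pmin(pmax(0.9 * e1 + rnorm(30, 0, 0.01), 0), 1)
    summ <- structure(
      tibble::tibble(cluster_id = 1:30, pair_id = NA_integer_, a = a,
                     e1c = e1, e2c = e2, y_c_hat = y),
      class = c("cluster_summaries", class(tibble::tibble()))
    )
    spec <- adaptive_prespecification(summ, candidates = c("e1c", "e2c"))
    if (identical(spec$or_covariate, "e1c")) hits <- hits + 1
  }
  expect_gte(hits, 38) # >= 95% of replicates
})

test_that("the selected spec never has higher CV variance than the unadjusted one", {
  set.seed(71)
  for (r in 1:10) {
    summ <- make_summaries(y = runif(10), a = rep(c(1, 0), 5),
                           e1c = rnorm(10), pair_id = rep(1:5, each = 2))
    for (m in c(TRUE, FALSE)) {
      spec <- adaptive_prespecification(summ, candidates = c("e1c", "e2c"),
                                        matched = m)
      base_ic <- crtmle:::cv_ic(summ, adjustment_spec(), "rd", 0.5,
                                matched = m)
      base_var <- if (m) {
        var(as.vector(tapply(base_ic, summ$pair_id, mean)))
      } else {
        var(base_ic)
      }
      expect_lte(attr(spec, "cv_variance"), base_var + 1e-12)
    }
  }
})

test_that("exhaustive search never does worse than the sequential search on the CV criterion", {
  set.seed(91)
  summ <- make_summaries(y = runif(12), a = rep(c(1, 0), 6),
                         e1c = rnorm(12), pair_id = rep(1:6, each = 2))
  seq_spec <- adaptive_prespecification(summ, candidates = c("e1c", "e2c"))
  exh_spec <- adaptive_prespecification(summ, candidates = c("e1c", "e2c"),
                                        search = "exhaustive")
  expect_lte(attr(exh_spec, "cv_variance"),
             attr(seq_spec, "cv_variance") + 1e-12)
})

test_that("influence-curve inference follows the stated variance and df conventions", {
  set.seed(81)
  y <- runif(30)
  summ <- make_summaries(y = y, a = rep(c(1, 0), 15), e1c = rnorm(30),
                         pair_id = rep(1:15, each = 2), matched = FALSE)
  est <- tmle_effect(summ, adjustment_spec(), scale = "rd", matched = FALSE)
  ic <- est$ic1 - est$ic0
  expect_equal(est$se, sqrt(var(ic) / 30), tolerance = 1e-12)
  expect_equal(est$df, 28)

  est_m <- tmle_effect(summ, adjustment_spec(), scale = "rd", matched = TRUE)
  pair_ic <- as.vector(tapply(ic, summ$pair_id, mean))
  expect_equal(est_m$se, sqrt(var(pair_ic) / 15), tolerance = 1e-12)
  expect_equal(est_m$df, 14)

  # widening the confidence level widens the interval
  est99 <- tmle_effect(summ, adjustment_spec(), scale = "rd",
                       matched = FALSE, conf_level = 0.99)
  expect_lt(est99$ci_lo, est$ci_lo)
  expect_gt(est99$ci_hi, est$ci_hi)
})

test_that("unadjusted IC-based variance matches two-sample variance algebra", {
  y <- c(0.21, 0.35, 0.44, 0.52, 0.30, 0.66, 0.48, 0.59, 0.28, 0.71)
  summ <- make_summaries(y = y, a = rep(c(1, 0), 5), e1c = rnorm(10),
                         pair_id = rep(1:5, each = 2))
  est <- tmle_effect(summ, adjustment_spec(), scale = "rd", matched = FALSE)
  tt <- t.test(y[summ$a == 1], y[summ$a == 0], var.equal = TRUE)
  n <- 10
  # IC variance uses N in the denominator; the pooled t uses N - 2
  expect_equal(est$se^2 * (n - 1), tt$stderr^2 * (n - 2), tolerance = 1e-10)
})

test_that("risk-ratio inference is on the log scale and symmetric under the null", {
  y <- c(0.3, 0.5, 0.7, 0.3, 0.5, 0.7)
  summ <- make_summaries(y = y, a = c(1, 1, 1, 0, 0, 0),
                         e1c = c(0, 1, 0, 0, 1, 0))
  est <- tmle_effect(summ, adjustment_spec(), scale = "rr", matched = FALSE)
  expect_equal(est$estimate, 1)
  expect_equal(est$ci_lo * est$ci_hi, 1, tolerance = 1e-10)
  expect_equal(est$p_value, 1, tolerance = 1e-10)
})

test_that("degenerate stage-2 inputs error clearly", {
  summ <- make_summaries(a = rep(1, 6))
  expect_error(tmle_effect(summ, adjustment_spec()), "both treatment arms")
  expect_error(
    tmle_effect(make_summaries(), adjustment_spec("nope", NULL)),
    "unknown outcome-regression covariate"
  )
  tiny <- make_summaries()[1:3, ]
  expect_warning(adaptive_prespecification(tiny, candidates = "e1c"),
                 "too few clusters")
})
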