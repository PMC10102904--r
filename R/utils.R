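# Internal numerical helpers shared across modules.

# Bounds used to keep logits finite for predicted probabilities.
.pred_bounds <- c(1e-4, 1 - 1e-4)

bound <- function(p, lo = .pred_bounds[1], hi = .pred_bounds[2]) {
  pmin(pmax(p, lo), hi)
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

#' @keywords internal
#' @noRd
fast_logit_fit <- function(x, y, weights = NULL, offset = NULL) {
  # Logistic (quasi-binomial) IRLS on a small design matrix; y may be
  # fractional. Hand-rolled rather than glm.fit because these fits sit in
  # tight per-cluster and leave-one-out loops. Tight deviance tolerance so
  # downstream score-equation invariants are solved to ~1e-12.
  n <- length(y)
  x <- as.matrix(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(offset)) offset <- rep(0, n)
  p_dim <- ncol(x)
  beta <- numeric(p_dim)
  eta <- offset
  dev_fun <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * sum(weights * (y * log(p) + (1 - y) * log(1 - p)))
  }
  p <- expit(eta)
  dev <- dev_fun(p)
  converged <- FALSE
  for (it in seq_len(100)) {
    mu_var <- pmax(p * (1 - p), 1e-10)
    wirls <- weights * mu_var
    z <- (eta - offset) + (y - p) / mu_var
    xw <- x * wirls
    beta_new <- tryCatch(
      drop(solve(crossprod(x, xw), crossprod(xw, z))),
      error = function(e) {
        # rank-deficient design: pivoted QR with aliased columns zeroed
        sw <- sqrt(wirls)
        b <- qr.coef(qr(x * sw), z * sw)
        b[is.na(b)] <- 0
        b
      }
    )
    # step-halving safeguard against deviance increase
    for (k in 0:20) {
      b_try <- beta + (beta_new - beta) / 2^k
      eta_try <- offset + drop(x %*% b_try)
      eta_try <- pmin(pmax(eta_try, -30), 30)
      p_try <- expit(eta_try)
      dev_try <- dev_fun(p_try)
      if (dev_try <= dev + 1e-12 || k == 20) break
    }
    delta <- abs(dev_try - dev)
    beta <- b_try; eta <- eta_try; p <- p_try; dev <- dev_try
    if (delta < 1e-12 * (abs(dev) + 0.1)) { converged <- TRUE; break }
  }
  # linear predictors pinned at the cap indicate (quasi-)separation
  converged <- converged && all(abs(eta) < 30 - 1e-8)
  list(coefficients = beta, converged = converged)
}

# Solve the one-dimensional logistic fluctuation score equation
#   f(eps) = sum(w * h * (y - expit(offset + eps * h))) = 0
# by safeguarded Newton iteration. f is strictly decreasing in eps, so the
# root is unique when it exists; eps is capped at +/-`cap` when the score
# cannot be zeroed within bounds (near-degenerate weighted outcomes).
solve_fluctuation <- function(y, offset, h = 1, w = 1, cap = 40,
                              tol = 1e-13) {
  h <- rep_len(h, length(y))
  w <- rep_len(w, length(y))
  score <- function(eps) sum(w * h * (y - expit(offset + eps * h)))
  dscore <- function(eps) {
    p <- expit(offset + eps * h)
    -sum(w * h^2 * p * (1 - p))
  }
  eps <- 0
  f <- score(eps)
  for (i in seq_len(200)) {
    if (abs(f) < tol) break
    d <- dscore(eps)
    if (d == 0) break
    step <- f / d
    eps_new <- eps - step
    # step-halving safeguard
    for (k in seq_len(30)) {
      if (abs(eps_new) <= cap && abs(score(eps_new)) < abs(f)) break
      eps_new <- (eps + eps_new) / 2
    }
    if (eps_new == eps) break
    eps <- eps_new
    f <- score(eps)
  }
  if (eps > cap) eps <- cap
  if (eps < -cap) eps <- -cap
  eps
}

logit_predict <- function(coefs, x, offset = NULL) {
  eta <- drop(x %*% coefs)
  if (!is.null(coefs) && anyNA(eta)) eta[is.na(eta)] <- 0
  if (!is.null(offset)) eta <- eta + offset
  expit(eta)
}

# Derive independent per-replicate seeds from one master seed without
# consuming the caller's RNG stream. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
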