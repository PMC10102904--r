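#' Configure the trial-simulation data-generating process
#'
#' Defines the structural equations used to simulate a cluster randomized
#' trial with differential outcome measurement. Three latent cluster-level
#' variables drive within-cluster dependence: `U1c, U2c ~ Unif(-1, 1)` set the
#' cluster-specific means of the individual baseline covariates
#' `W1 ~ Norm(U1c, 0.5)` and `W2 ~ Norm(U2c, 0.5)` (sd 0.5), and
#' `U3c ~ Norm(0, 1)` is a shared outcome/mediator shift that also drives
#' pair-matching. Observed cluster-level covariates `E1c, E2c` are the
#' within-cluster empirical means of `W1, W2`.
#'
#' Given a cluster-level treatment `a`, each individual's post-baseline
#' mediator, outcome, and measurement indicator are threshold indicators of
#' independent uniforms:
#' \deqn{M = 1\{U_M < \mathrm{expit}(-1 + 2a + W1 + W2 + 0.2(1-a)(E1c+E2c) + 0.25 U3c)\}}
#' \deqn{Y = 1\{U_Y < \mathrm{expit}(1 - 2.5a + 4M + 0.5 W1 + 0.5 W2 + 0.2 E1c + 0.2 E2c + 0.25 U3c)\}}
#' \deqn{\Delta = 1\{U_\Delta < a\,\mathrm{expit}(3 - 3M - 0.5 W1 - 0.5 W2) + (1-a)\,\mathrm{expit}(-2 + 3M + 0.5 W1 + 0.5 W2)\}}
#' so measurement is strongly differential by arm (about 70% of outcomes
#' measured under treatment and 43% under control) and depends on the
#' post-baseline mediator `M`, which also mediates the treatment effect.
#' The outcome `Y` is only recorded when `Delta = 1`.
#'
#' Counterfactual mediators, outcomes, and measurement indicators under both
#' arms are generated from the *same* uniforms, so individual-level
#' counterfactuals are exact and deterministic given the latent draws.
#'
#' @param n_clusters Number of clusters per trial (default 30; must be even
#'   when pair-matched randomization is used).
#' @param cluster_sizes Integer vector of possible cluster sizes, sampled
#'   with equal probability per cluster (default `c(100, 150, 200)`).
#' @param null_effect If `TRUE`, all treatment terms are removed from the
#'   mediator and outcome equations so the true effect is exactly null
#'   (risk difference 0, risk ratio 1) while measurement remains
#'   differential by arm.
#' @param m_coefs,y_coefs,delta1_coefs,delta0_coefs Optional named numeric
#'   overrides for the structural-equation coefficients (see Details for the
#'   defaults and names).
#' @return A list of class `dgp_config`.
#' @export
#' @examples
#' cfg <- dgp_config(n_clusters = 6, cluster_sizes = 50)
#' trial <- simulate_trial(cfg, matched = TRUE, seed = 1)
#' dplyr::count(trial, cluster_id, a)
dgp_config <- function(n_clusters = 30,
                       cluster_sizes = c(100, 150, 200),
                       null_effect = FALSE,
                       m_coefs = NULL,
                       y_coefs = NULL,
                       delta1_coefs = NULL,
                       delta0_coefs = NULL) {
  stopifnot(n_clusters >= 1, all(cluster_sizes >= 1))
  defaults <- list(
    m_coefs = c(intercept = -1, a = 2, w1 = 1, w2 = 1, e_ctrl = 0.2, u3 = 0.25),
    y_coefs = c(intercept = 1, a = -2.5, m = 4, w1 = 0.5, w2 = 0.5,
                e1 = 0.2, e2 = 0.2, u3 = 0.25),
    delta1_coefs = c(intercept = 3, m = -3, w1 = -0.5, w2 = -0.5),
    delta0_coefs = c(intercept = -2, m = 3, w1 = 0.5, w2 = 0.5)
  )
  merge_coefs <- function(def, user) {
    if (is.null(user)) return(def)
    stopifnot(all(names(user) %in% names(def)))
    def[names(user)] <- user
    def
  }
  cfg <- list(
    n_clusters = as.integer(n_clusters),
    cluster_sizes = as.integer(cluster_sizes),
    null_effect = isTRUE(null_effect),
    m_coefs = merge_coefs(defaults$m_coefs, m_coefs),
    y_coefs = merge_coefs(defaults$y_coefs, y_coefs),
    delta1_coefs = merge_coefs(defaults$delta1_coefs, delta1_coefs),
    delta0_coefs = merge_coefs(defaults$delta0_coefs, delta0_coefs)
  )
  if (cfg$null_effect) {
    # Null construction: zero every treatment term in the M and Y equations.
    # The control-arm-only E-term becomes a common term so both arms share
    # one structural equation; the measurement equations keep their arm
    # dependence (missingness stays differential under the null).
    cfg$m_coefs["a"] <- 0
    cfg$y_coefs["a"] <- 0
  }
  structure(cfg, class = "dgp_config")
}

# Draw a population of clusters with counterfactuals under both arms.
# Returns per-individual and per-cluster tibbles; no treatment assigned yet.
draw_cluster_population <- function(config, n_clusters) {
  sizes <- if (length(config$cluster_sizes) == 1) {
    rep(config$cluster_sizes, n_clusters)
  } else {
    sample(config$cluster_sizes, n_clusters, replace = TRUE)
  }
  n <- sum(sizes)
  cl <- rep.int(seq_len(n_clusters), sizes)

  u1c <- stats::runif(n_clusters, -1, 1)
  u2c <- stats::runif(n_clusters, -1, 1)
  u3c <- stats::rnorm(n_clusters, 0, 1)

  w1 <- stats::rnorm(n, u1c[cl], 0.5)
  w2 <- stats::rnorm(n, u2c[cl], 0.5)
  e1c <- as.vector(tapply(w1, cl, mean))[cl]
  e2c <- as.vector(tapply(w2, cl, mean))[cl]
  u3 <- u3c[cl]

  u_m <- stats::runif(n)
  u_y <- stats::runif(n)
  u_d <- stats::runif(n)

  mc <- config$m_coefs
  yc <- config$y_coefs
  d1 <- config$delta1_coefs
  d0 <- config$delta0_coefs
  e_ctrl_mult <- if (config$null_effect) 1 else NULL # see dgp_config()

  m_prob <- function(a) {
    # Under the default process the 0.2(E1c+E2c) term applies only in the
    # control arm; under the null it is common to both arms.
    ctrl <- if (config$null_effect) 1 else (1 - a)
    expit(mc["intercept"] + mc["a"] * a + mc["w1"] * w1 + mc["w2"] * w2 +
            mc["e_ctrl"] * ctrl * (e1c + e2c) + mc["u3"] * u3)
  }
  y_prob <- function(a, m) {
    expit(yc["intercept"] + yc["a"] * a + yc["m"] * m + yc["w1"] * w1 +
            yc["w2"] * w2 + yc["e1"] * e1c + yc["e2"] * e2c + yc["u3"] * u3)
  }
  d_prob <- function(a, m) {
    a * expit(d1["intercept"] + d1["m"] * m + d1["w1"] * w1 + d1["w2"] * w2) +
      (1 - a) * expit(d0["intercept"] + d0["m"] * m + d0["w1"] * w1 + d0["w2"] * w2)
  }

  m1 <- as.integer(u_m < m_prob(1))
  m0 <- as.integer(u_m < m_prob(0))
  y1 <- as.integer(u_y < y_prob(1, m1))
  y0 <- as.integer(u_y < y_prob(0, m0))
  dl1 <- as.integer(u_d < d_prob(1, m1))
  dl0 <- as.integer(u_d < d_prob(0, m0))

  individuals <- tibble::tibble(
    cluster_id = cl,
    w1 = w1, w2 = w2, e1c = e1c, e2c = e2c,
    .m1 = m1, .m0 = m0, .y1 = y1, .y0 = y0, .delta1 = dl1, .delta0 = dl0
  )
  clusters <- tibble::tibble(
    cluster_id = seq_len(n_clusters),
    size = sizes,
    u1c = u1c, u2c = u2c, u3c = u3c,
    y_c_true1 = as.vector(tapply(y1, cl, mean)),
    y_c_true0 = as.vector(tapply(y0, cl, mean))
  )
  list(individuals = individuals, clusters = clusters)
}

#' Randomize treatment over a drawn cluster population
#'
#' Assigns the cluster-level treatment and realizes the observed data from
#' the pre-drawn counterfactuals. With `matched = TRUE` clusters are ranked
#' on the latent matching variable `U3c`, adjacent clusters are paired, and
#' one member of each pair is assigned treatment with probability 1/2; with
#' `matched = FALSE` a simple balanced 1:1 allocation is used. Either way
#' exactly half the clusters are treated.
#'
#' @param population A list with `individuals` and `clusters` tibbles as
#'   produced internally by [simulate_trial()]; exposed for users building
#'   custom designs on the same counterfactual draws.
#' @param matched Pair-matched randomization on `U3c`?
#' @return A `crt_trial` tibble (see [simulate_trial()]).
#' @export
randomize_trial <- function(population, matched = TRUE) {
  clusters <- population$clusters
  n_cl <- nrow(clusters)
  if (matched && n_cl %% 2 != 0) {
    stop("pair-matched randomization requires an even number of clusters")
  }
  if (matched) {
    ord <- order(clusters$u3c)
    pair_of <- integer(n_cl)
    pair_of[ord] <- rep(seq_len(n_cl / 2), each = 2)
    first_treated <- stats::runif(n_cl / 2) < 0.5
    a <- integer(n_cl)
    for (j in seq_len(n_cl / 2)) {
      members <- ord[c(2 * j - 1, 2 * j)]
      a[members] <- if (first_treated[j]) c(1L, 0L) else c(0L, 1L)
    }
    clusters$pair_id <- pair_of
  } else {
    a <- integer(n_cl)
    a[sample.int(n_cl, n_cl %/% 2)] <- 1L
    clusters$pair_id <- NA_integer_
  }
  clusters$a <- a

  ind <- population$individuals
  ai <- a[ind$cluster_id]
  ind$pair_id <- clusters$pair_id[ind$cluster_id]
  ind$a <- ai
  ind$m <- ifelse(ai == 1, ind$.m1, ind$.m0)
  ind$delta <- ifelse(ai == 1, ind$.delta1, ind$.delta0)
  y_pot <- ifelse(ai == 1, ind$.y1, ind$.y0)
  ind$y <- ifelse(ind$delta == 1, y_pot, NA_integer_)

  out <- dplyr::select(
    ind, "cluster_id", "pair_id", "a", "e1c", "e2c", "w1", "w2",
    "m", "delta", "y", dplyr::starts_with(".")
  )
  new_crt_trial(out, matched = matched, clusters = clusters)
}

#' Simulate one cluster randomized trial
#'
#' Draws `n_clusters` clusters from the configured structural equations
#' (see [dgp_config()]), randomizes the cluster-level treatment, and returns
#' the observed individual-level data together with the counterfactual draws
#' needed to evaluate estimators against the truth.
#'
#' @param config A [dgp_config()] object.
#' @param matched Use pair-matched randomization on the latent `U3c`?
#' @param seed Optional integer seed; when supplied the trial is fully
#'   reproducible.
#' @return A tibble of class `crt_trial`, one row per individual, with
#'   columns `cluster_id`, `pair_id`, `a`, `e1c`, `e2c`, `w1`, `w2`, `m`,
#'   `delta`, `y` (`NA` when unmeasured), and dot-prefixed counterfactual
#'   columns (`.m1`, `.m0`, `.y1`, `.y0`, `.delta1`, `.delta0`). The
#'   per-cluster latent variables and true counterfactual cluster means are
#'   attached as the `clusters` attribute.
#' @export
simulate_trial <- function(config = dgp_config(), matched = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (matched && config$n_clusters %% 2 != 0) {
    stop("pair-matched randomization requires an even number of clusters")
  }
  pop <- draw_cluster_population(config, config$n_clusters)
  randomize_trial(pop, matched = matched)
}

#' Compute the true treatment-specific means from a cluster population
#'
#' Generates a large population of clusters from the configured process and
#' averages the cluster-level counterfactual outcome means under each arm.
#' The population risk difference and risk ratio follow directly. Under the
#' default configuration with a population of 5000 clusters the risk
#' difference is about -0.091 and the risk ratio about 0.88.
#'
#' @param config A [dgp_config()] object.
#' @param n_population Number of clusters in the truth population
#'   (default 5000).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `psi1`, `psi0`, `rd`, and `rr` (`rr` is
#'   `NA` with a warning when `psi0` is zero).
#' @export
#' @examples
#' compute_truth(dgp_config(), n_population = 200, seed = 1)
compute_truth <- function(config = dgp_config(), n_population = 5000,
                          seed = NULL) {
  stopifnot(n_population >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pop <- draw_cluster_population(config, n_population)
  psi1 <- mean(pop$clusters$y_c_true1)
  psi0 <- mean(pop$clusters$y_c_true0)
  rr <- if (psi0 == 0) {
    warning("psi0 is zero; risk ratio undefined")
    NA_real_
  } else psi1 / psi0
  tibble::tibble(psi1 = psi1, psi0 = psi0, rd = psi1 - psi0, rr = rr)
}

#' Coefficient of variation of true cluster-level outcomes by arm
#'
#' Standard CRT dependence diagnostic: the between-cluster standard
#' deviation of the cluster-level outcome divided by its mean, per arm.
#' Reported on both the true counterfactual cluster means and the observed
#' complete-case cluster means, since the two definitions differ under
#' differential measurement.
#'
#' @param trial A `crt_trial` from [simulate_trial()].
#' @return A tibble with one row per arm and columns `cv_true`
#'   (counterfactual cluster means under the assigned arm) and
#'   `cv_observed` (complete-case cluster means).
#' @export
coefficient_of_variation <- function(trial) {
  clusters <- trial_clusters(trial)
  obs <- trial |>
    dplyr::filter(.data$delta == 1) |>
    dplyr::group_by(.data$cluster_id, .data$a) |>
    dplyr::summarise(y_cc = mean(.data$y), .groups = "drop")
  clusters |>
    dplyr::mutate(y_true = ifelse(.data$a == 1, .data$y_c_true1, .data$y_c_true0)) |>
    dplyr::left_join(obs, by = c("cluster_id", "a")) |>
    dplyr::group_by(.data$a) |>
    dplyr::summarise(
      cv_true = stats::sd(.data$y_true) / mean(.data$y_true),
      cv_observed = stats::sd(.data$y_cc) / mean(.data$y_cc),
      .groups = "drop"
    )
}
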