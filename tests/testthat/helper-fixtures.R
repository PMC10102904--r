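# Small deterministic fixtures shared across test files.

# Cluster-summary table with six clusters (three per arm) and optional
# pairing; y values chosen distinct so arm means are easy to follow.
make_summaries <- function(y = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                           a = c(1, 1, 1, 0, 0, 0),
                           e1c = c(0, 1, 0, 1, 0, 1),
                           pair_id = c(1, 2, 3, 1, 2, 3),
                           matched = FALSE) {
  structure(
    tibble::tibble(
      cluster_id = seq_along(y), pair_id = pair_id, a = a,
      e1c = e1c, e2c = rev(e1c), y_c_hat = y
    ),
    matched = matched,
    class = c("cluster_summaries", class(tibble::tibble()))
  )
}

# Individual-level trial with fully measured outcomes, built from explicit
# per-cluster outcome vectors.
make_complete_trial <- function(y_by_cluster, a_by_cluster,
                                pair_by_cluster = NULL) {
  n_cl <- length(y_by_cluster)
  if (is.null(pair_by_cluster)) pair_by_cluster <- rep(NA_integer_, n_cl)
  rows <- lapply(seq_len(n_cl), function(i) {
    y <- y_by_cluster[[i]]
    tibble::tibble(
      cluster_id = i, pair_id = pair_by_cluster[i], a = a_by_cluster[i],
      e1c = mean(y), e2c = 0, w1 = seq_along(y) / length(y), w2 = 0,
      m = 0L, delta = 1L, y = y
    )
  })
  trial <- dplyr::bind_rows(rows)
  attr(trial, "matched") <- !all(is.na(pair_by_cluster))
  class(trial) <- c("crt_trial", class(tibble::tibble()))
  trial
}

# One cluster with a single binary covariate where measurement depends only
# on that covariate; used against the stratified G-computation oracle.
make_stratified_cluster <- function() {
  tibble::tibble(
    w1 = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
    delta = c(1, 1, 1, 0, 0, 0, 1, 1, 1, 1, 0, 0),
    y = c(1, 0, 0, NA, NA, NA, 1, 1, 0, 1, NA, NA)
  )
}

# Hand-computed stratified G-computation: sum_w P(w) * mean(y | measured, w).
gcomp_oracle <- function(cluster, w = "w1") {
  strata <- unique(cluster[[w]])
  p_w <- vapply(strata, function(s) mean(cluster[[w]] == s), numeric(1))
  q_w <- vapply(strata, function(s) {
    sel <- cluster[[w]] == s & cluster$delta == 1
    mean(cluster$y[sel])
  }, numeric(1))
  sum(p_w * q_w)
}
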