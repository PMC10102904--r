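#' @importFrom rlang .data
NULL

new_crt_trial <- function(data, matched = FALSE, clusters = NULL) {
  structure(
    tibble::as_tibble(data),
    matched = isTRUE(matched),
    clusters = clusters,
    class = c("crt_trial", class(tibble::tibble()))
  )
}

#' Per-cluster metadata of a trial
#'
#' Returns the cluster-level table attached to a `crt_trial`: one row per
#' cluster with `cluster_id`, `pair_id`, `a`, and, for simulated trials, the
#' latent variables and true counterfactual cluster means.
#'
#' @param trial A `crt_trial`.
#' @return A tibble with one row per cluster.
#' @export
trial_clusters <- function(trial) {
  cl <- attr(trial, "clusters")
  if (!is.null(cl)) return(tibble::as_tibble(cl))
  trial |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      pair_id = .data$pair_id[1], a = .data$a[1], size = dplyr::n(),
      .groups = "drop"
    )
}

#' Is a trial pair-matched?
#' @param trial A `crt_trial`.
#' @return Logical flag recorded when the trial was read or simulated.
#' @export
is_matched <- function(trial) isTRUE(attr(trial, "matched"))

#' Column schema for individual-level trial files
#'
#' Maps the columns of a delimited individual-level file onto the roles the
#' estimators need. Covariate columns are named explicitly (vectors), so any
#' header naming convention can be accommodated.
#'
#' @param cluster_id,pair_id,a,delta,y Column names for the cluster
#'   identifier, optional pair identifier, treatment indicator, measurement
#'   indicator, and outcome.
#' @param e Character vector of cluster-level baseline covariate columns.
#' @param w Character vector of individual-level baseline covariate columns.
#' @param m Character vector of post-baseline covariate columns.
#' @return A named list of class `trial_schema`.
#' @export
trial_schema <- function(cluster_id = "cluster_id", pair_id = "pair_id",
                         a = "a", e = c("e1c", "e2c"), w = c("w1", "w2"),
                         m = "m", delta = "delta", y = "y") {
  structure(
    list(cluster_id = cluster_id, pair_id = pair_id, a = a,
         e = e, w = w, m = m, delta = delta, y = y),
    class = "trial_schema"
  )
}

#' Read an individual-level trial from a delimited file
#'
#' Reads a comma-delimited file with one row per participant, renames
#' columns to the canonical roles of [trial_schema()], and validates the
#' trial invariants: treatment, pair id, and cluster-level covariates
#' constant within cluster; measurement indicator in \{0, 1\}; outcome
#' present exactly when measured (empty cells encode unmeasured outcomes);
#' and, for matched trials, pairs of exactly two clusters with opposite
#' arms.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema A [trial_schema()] mapping file columns to roles.
#' @param matched Treat the trial as pair-matched? Defaults to `TRUE` when
#'   the pair-id column is present and non-missing.
#' @return A validated `crt_trial` tibble.
#' @export
read_trial <- function(path, schema = trial_schema(), matched = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- c(cluster_id = schema$cluster_id, a = schema$a,
            delta = schema$delta, y = schema$y)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- raw
  for (role in names(cols)) names(out)[names(out) == cols[[role]]] <- role
  if (schema$pair_id %in% names(raw)) {
    names(out)[names(out) == schema$pair_id] <- "pair_id"
  } else {
    out$pair_id <- NA_integer_
  }
  for (v in c(schema$e, schema$w, schema$m)) {
    if (!v %in% names(out)) stop("missing covariate column: ", v)
  }
  if (is.null(matched)) matched <- !all(is.na(out$pair_id))
  trial <- new_crt_trial(out, matched = matched)
  attr(trial, "schema") <- schema
  validate_trial(trial)
}

#' Validate trial invariants
#'
#' Checks the structural invariants of an individual-level trial and errors
#' with the offending cluster or pair named. See [read_trial()] for the
#' invariant list.
#'
#' @param trial A `crt_trial` tibble.
#' @return The trial, invisibly unchanged, if valid.
#' @export
validate_trial <- function(trial) {
  stopifnot(is.data.frame(trial))
  if (nrow(trial) == 0) stop("trial has no individuals")
  schema <- attr(trial, "schema") %||% trial_schema()
  const_cols <- intersect(c("a", "pair_id", schema$e), names(trial))
  for (col in const_cols) {
    n_distinct <- tapply(trial[[col]], trial$cluster_id,
                         function(v) length(unique(v)))
    bad <- names(n_distinct)[n_distinct > 1]
    if (length(bad) > 0) {
      stop(sprintf("column '%s' is not constant within cluster %s",
                   col, bad[1]))
    }
  }
  if (!all(trial$delta %in% c(0, 1))) {
    stop("measurement indicator 'delta' must be 0 or 1")
  }
  if (any(trial$delta == 0 & !is.na(trial$y))) {
    bad <- unique(trial$cluster_id[trial$delta == 0 & !is.na(trial$y)])
    stop("outcome present with delta = 0 in cluster ", bad[1])
  }
  if (any(trial$delta == 1 & is.na(trial$y))) {
    bad <- unique(trial$cluster_id[trial$delta == 1 & is.na(trial$y)])
    stop("outcome missing with delta = 1 in cluster ", bad[1])
  }
  if (!all(trial$a %in% c(0, 1))) stop("treatment 'a' must be 0 or 1")
  cl <- trial |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(a = .data$a[1], pair_id = .data$pair_id[1],
                     .groups = "drop")
  if (length(unique(cl$cluster_id)) != nrow(cl)) stop("cluster ids not unique")
  if (is_matched(trial)) {
    if (any(is.na(cl$pair_id))) stop("matched trial with missing pair ids")
    by_pair <- split(cl$a, cl$pair_id)
    for (p in names(by_pair)) {
      if (length(by_pair[[p]]) != 2) {
        stop("pair ", p, " does not contain exactly two clusters")
      }
      if (sum(by_pair[[p]]) != 1) {
        stop("pair ", p, " does not contain one treated and one control cluster")
      }
    }
  }
  invisible(trial)
}

#' Write an individual-level trial to CSV
#'
#' Inverse of [read_trial()]: unmeasured outcomes are written as empty
#' cells. Counterfactual (dot-prefixed) columns of simulated trials are
#' dropped, since they are never observed.
#'
#' @param trial A `crt_trial`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  out <- dplyr::select(tibble::as_tibble(trial), -dplyr::starts_with("."))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Aggregate a trial to cluster-level summaries
#'
#' Collapses individual-level data to one row per cluster: the cluster-level
#' covariates `E^c`, summary measures `W^c` of the individual baseline
#' covariates (by default within-cluster means, mirroring how the simulated
#' `E^c` are constructed), and the estimated cluster endpoint. Each cluster
#' contributes one row regardless of its size, so downstream effect
#' estimation weights clusters equally.
#'
#' @param trial A `crt_trial`.
#' @param y_c_hat Either a `stage1_fits` tibble from [estimate_endpoints()]
#'   or a numeric vector of cluster endpoints in cluster-id order.
#' @param w_aggregators Named list of functions applied to each individual
#'   baseline covariate within cluster (default `list(mean = mean)`);
#'   summary columns are named `<covariate>_<aggregator>`.
#' @param schema A [trial_schema()] naming the covariate columns.
#' @return A `cluster_summaries` tibble with columns `cluster_id`,
#'   `pair_id`, `a`, the `E^c` columns, the `W^c` summaries, and `y_c_hat`.
#' @export
summarize_clusters <- function(trial, y_c_hat,
                               w_aggregators = list(mean = mean),
                               schema = attr(trial, "schema") %||% trial_schema()) {
  if (nrow(trial) == 0) stop("empty trial")
  e_cols <- intersect(schema$e, names(trial))
  w_cols <- intersect(schema$w, names(trial))
  base <- trial |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      pair_id = .data$pair_id[1], a = .data$a[1],
      dplyr::across(dplyr::all_of(e_cols), ~ .x[1]),
      .groups = "drop"
    )
  for (w in w_cols) {
    for (agg in names(w_aggregators)) {
      f <- w_aggregators[[agg]]
      base[[paste(w, agg, sep = "_")]] <-
        as.vector(tapply(trial[[w]], trial$cluster_id, f))[
          match(base$cluster_id, sort(unique(trial$cluster_id)))]
    }
  }
  if (is.data.frame(y_c_hat)) {
    if (!all(c("cluster_id", "y_c_hat") %in% names(y_c_hat))) {
      stop("y_c_hat data frame must have columns cluster_id and y_c_hat")
    }
    base <- dplyr::left_join(
      base, dplyr::select(y_c_hat, "cluster_id", "y_c_hat"),
      by = "cluster_id"
    )
  } else {
    if (length(y_c_hat) != nrow(base)) {
      stop("y_c_hat must have one value per cluster")
    }
    base$y_c_hat <- y_c_hat
  }
  if (anyNA(base$y_c_hat) || any(!is.finite(base$y_c_hat))) {
    stop("y_c_hat must be finite for every cluster")
  }
  structure(base, class = c("cluster_summaries", class(tibble::tibble())),
            matched = is_matched(trial))
}

#' Write an effect estimate to a JSON results file
#'
#' Serializes a completed [tmle_effect()] (or comparator) result as
#' key-value JSON, including the point estimate, confidence interval,
#' standard error, degrees of freedom, p-value, scale, selected adjustment
#' specification, and the per-unit influence-curve values. Numbers
#' round-trip through [read_results()] at full double precision.
#'
#' @param estimate A `crt_effect` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimate, path) {
  required <- c("estimate", "se", "ci_lo", "ci_hi", "df", "p_value", "scale")
  missing_fields <- required[!vapply(required, function(f)
    !is.null(estimate[[f]]) && !anyNA(estimate[[f]]), logical(1))]
  if (length(missing_fields) > 0) {
    stop("incomplete estimate; missing ", paste(missing_fields, collapse = ", "))
  }
  payload <- list(
    estimator = estimate$estimator %||% "tmle2stage",
    scale = estimate$scale,
    matched = isTRUE(estimate$matched),
    psi1 = estimate$psi1, psi0 = estimate$psi0,
    estimate = estimate$estimate, se = estimate$se,
    ci_lo = estimate$ci_lo, ci_hi = estimate$ci_hi,
    df = estimate$df, p_value = estimate$p_value,
    selection = list(
      or_covariate = estimate$selection$or_covariate %||% NA,
      ps_covariate = estimate$selection$ps_covariate %||% NA
    ),
    ic = estimate$ic
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#' @param path Path to the JSON file.
#' @return A list with the stored fields.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
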