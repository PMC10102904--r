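#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.crt_effect <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator,
    scale = x$scale,
    matched = x$matched,
    estimate = x$estimate,
    std.error = x$se,
    df = x$df,
    p.value = x$p_value,
    conf.low = x$ci_lo,
    conf.high = x$ci_hi
  )
}

#' @exportS3Method generics::glance
glance.crt_effect <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator,
    psi1 = x$psi1 %||% NA_real_,
    psi0 = x$psi0 %||% NA_real_,
    n_units = x$df + ifelse(isTRUE(x$matched), 1L, 2L),
    or_covariate = x$selection$or_covariate %||% NA_character_,
    ps_covariate = x$selection$ps_covariate %||% NA_character_
  )
}

#' @export
print.crt_effect <- function(x, ...) {
  scale_lab <- c(rd = "risk difference", rr = "risk ratio")[x$scale]
  cat(sprintf("%s (%s, %s)\n", x$estimator, scale_lab,
              if (x$matched) "keeping the matches" else "breaking the matches"))
  if (!is.null(x$psi1)) {
    cat(sprintf("  psi(1) = %.4f, psi(0) = %.4f\n", x$psi1, x$psi0))
  }
  cat(sprintf("  estimate = %.4f  (%d%% CI %.4f to %.4f)\n",
              x$estimate, round(100 * (x$conf_level %||% 0.95)),
              x$ci_lo, x$ci_hi))
  cat(sprintf("  se = %.4f%s, df = %d, p = %.4g\n", x$se,
              if (x$scale == "rr") " (log scale)" else "", x$df, x$p_value))
  if (!is.null(x$selection)) {
    cat(sprintf("  adjustment: OR ~ %s, PS ~ %s\n",
                x$selection$or_covariate %||% "(none)",
                x$selection$ps_covariate %||% "(none)"))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.crt_benchmark <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.crt_benchmark <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps, seed = x$seed,
    true_rd = x$truth$rd, true_rr = x$truth$rr,
    estimators = paste(x$estimators, collapse = ",")
  )
}

#' @export
print.crt_benchmark <- function(x, ...) {
  cat(sprintf("CRT estimator benchmark: %d replicates, true RD = %.4f, true RR = %.4f\n",
              x$n_reps, x$truth$rd, x$truth$rr))
  print(as.data.frame(dplyr::select(
    x$metrics, "estimator", "scale", "matched", "pt", "bias",
    "sd_est", "mean_se", "coverage", "power"
  )), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot benchmark metrics
#'
#' Dot plot of bias, 95% CI coverage, and power per estimator, scale, and
#' analysis (keeping vs breaking the matches), with reference lines at zero
#' bias and nominal coverage.
#'
#' @param object A `crt_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.crt_benchmark <- function(object, ...) {
  long <- object$metrics |>
    dplyr::mutate(
      analysis = ifelse(.data$matched, "keeping matches", "breaking matches"),
      label = paste(.data$estimator, toupper(.data$scale))
    ) |>
    tidyr::pivot_longer(c("bias", "coverage", "power"),
                        names_to = "metric", values_to = "value")
  ref <- tibble::tibble(metric = c("bias", "coverage"), yint = c(0, 95))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     shape = .data$analysis)) +
    ggplot2::geom_point(size = 2,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$yint),
                        linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot cluster endpoints by arm
#'
#' Dot plot of the estimated cluster-level endpoints by treatment arm;
#' matched pairs are connected when pair ids are available.
#'
#' @param object A `cluster_summaries` tibble from [summarize_clusters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_summaries <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       arm = factor(ifelse(.data$a == 1, "intervention",
                                           "control"),
                                    levels = c("control", "intervention")))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$arm, y = .data$y_c_hat))
  if (!all(is.na(dat$pair_id))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$pair_id),
                                colour = "grey70")
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = "estimated cluster endpoint") +
    ggplot2::theme_bw()
}
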