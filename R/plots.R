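#' Plot a beta-weight trajectory
#'
#' Beta weight against volume, one line per component, faceted by trial
#' type: the raw material of the convergence analysis.
#'
#' @param object A `beta_trajectory`.
#' @param trial_types Types to show.
#' @param max_components Cap on the number of components drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_trajectory <- function(object,
                                     trial_types = feature_trial_types(),
                                     max_components = 6L, ...) {
  d <- tidy(object)
  comps <- utils::head(unique(d$component), max_components)
  d <- d[d$trial_type %in% trial_types & d$component %in% comps, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$volume, .data$beta,
                                  colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~trial_type, scales = "free_y") +
    ggplot2::labs(x = "volume", y = expression(beta[t]),
                  title = object$subject_id) +
    ggplot2::theme_minimal()
}

#' Plot a SoAD series with its fitted exponential decay
#'
#' @param series Tibble from [soad()].
#' @param fit Optional `decay_fit` for the overlaid decay curve.
#' @param log_y Show the log-linear view instead of the raw series.
#' @return A ggplot.
#' @export
plot_soad <- function(series, fit = NULL, log_y = FALSE) {
  p <- ggplot2::ggplot(series, ggplot2::aes(.data$volume, .data$soad)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "volume", y = "SoAD") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && fit$valid) {
    curve_d <- tibble::tibble(
      volume = series$volume,
      soad = fit$n0 * exp(-fit$lambda * series$volume)
    )
    p <- p + ggplot2::geom_line(data = curve_d, colour = "red")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Box plots of stopping-time distributions
#'
#' Stopping volume by half-life count, optionally split by group and trial
#' type, with a reference line at the full acquisition length.
#'
#' @param osts Tibble from [ost_table()].
#' @param manifest Optional cohort manifest (adds group facets).
#' @param T Full acquisition length for the reference line.
#' @return A ggplot.
#' @export
plot_ost_distribution <- function(osts, manifest = NULL, T = NULL) {
  d <- osts
  if (!is.null(manifest)) {
    d <- dplyr::left_join(d, manifest[, c("subject_id", "group")],
                          by = "subject_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(factor(.data$k), .data$stop_volume)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "half-lives (k)", y = "stopping volume") +
    ggplot2::theme_minimal()
  if (!is.null(manifest)) {
    p <- p + ggplot2::aes(fill = .data$group) +
      ggplot2::facet_wrap(~trial_type)
  }
  if (!is.null(T)) {
    p <- p + ggplot2::geom_hline(yintercept = T, linetype = "dashed")
  }
  p
}

#' Plot per-subject classification scores
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$label, .data$score)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "group", y = "fraction of classifiers correct",
                  title = object$condition) +
    ggplot2::theme_minimal()
}
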