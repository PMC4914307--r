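#' Kaplan-Meier plot of a survival comparison
#'
#' Step curves of the product-limit survival estimate per risk group, with
#' the log-rank p-value in the subtitle.
#'
#' @param object A `survival_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survival_comparison
#' @export
autoplot.survival_comparison <- function(object, ...) {
  curves <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1, n_risk = max(.x$n_risk),
                     n_event = 0L), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$surv,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Overall survival (months)", y = "Survival probability",
                  color = "Risk group",
                  subtitle = sprintf("log-rank p = %.3g", object$logrank$p)) +
    ggplot2::theme_minimal()
}

#' ROC plot of a time-dependent ROC analysis
#' @param object A `td_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot td_roc
#' @export
autoplot.td_roc <- function(object, ...) {
  pts <- object$points[order(1 - object$points$specificity,
                             object$points$sensitivity), ]
  ggplot2::ggplot(pts, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("AUC = %.3f at %g months",
                                     object$auc, object$eval_time)) +
    ggplot2::theme_minimal()
}

#' Degree distribution of a ceRNA network on log-log axes
#' @param net A `cerna_network`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net) {
  deg <- node_centralities(net)$degree
  tab <- dplyr::count(tibble::tibble(degree = deg[deg > 0]), .data$degree)
  ggplot2::ggplot(tab, ggplot2::aes(.data$degree, .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Number of nodes") +
    ggplot2::theme_minimal()
}

#' Null-distribution plot of a randomization test
#'
#' Histogram of the null metric values with the observed value marked.
#'
#' @param result One row (or the full tibble) from [randomization_test()].
#' @return A ggplot object (faceted when several metrics are present).
#' @export
plot_randomization <- function(result) {
  long <- result |>
    dplyr::select("metric", "observed", "null_values") |>
    tidyr::unnest("null_values")
  ggplot2::ggplot(long, ggplot2::aes(.data$null_values)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                        color = "red") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Null metric value", y = "Random networks") +
    ggplot2::theme_minimal()
}
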