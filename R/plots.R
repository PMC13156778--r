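#' Plot a fused importance report
#'
#' Bar chart of fused importance scores with the three component scores
#' overlaid as points.
#'
#' @param object An `importance_report` from [feature_importance()] or
#'   [fuse_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot importance_report
autoplot.importance_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("feature", "pi_norm", "pdr_norm", "sv_norm")],
    -"feature", names_to = "metric", values_to = "score")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$feature, .data$fused),
                               y = .data$fused)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(y = .data$score, colour = .data$metric)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "importance (fused, min-max normalized)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot partial-dependence curves
#'
#' @param curves Long tibble from [partial_dependence()].
#' @return A ggplot object, one facet per feature.
#' @export
plot_partial_dependence <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$value, .data$pd)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = "feature value (scaled)",
                  y = "partial dependence (yield %)") +
    ggplot2::theme_minimal()
}

#' Plot outer-fold cross-validation metrics
#'
#' @param object An `svr_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot svr_cv
autoplot.svr_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$outer[c("fold", "r.squared", "rmse")],
                              -"fold", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$fold), .data$value)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "outer fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Parity plot for predictions
#'
#' Observed versus predicted yields with the 1:1 reference line.
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @param label Optional series label.
#' @return A ggplot object.
#' @export
plot_parity <- function(y, y_hat, label = NULL) {
  d <- tibble::tibble(observed = y, predicted = y_hat)
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed yield (%)", y = "predicted yield (%)") +
    ggplot2::theme_minimal()
  if (!is.null(label)) gg <- gg + ggplot2::ggtitle(label)
  gg
}
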