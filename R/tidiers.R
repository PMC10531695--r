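#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a fitted GS model
#'
#' One row per marker effect for models that define them, otherwise one
#' row per genotype GEBV.
#'
#' @param x A `gs_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate` (plus `sign_prob` for the
#'   Bayesian ridge).
#' @export
tidy.gs_fit <- function(x, ...) {
  if (!is.null(x$marker_effects)) {
    out <- tibble::tibble(
      term = names(x$marker_effects) %||%
        marker_ids(length(x$marker_effects)),
      estimate = unname(x$marker_effects)
    )
    if (!is.null(x$training_meta$sign_prob))
      out$sign_prob <- unname(x$training_meta$sign_prob)
    out
  } else {
    tibble::tibble(
      term = names(x$gebv) %||% genotype_ids(length(x$gebv)),
      estimate = unname(x$gebv)
    )
  }
}

#' One-row summary of a fitted GS model
#'
#' @param x A `gs_fit`.
#' @param ... Unused.
#' @return A tibble with the model name, training size, intercept,
#'   regularization scalar(s) and variance components where available.
#' @export
glance.gs_fit <- function(x, ...) {
  vc <- x$vc
  tibble::tibble(
    model = x$model,
    n = length(x$gebv),
    intercept = x$intercept,
    lambda = x$regularization$lambda %||% NA_real_,
    sigma2_a = if (!is.null(vc)) vc$sigma2_a else NA_real_,
    sigma2_e = if (!is.null(vc)) vc$sigma2_e else NA_real_,
    h2 = if (!is.null(vc)) vc$h2 else NA_real_,
    train_mse = mean(x$residuals^2)
  )
}

#' Plot an evaluation report
#'
#' Test-phase accuracy per model and N level, the headline comparison of
#' the nine GS predictors.
#'
#' @param object An `evaluation_report`.
#' @param metric Column to plot (default `accuracy_test`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, metric = "accuracy_test",
                                       ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$model, .data[[metric]]),
    y = .data[[metric]], fill = .data$n_level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric, fill = "N level",
                  title = "GS model comparison") +
    ggplot2::theme_minimal()
}

#' Plot a bias-variance decomposition
#'
#' Bias^2, variance, expected loss and the irreducible error floor against
#' model complexity (for KNN: the neighbour count).
#'
#' @param object A `bias_variance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bias_variance <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as.data.frame(object)[, c("complexity", "bias2", "variance",
                              "expected_loss", "irreducible_error")],
    -"complexity", names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$complexity, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "complexity (k neighbours)", y = "trait units²",
                  title = "Bias-variance tradeoff") +
    ggplot2::theme_minimal()
}

#' Plot an adaptive-SE comparison matrix
#'
#' Figure-style tile heatmap of the normalized pairwise adaptive standard
#' errors of prediction.
#'
#' @param object A `comparison_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(object$normalized))
  names(df) <- c("model_a", "model_b", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$model_a, .data$model_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#d81b60", mid = "#f5f5f5",
                                  high = "#546e7a", midpoint = 0,
                                  limits = object$bounds) +
    ggplot2::labs(x = NULL, y = NULL, fill = "adaptive SE",
                  title = "Pairwise adaptive SE of prediction") +
    ggplot2::theme_minimal()
}

#' Plot a selection-gain report
#'
#' Top genotypes per N level by GEBV with their relative-efficiency
#' percentages; overlapping genotypes are highlighted.
#'
#' @param object A `gain_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gain_report <- function(object, ...) {
  df <- object$top
  df$duplicated <- df$genotype_id %in% object$overlap
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$genotype_id, .data$gebv),
    y = .data$gebv, fill = .data$duplicated)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~n_level, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32",
                                          `FALSE` = "#9e9e9e")) +
    ggplot2::labs(x = NULL, y = "GEBV", fill = "both N levels",
                  title = sprintf("Top %d genotypes (%s model)",
                                  object$k, object$model)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
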