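#' Plot methods
#'
#' `autoplot()` methods for the package's result types: ROC curves
#' ([roc_auc()], [repeated_cv()]), learning curves ([learning_curve()]),
#' feature-usage boxplots ([feature_usage_summary()]), and the
#' abundance-missingness diagnostic ([missingness_profile()]).
#'
#' @param object A result object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name adaptms-plots
NULL

#' @rdname adaptms-plots
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname adaptms-plots
#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_report <- function(object, ...) {
  subtitle <- if (all(is.na(object$auc_ci))) NULL else
    sprintf("95%% CI over repeats: [%.3f, %.3f]", object$auc_ci[1], object$auc_ci[2])
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s: mean AUC = %.3f", object$method, object$auc),
      subtitle = subtitle
    ) +
    ggplot2::theme_minimal()
}

#' @rdname adaptms-plots
#' @exportS3Method ggplot2::autoplot
autoplot.learning_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_train, y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Training samples", y = "Validation AUC",
                  title = "Learning curve") +
    ggplot2::theme_minimal()
}

#' @rdname adaptms-plots
#' @exportS3Method ggplot2::autoplot
autoplot.feature_usage <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$correct, y = .data$n_features_used)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = "Correctly classified", y = "Features used per sample",
                  title = "Feature usage vs classification correctness") +
    ggplot2::theme_minimal()
}

#' @rdname adaptms-plots
#' @exportS3Method ggplot2::autoplot
autoplot.missingness_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mean_observed, y = .data$missing_fraction)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "Mean observed log10 abundance", y = "Missing fraction",
                  title = "Abundance-dependent missingness") +
    ggplot2::theme_minimal()
}
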