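# ggplot2 methods for the package's result types.

#' @export
#' @method autoplot ipd_roc
autoplot.ipd_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate (IP flagged as GP)",
                  y = "True-positive rate (GP flagged as GP)",
                  title = sprintf("Identification ROC: %d rounds, eps = %g (AUC %.3f)",
                                  object$rounds, object$epsilon, object$auc))
}

#' @export
#' @method autoplot ipd_curve
autoplot.ipd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f, y = .data$difference)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "Invader population fraction f",
                  y = "Mean score difference (invader - resident)")
}

#' @export
#' @method autoplot ipd_noise_sweep
autoplot.ipd_noise_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epsilon, y = .data$odds_ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Noise level", y = "Fixation odds ratio (1 = neutral)")
}

#' @export
#' @method autoplot ipd_self_score
autoplot.ipd_self_score <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epsilon, y = .data$self_score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Noise level", y = "Stationary self-score")
}
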