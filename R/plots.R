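#' Plot a screen grid
#'
#' Scatter of log2 fold-change (`diff_mean`) against the signed
#' detection-fraction separation (`beta`), one panel per comparison, with
#' primary passers highlighted.
#'
#' @param object A [screen_grid()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_grid <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$beta, y = .data$diff_mean,
                               colour = .data$passes_primary)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = log2(3), linetype = "dotted") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "beta (signed detection-fraction difference)",
                  y = "diff_mean (log2 fold-change)",
                  colour = "passes screen") +
    ggplot2::theme_minimal()
}

#' Plot a challenge result
#'
#' Group mean log10 drug/vehicle ratios with their confidence intervals, per
#' behavioural parameter; the zero line marks parameter identity between
#' conditions.
#'
#' @param object A [challenge_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.challenge_result <- function(object, ...) {
  ggplot2::ggplot(object$tests,
                  ggplot2::aes(x = .data$parameter, y = .data$mean_log_ratio,
                               ymin = .data$ci_lo, ymax = .data$ci_hi,
                               colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(y = sprintf("log10 %s / %s", object$drug, object$vehicle),
                  x = NULL, colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot a classified session as an outcome raster
#'
#' @param trials Output of [classify_trials()].
#' @return A ggplot with trial index against outcome.
#' @export
plot_session_outcomes <- function(trials) {
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial, y = .data$outcome,
                                       colour = .data$outcome)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal()
}
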