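#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_col
#'   geom_point labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object a `vs_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vs_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "#2c7fb8") +
    labs(x = "1 - specificity (FPR)", y = "sensitivity (TPR)",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' Plot the enrichment-factor profile of a metrics report
#'
#' @param object a `vs_metrics`.
#' @param ... unused.
#' @return a ggplot of EF against the screened top fraction.
#' @export
autoplot.vs_metrics <- function(object, ...) {
  ggplot(object$ef, aes(x = factor(sprintf("%g%%", 100 * .data$fraction),
                                   levels = sprintf("%g%%",
                                                    100 * .data$fraction)),
                        y = .data$ef)) +
    geom_col(fill = "#2c7fb8") +
    labs(x = "top fraction screened", y = "enrichment factor",
         title = sprintf("Enrichment (AUC %.2f, BEDROC %.2f)",
                         object$auc, object$bedroc)) +
    theme_minimal()
}

#' Plot score distributions of a similarity score table
#'
#' @param object a `vs_score_table` from [similarity_search()].
#' @param ... unused.
#' @return a ggplot, one panel per fingerprint measure.
#' @export
autoplot.vs_score_table <- function(object, ...) {
  ggplot(object, aes(x = .data$sim)) +
    ggplot2::geom_histogram(bins = 40, fill = "#2c7fb8") +
    facet_wrap(~measure) +
    labs(x = "Tanimoto similarity", y = "count") +
    theme_minimal()
}
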