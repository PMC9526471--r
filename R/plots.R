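# ggplot2 views of the main result types.

#' Volcano plot of a dual-context DE table
#'
#' @param object an `mtc_de` tibble from [de_table()].
#' @param p_cut,fc_cut thresholds drawn as guides (defaults 1e-6 and 6).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mtc_de <- function(object, p_cut = 1e-6, fc_cut = 6, ...) {
  df <- dplyr::mutate(object,
                      neglog_p = -log10(pmax(.data$adj_p, 1e-300)),
                      hit = .data$adj_p < p_cut & .data$log2fc > fc_cut)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neglog_p,
                                   colour = .data$hit)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~context) +
    ggplot2::geom_vline(xintercept = fc_cut, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change (MTC / non-MTC)",
                  y = "-log10 adjusted p")
}

#' Strip plot of classifier scores
#'
#' @param object an `mtc_scores` tibble from [predict.mtc_classifier()].
#' @param labels optional reference labels to colour by.
#' @param threshold decision threshold line (default 0).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mtc_scores <- function(object, labels = NULL, threshold = 0, ...) {
  df <- dplyr::mutate(object,
                      group = if (is.null(labels)) .data$call else labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "logit score", colour = NULL)
}

#' Per-setting cross-validation performance
#'
#' @param object an `mtc_cv` tibble from [repeated_cv()].
#' @param ... unused.
#' @return A ggplot of mean sensitivity and specificity per setting.
#' @export
autoplot.mtc_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(summarize_cv(object),
                            c("mean_sens", "mean_spec"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$set_id), .data$value,
                                   shape = .data$family,
                                   colour = .data$metric)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "candidate feature set", y = "mean CV rate",
                  colour = NULL, shape = NULL)
}
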