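# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_line
#'   geom_point geom_errorbar scale_fill_gradient2 labs theme_minimal
#'   sec_axis scale_y_continuous
NULL

#' @export
ggplot2::autoplot

#' Correlation heatmap
#'
#' @param object a `vts_corr` from [correlation_heatmap()].
#' @param method `"pearson"` or `"spearman"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vts_corr
#' @export
autoplot.vts_corr <- function(object, method = c("pearson", "spearman"), ...) {
  method <- match.arg(method)
  m <- object[[method]]
  df <- as.data.frame(as.table(m))
  names(df) <- c("f1", "f2", "r")
  ggplot(df, aes(x = .data$f1, y = .data$f2, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = paste0(method, " r"),
         title = "Pairwise feature correlations") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Forest plot of association odds ratios
#'
#' @param object a `vts_association` from [associate()].
#' @param which `"multi"` (default) or `"single"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vts_association
#' @export
autoplot.vts_association <- function(object, which = c("multi", "single"), ...) {
  which <- match.arg(which)
  df <- object[[which]]
  df$feature <- stats::reorder(df$feature, -df$p_value)
  ggplot(df, aes(x = .data$odds_ratio, y = .data$feature)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$ci_low, xmax = .data$ci_high), width = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    labs(x = "odds ratio per 1 SD (95% CI)", y = NULL,
         title = sprintf("%s-variable mixed-effects associations", which)) +
    theme_minimal()
}

#' AUC and prevalence versus labeling radius
#'
#' Bars show the held-out AUC at each radius; the line shows the
#' positive-class prevalence.
#'
#' @param object a `vts_sensitivity` from [distance_sensitivity()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vts_sensitivity
#' @export
autoplot.vts_sensitivity <- function(object, ...) {
  sc <- max(object$auc, na.rm = TRUE) / max(object$prevalence, 1e-9)
  ggplot(object, aes(x = .data$radius_mm)) +
    geom_col(aes(y = .data$auc), fill = "steelblue", alpha = 0.8) +
    geom_line(aes(y = .data$prevalence * sc), colour = "darkorange",
              linewidth = 1) +
    geom_point(aes(y = .data$prevalence * sc), colour = "darkorange") +
    scale_y_continuous(
      name = "held-out AUC",
      sec.axis = sec_axis(~ . / sc, name = "prevalence")) +
    labs(x = "labeling radius (mm)",
         title = "Discrimination vs spatial precision") +
    theme_minimal()
}

#' CV metric dispersion of an evaluation report
#'
#' @param object a `vts_eval` from [train_eval()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot vts_eval
#' @export
autoplot.vts_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$cv, -c("repeat_id", "threshold"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    labs(x = NULL, y = NULL,
         title = sprintf("%s: CV metric dispersion over %d repeats",
                         object$config$algorithm, nrow(object$cv))) +
    theme_minimal()
}
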