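#' @export
autoplot.soft_threshold <- function(object, ...) {
  ggplot2::ggplot(object$report, ggplot2::aes(x = .data$power, y = .data$fit_r2)) +
    ggplot2::geom_hline(yintercept = object$target_r2, linetype = 2, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$power), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "soft-thresholding power",
                  y = expression("signed scale-free fit" ~ R^2),
                  title = paste0("Scale-free topology fit (", object$cohort, ")")) +
    ggplot2::theme_minimal()
}

#' Module-trait correlation heatmap
#'
#' @param object a [select_candidate_modules()] result.
#' @param ... unused.
#' @return a ggplot object: modules x trait/cohort tiles coloured by r,
#'   starred when passing both selection thresholds.
#' @export
autoplot.candidate_module_report <- function(object, ...) {
  df <- object$tests |>
    mutate(test = paste(.data$trait, .data$cohort, sep = "\n"),
           label = sprintf("%.2f%s", .data$r, ifelse(.data$pass, "*", "")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$module, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = "Module eigengene - trait correlations") +
    ggplot2::theme_minimal()
}

#' Zsummary preservation plot
#'
#' @param preservation a [module_preservation()] tibble.
#' @return a ggplot object: Zsummary against module size with the 2/10
#'   moderate/strong reference lines.
#' @export
plot_preservation <- function(preservation) {
  ggplot2::ggplot(preservation,
                  ggplot2::aes(x = .data$n_genes, y = .data$zsummary,
                               label = .data$module)) +
    ggplot2::geom_hline(yintercept = c(2, 10), linetype = 2,
                        colour = c("darkgreen", "blue")) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$preservation), size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "module size (genes)", y = "Zsummary",
                  colour = "preservation",
                  title = "Module preservation in the test cohort") +
    ggplot2::theme_minimal()
}

#' Precision-recall curve
#'
#' @param scores classification scores.
#' @param y binary labels.
#' @return a ggplot object of the precision-recall curve, annotated with the
#'   average precision from [evaluate_prauc()].
#' @export
plot_pr_curve <- function(scores, y) {
  y <- as_binary(y)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  df <- tibble(
    recall = cumsum(ys) / sum(ys),
    precision = cumsum(ys) / seq_along(ys)
  )
  ap <- evaluate_prauc(scores, y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_hline(yintercept = mean(y), linetype = 2, colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Precision-recall curve (AP = %.3f)", ap),
                  x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}
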