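#' Plot gene counts per phylostratum
#'
#' Bar chart of the per-stratum gene counts colored by age cohort — the
#' tabular counterpart of a timeline figure.
#'
#' @param object An `age_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot age_summary
#' @export
autoplot.age_summary <- function(object, ...) {
  df <- object$by_stratum
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$ps_index),
                                   y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(ancient = "grey95", medium_aged = "grey70",
                 modern = "grey40")) +
    ggplot2::labs(x = "phylostratum (1 = oldest)", y = "genes",
                  fill = "age cohort") +
    ggplot2::theme_minimal()
}

#' Plot the per-branch distribution of transformed dN/dS values
#'
#' Box plots of `log(1 + max dN/dS)` per branch/node with significant
#' genes highlighted and the neutral point `log 2` marked.
#'
#' @param object A `selection_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_summary
#' @export
autoplot.selection_summary <- function(object, ...) {
  df <- object$results
  df <- df[df$complete & !is.na(df$max_dnds), ]
  df$log_dnds <- dnds_transform(df$max_dnds)
  df$significant <- !is.na(df$p_fdr) & df$p_fdr < object$alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_dnds,
                                   y = .data$branch)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 1) +
    ggplot2::geom_vline(xintercept = log(2), linetype = "dotted",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "magenta3")) +
    ggplot2::labs(x = "log(1 + max dN/dS)  [log 2 = neutral]",
                  y = NULL, colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot region-versus-whole-brain test results
#'
#' Per-region t statistics, flagged where the FDR-adjusted P value
#' clears the threshold.
#'
#' @param object A `region_tests` tibble.
#' @param alpha Highlight threshold on `p_fdr` (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot region_tests
#' @export
autoplot.region_tests <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- !is.na(df$p_fdr) & df$p_fdr < alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$t, y = stats::reorder(.data$region, .data$t),
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "t (region vs whole-brain mean)", y = NULL,
                  fill = paste0("p_fdr < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot tissue enrichment results
#'
#' Bonferroni-corrected hypergeometric enrichment per tissue on a
#' `-log10` scale.
#'
#' @param object An `enrichment_results` tibble.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_results
#' @export
autoplot.enrichment_results <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$p_bonferroni < alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$p_bonferroni, 1e-300)),
    y = stats::reorder(.data$tissue, -.data$p_bonferroni),
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(alpha),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey70", `TRUE` = "steelblue")) +
    ggplot2::labs(x = "-log10 Bonferroni P", y = NULL,
                  fill = paste0("P < ", alpha)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
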