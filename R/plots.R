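#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' AMMI biplot
#'
#' Genotype and environment scores on the first two interaction principal
#' component axes (symmetric scaling). Genotypes near the origin interact
#' little with environments and are stable; environment arrows point toward
#' the harvests they discriminate.
#'
#' @param object An [fit_ammi()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ammi_fit <- function(object, ...) {
  sc <- ammi_biplot_scores(object)
  gei <- 100 * object$lambdas^2 / sum(object$lambdas^2)
  env <- dplyr::filter(sc, .data$type == "environment")
  gen <- dplyr::filter(sc, .data$type == "genotype")
  ggplot2::ggplot(gen, ggplot2::aes(x = .data$IPC1, y = .data$IPC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_segment(data = env,
                          ggplot2::aes(x = 0, y = 0, xend = .data$IPC1,
                                       yend = .data$IPC2),
                          colour = "firebrick",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = env, ggplot2::aes(label = .data$label),
                       colour = "firebrick", vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("IPC1 (%.1f%% of GEI)", gei[1]),
                  y = sprintf("IPC2 (%.1f%% of GEI)", gei[2]),
                  title = "AMMI interaction biplot") +
    ggplot2::theme_minimal()
}

#' Yield-versus-stability plot
#'
#' Mean yield against ASV for each genotype; the desirable corner is high
#' yield and low ASV (low YSI).
#'
#' @param object A [stability_ranking()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_yield, y = .data$ASV,
                                       colour = .data$YSI)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(direction = -1) +
    ggplot2::labs(x = "Mean yield across environments", y = "ASV",
                  colour = "YSI",
                  title = "Yield vs. AMMI stability") +
    ggplot2::theme_minimal()
}

#' Trait PCA biplot
#'
#' Genotype scores and trait loadings on the first two principal
#' components of the trait correlation matrix.
#'
#' @param object A `trait_pca` object from [correlation_pca()] or
#'   [tolerance_pca()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trait_pca <- function(object, ...) {
  ve <- 100 * object$var_explained
  load <- tibble::as_tibble(object$loadings, rownames = "trait")
  # arrows scaled to the score cloud for joint display
  rad <- max(abs(as.matrix(object$scores[c("PC1", "PC2")])))
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(data = load,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * rad,
                                       yend = .data$PC2 * rad),
                          colour = "steelblue",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = load,
                       ggplot2::aes(x = .data$PC1 * rad, y = .data$PC2 * rad,
                                    label = .data$trait),
                       colour = "steelblue", vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}

#' Tolerance-classification scatter plot
#'
#' STI against stress-season yield, coloured by the hierarchical tolerance
#' group.
#'
#' @param table A classified index table from [classify_tolerance()].
#' @return A ggplot.
#' @export
plot_tolerance_groups <- function(table) {
  if (!"cluster" %in% names(table)) {
    abort("table carries no cluster column; run classify_tolerance() first")
  }
  ggplot2::ggplot(table, ggplot2::aes(x = .data$Ys, y = .data$STI,
                                      colour = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Stress-season TDW", y = "STI", colour = "Group") +
    ggplot2::theme_minimal()
}
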