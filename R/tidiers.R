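#' Tidy a differential-expression result
#'
#' @param x A `pt_de` tibble from [de_anova()].
#' @param ... Unused.
#' @return Tibble with `feature`, the per-population `log2fc_*` columns,
#'   `lr`, `p` and `q`.
#' @method tidy pt_de
#' @export
tidy.pt_de <- function(x, ...) {
  cols <- c("feature", grep("^log2fc_", names(x), value = TRUE),
            "lr", "df", "p", "q")
  as_tibble(x)[, cols]
}

#' @param alpha FDR threshold used by the significance count.
#' @rdname tidy.pt_de
#' @return `glance`: one row with `n_features`, `n_significant`,
#'   `n_flagged`, `alpha`.
#' @method glance pt_de
#' @export
glance.pt_de <- function(x, alpha = 0.05, ...) {
  tibble(n_features = nrow(x),
         n_significant = sum(x$q < alpha, na.rm = TRUE),
         n_flagged = sum(x$flagged, na.rm = TRUE),
         alpha = alpha)
}

#' Tidy a variance-decomposition result
#'
#' @param x A `pt_decomp` tibble from [pop_variance_decomposition()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy pt_decomp
#' @export
tidy.pt_decomp <- function(x, ...) as_tibble(x)

#' @rdname tidy.pt_decomp
#' @return `glance`: one row with the gene count, mean `r2` (the average
#'   percent variance attributable to population, as a fraction), mean
#'   adjusted `r2` and mean expression share.
#' @method glance pt_decomp
#' @export
glance.pt_decomp <- function(x, ...) {
  tibble(n_genes = nrow(x),
         mean_r2 = mean(x$r2, na.rm = TRUE),
         mean_r2_adj = mean(x$r2_adj, na.rm = TRUE),
         mean_share_expression = mean(x$share_expression, na.rm = TRUE))
}

#' Plot methods for the main result types
#'
#' `autoplot.pt_decomp` mirrors the usual variance-decomposition displays:
#' histograms of the percent variance explained by population, its
#' permutation p-values, and the expression share. `autoplot.pt_de` shows
#' the population-effect likelihood-ratio p-value histogram;
#' `autoplot.pt_pca` a score scatter of two components; `autoplot.qc_report`
#' the per-sample D-statistics with the outlier threshold.
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pt_decomp
#' @export
autoplot.pt_decomp <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("gene", "r2", "p", "share_expression")],
    c("r2", "p", "share_expression"),
    names_to = "panel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "genes")
}

#' @rdname autoplot.pt_decomp
#' @method autoplot pt_de
#' @export
autoplot.pt_de <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey35") +
    ggplot2::labs(x = "ANOVA p-value", y = "features")
}

#' @param components Two component indices to display.
#' @param labels Optional population labels for coloring.
#' @rdname autoplot.pt_decomp
#' @method autoplot pt_pca
#' @export
autoplot.pt_pca <- function(object, components = c(1, 2), labels = NULL, ...) {
  sc <- object$scores[, components, drop = FALSE]
  df <- tibble(x = sc[, 1], y = sc[, 2],
               sample = rownames(sc) %||% as.character(seq_len(nrow(sc))))
  if (!is.null(labels)) {
    df$population <- unname(as_population_map(labels, df$sample))
  }
  ve <- round(100 * object$var_explained[components], 1)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = sprintf("PC%d (%.1f%%)", components[1], ve[1]),
                  y = sprintf("PC%d (%.1f%%)", components[2], ve[2]))
  if (is.null(labels)) {
    gg + ggplot2::geom_point()
  } else {
    gg + ggplot2::geom_point(ggplot2::aes(colour = .data$population))
  }
}

#' @param threshold Outlier threshold drawn as a reference line.
#' @rdname autoplot.pt_decomp
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, threshold = 0.8, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$sample, y = .data$d,
                               fill = .data$outlier)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "D-statistic") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Plot an F_ST clustering tree
#'
#' @param fst Population x population F_ST matrix.
#' @param ... Passed to [fst_tree()].
#' @export
plot_fst_tree <- function(fst, ...) {
  plot(fst_tree(fst, ...), main = "UPGMA tree of pairwise F_ST")
}
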