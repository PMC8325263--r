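#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_tile
#'   geom_boxplot geom_col geom_point facet_grid facet_wrap labs
#'   scale_fill_viridis_c theme_bw vars
#' @export
ggplot2::autoplot

#' LOD profile plot for a one-dimensional scan
#'
#' @param object A `ttc_scan` from [scan1d()].
#' @param threshold Optional LOD threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ttc_scan
#' @export
autoplot.ttc_scan <- function(object, threshold = NULL, ...) {
  if (inherits(threshold, "ttc_perm_threshold")) threshold <- threshold$threshold
  p <- ggplot(tibble::as_tibble(object), aes(x = .data$pos_cM, y = .data$lod)) +
    geom_line(colour = "steelblue4") +
    facet_grid(cols = vars(.data$chrom), scales = "free_x", space = "free_x") +
    labs(x = "position (cM)", y = "LOD",
         title = attr(object, "dataset") %||% NULL) +
    theme_bw()
  if (!is.null(threshold)) {
    p <- p + geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick")
  }
  p
}

#' Interaction LOD heatmap for a two-dimensional scan
#'
#' @param object A `ttc_pairscan` from [pair_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ttc_pairscan
#' @export
autoplot.ttc_pairscan <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$key_i <- paste0(df$chrom_i, ":", df$pos_i)
  df$key_j <- paste0(df$chrom_j, ":", df$pos_j)
  ggplot(df, aes(x = .data$key_i, y = .data$key_j, fill = .data$lod)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "locus i (chrom:cM)", y = "locus j (chrom:cM)", fill = "LOD",
         title = attr(object, "dataset") %||% NULL) +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Accuracy distribution of a cross-validation
#'
#' @param object A `ttc_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot (boxplot of per-fold accuracies).
#' @method autoplot ttc_cv
#' @export
autoplot.ttc_cv <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$trait <- attr(object, "trait") %||% "trait"
  ggplot(df, aes(x = .data$trait, y = .data$accuracy)) +
    geom_boxplot(fill = "grey85") +
    labs(x = NULL, y = "prediction accuracy (Pearson r)") +
    theme_bw()
}

#' Bar plot of mid-parent heterosis by trait
#'
#' @param mph_tbl Output of [mph()] / [mph_from_blues()] with a `trait`
#'   column.
#' @return A ggplot.
#' @export
plot_mph <- function(mph_tbl) {
  stop_if_not("trait" %in% names(mph_tbl), "need a `trait` column")
  ggplot(mph_tbl, aes(x = .data$trait, y = .data$mph_percent)) +
    geom_col(fill = "steelblue4") +
    labs(x = NULL, y = "mid-parent heterosis (%)") +
    theme_bw()
}

#' Accuracy vs marker-number curve
#'
#' @param curve Output of [marker_subset_experiment()].
#' @return A ggplot.
#' @export
plot_subset_curve <- function(curve) {
  ggplot(curve, aes(x = .data$n_markers, y = .data$accuracy)) +
    geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    labs(x = "number of markers", y = "prediction accuracy") +
    theme_bw()
}
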