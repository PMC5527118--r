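#' Manhattan-style plot of a genome scan
#'
#' @param object An `aao_scan` tibble (from [gwas_scan()]).
#' @param suggestive,genomewide Threshold lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aao_scan <- function(object, suggestive = 1e-4,
                              genomewide = 7.2e-8, ...) {
  df <- object[!is.na(object$p_wald), ]
  df$chrom_n <- suppressWarnings(as.numeric(df$chrom))
  df$chrom <- factor(df$chrom, levels = unique(df$chrom[order(df$chrom_n,
                                                              df$chrom)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = -log10(.data$p_wald),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::geom_hline(yintercept = -log10(suggestive),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(yintercept = -log10(genomewide),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' Plot MDS components coloured by a grouping
#'
#' @param mds An `mds_components` object.
#' @param groups Optional named labels per sample.
#' @param dims Which two components to draw.
#' @return A ggplot.
#' @export
plot_mds <- function(mds, groups = NULL, dims = c(1, 2)) {
  co <- mds$coords
  xcol <- paste0("mds", dims[1]); ycol <- paste0("mds", dims[2])
  co$group <- if (is.null(groups)) "sample" else groups[co$iid]
  ggplot2::ggplot(co, ggplot2::aes(x = .data[[xcol]], y = .data[[ycol]],
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' Plot GRS means with standard errors across onset groups
#'
#' @param scores Tibble `iid`, `grs`.
#' @param groups Named onset-group labels per sample.
#' @return A ggplot of mean +/- SE per ordered group.
#' @export
plot_grs_groups <- function(scores, groups) {
  grp <- groups[scores$iid]
  levs <- intersect(c("earliest", "earlier", "later", "latest"),
                    unique(grp))
  df <- tibble::tibble(group = factor(grp, levels = levs),
                       grs = scores$grs) |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$grs),
                     se = stats::sd(.data$grs) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "genetic risk score (mean ± SE)") +
    ggplot2::theme_minimal()
}
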