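#' Plot a pseudotime trajectory
#'
#' Species in the reduced two-component space, MST edges drawn as
#' segments, points coloured by pseudotime (or by a metadata column
#' supplied via `colour_by`).
#'
#' @param object A `pseudotime_result`.
#' @param colour_by Optional named character vector (by species id) used
#'   to colour the points, e.g. domains.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pseudotime_result <- function(object, colour_by = NULL, ...) {
  pts <- object$times
  seg <- dplyr::left_join(object$mst_edges,
                          dplyr::select(pts, "species_id", x = "IC1", y = "IC2"),
                          by = c(from = "species_id")) |>
    dplyr::left_join(dplyr::select(pts, "species_id", xend = "IC1", yend = "IC2"),
                     by = c(to = "species_id"))
  if (!is.null(colour_by)) {
    pts$colour <- colour_by[pts$species_id]
    colour_lab <- "group"
  } else {
    pts$colour <- pts$pseudotime
    colour_lab <- "pseudotime"
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$IC1, y = .data$IC2)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 2) +
    ggplot2::labs(colour = colour_lab,
                  title = "Quasi-evolutionary time trajectory",
                  subtitle = paste("root:", object$root)) +
    ggplot2::theme_minimal()
}

#' Plot amino-acid usage trends along pseudotime
#'
#' Usage (percent) versus pseudotime per amino acid, with the fitted
#' regression line, faceted; the facet label carries the gain/loss class
#' and the fit R-squared.
#'
#' @param object An `aa_trends` tibble from [fit_trends()].
#' @param amino_acids_shown Subset of amino acids to plot (default: all
#'   non-neutral, or everything if all are neutral).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aa_trends <- function(object, amino_acids_shown = NULL, ...) {
  data <- attr(object, "data")
  if (is.null(data)) stop("trend fit carries no data; refit with fit_trends()",
                          call. = FALSE)
  if (is.null(amino_acids_shown)) {
    amino_acids_shown <- object$amino_acid[object$class != "neutral"]
    if (length(amino_acids_shown) == 0) amino_acids_shown <- object$amino_acid
  }
  lab <- sprintf("%s (%s, R2=%.2f)", object$amino_acid, object$class,
                 object$r_squared)
  names(lab) <- object$amino_acid
  data <- dplyr::filter(data, .data$amino_acid %in% amino_acids_shown)
  data$panel <- lab[data$amino_acid]
  ggplot2::ggplot(data, ggplot2::aes(x = .data$pseudotime,
                                     y = .data$usage_percent)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "quasi-evolution time", y = "amino acid usage (%)") +
    ggplot2::theme_minimal()
}

#' Plot a GC-stratified fold-change table
#'
#' Log2 fold change per codon, coloured by the codon's third base; the
#' G/C-ending codons sit above zero when high-GC species favour them.
#'
#' @param object An `fc_table` from [fold_change()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      third = substr(.data$codon, 3, 3),
                      ending = ifelse(.data$third %in% c("G", "C"),
                                      "G/C-ending", "A/T-ending"))
  df <- dplyr::filter(df, !is.na(.data$fc) & .data$fc > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$codon, .data$fc),
    y = log2(.data$fc), fill = .data$ending)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log2 fold change (GC >= threshold / GC < threshold)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Plot a usage correlation matrix as a heatmap
#'
#' Features are ordered by average-linkage clustering on 1 - r so the two
#' correlation blocks are visible.
#'
#' @param object A `usage_correlation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.usage_correlation <- function(object, ...) {
  r <- object$r
  ok <- !apply(is.na(r), 1, all)
  r <- r[ok, ok]
  ord <- stats::hclust(stats::as.dist(1 - r), method = "average")$order
  lev <- rownames(r)[ord]
  df <- tibble::as_tibble(as.table(r), .name_repair = \(x) c("f1", "f2", "r"))
  df$f1 <- factor(df$f1, levels = lev)
  df$f2 <- factor(df$f2, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_text(size = 5))
}

#' Plot a usage dendrogram
#'
#' Base-graphics dendrogram of the species tree, optionally coloured tip
#' labels.
#'
#' @param x A `usage_dendrogram`.
#' @param ... Passed to [plot.hclust()].
#' @return `x`, invisibly.
#' @method plot usage_dendrogram
#' @export
plot.usage_dendrogram <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = paste0("UPGMA, ", x$dist_method, " distance"), ...)
  invisible(x)
}
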