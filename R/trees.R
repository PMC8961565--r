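#' Species dendrogram from a usage matrix
#'
#' Builds an average-linkage (UPGMA) dendrogram of species from their
#' codon-usage (64-element) or amino-acid-usage (20-element) vectors,
#' using the correlation distance d = 1 - Pearson(species_i, species_j).
#' The result is ultrametric: cophenetic distances equal merge heights.
#'
#' @param usage Wide usage tibble: `species_id` plus numeric feature
#'   columns; at least 3 species, unique ids.
#' @return An object of class `usage_dendrogram` wrapping the `hclust`
#'   fit, with fields `hclust`, `labels`, `dist_method`
#'   (`"1 - Pearson"`), `linkage` (`"average"`) and `n_features`.
#' @export
build_usage_tree <- function(usage) {
  mat <- usage_matrix(usage)
  if (nrow(mat) < 3) stop("need at least 3 species to build a tree", call. = FALSE)
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate species ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(t(mat))
  if (anyNA(r)) stop("undefined species correlations (constant profile?)",
                     call. = FALSE)
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, labels = rownames(mat),
                 dist_method = "1 - Pearson", linkage = "average",
                 n_features = ncol(mat)),
            class = "usage_dendrogram")
}

#' @export
print.usage_dendrogram <- function(x, ...) {
  cat("<usage_dendrogram> ", length(x$labels), " species, ", x$n_features,
      " features, ", x$dist_method, " distance, ", x$linkage, " linkage\n",
      sep = "")
  invisible(x)
}

#' Convert a usage dendrogram to an ape phylo tree
#'
#' Branch lengths follow the ultrametric convention: each leaf sits at
#' half the merge height below its parent (the `ape` hclust conversion).
#'
#' @param x A `usage_dendrogram`.
#' @param ... Unused.
#' @return An `ape::phylo` object.
#' @export
as.phylo.usage_dendrogram <- function(x, ...) {
  ape::as.phylo(x$hclust)
}

#' Write a usage dendrogram to a Newick file
#'
#' @param tree A `usage_dendrogram` (or `phylo`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "usage_dendrogram")) ape::as.phylo(tree) else tree
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Agreement between two usage dendrograms
#'
#' Quantifies how similar two dendrograms over the same species are:
#' the cophenetic correlation (Pearson correlation between the two
#' cophenetic distance matrices) and the Robinson-Foulds topological
#' distance normalized to \[0, 1\].
#'
#' @param t1,t2 `usage_dendrogram` objects with identical leaf sets.
#' @return A tibble with columns `cophenetic_correlation` and
#'   `rf_distance`.
#' @export
tree_agreement <- function(t1, t2) {
  stopifnot(inherits(t1, "usage_dendrogram"), inherits(t2, "usage_dendrogram"))
  if (!setequal(t1$labels, t2$labels)) {
    extra1 <- setdiff(t1$labels, t2$labels)
    extra2 <- setdiff(t2$labels, t1$labels)
    stop("leaf sets differ; only in tree 1: ",
         paste(extra1, collapse = ", "), "; only in tree 2: ",
         paste(extra2, collapse = ", "), call. = FALSE)
  }
  c1 <- as.matrix(stats::cophenetic(t1$hclust))
  c2 <- as.matrix(stats::cophenetic(t2$hclust))
  ord <- t1$labels
  c2 <- c2[ord, ord]
  lower <- lower.tri(c1)
  coph <- stats::cor(c1[lower], c2[lower])
  rf <- phangorn::RF.dist(ape::as.phylo(t1$hclust), ape::as.phylo(t2$hclust),
                          normalize = TRUE, rooted = FALSE)
  tibble::tibble(cophenetic_correlation = coph, rf_distance = rf)
}
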