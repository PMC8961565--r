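#' Usage correlation between features across species
#'
#' Pairwise Pearson (or Spearman) correlation between feature columns
#' (codons, degenerate codon families, or amino acids) over the species of
#' a cohort: for features p and y, cov(p, y) / (sd(p) sd(y)). Constant
#' columns have undefined correlation and yield `NA` rows/columns with a
#' warning.
#'
#' @param usage Wide usage tibble: `species_id` plus numeric feature
#'   columns.
#' @param method `"pearson"` or `"spearman"`.
#' @return An object of class `usage_correlation`: list with `r` (symmetric
#'   correlation matrix, unit diagonal), `features`, `method`, `n` (number
#'   of species).
#' @export
usage_correlation <- function(usage, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  mat <- usage_matrix(usage)
  if (nrow(mat) < 3) stop("need at least 3 species for usage correlation",
                          call. = FALSE)
  const <- apply(mat, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant feature column(s) give undefined correlations: ",
            paste(colnames(mat)[const], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(mat, method = method))
  diag(r) <- 1
  structure(list(r = r, features = colnames(mat), method = method,
                 n = nrow(mat)),
            class = "usage_correlation")
}

#' @export
print.usage_correlation <- function(x, ...) {
  cat("<usage_correlation> ", length(x$features), " features, ", x$method,
      ", n = ", x$n, " species\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation, closed form
#'
#' The classical 1 - 6 * sum(d^2) / (n (n^2 - 1)) formula on the rank
#' differences, exact only without ties; with ties present the
#' tie-corrected value (Pearson correlation of midranks) is returned
#' instead, with a message.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return Spearman correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    message("ties present: returning tie-corrected Spearman (Pearson on midranks)")
    return(stats::cor(rx, ry))
  }
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

#' Two-cluster extraction from a correlation matrix
#'
#' Builds a graph with an edge wherever the correlation exceeds `r_star`
#' (default 0.5) and takes the two largest connected components as the two
#' clusters; remaining features are left unassigned (`NA`). For codon
#' input, remove stop codons beforehand. If the graph has a single
#' component a one-cluster result is returned with a warning.
#'
#' @param corr A `usage_correlation` (or a symmetric correlation matrix).
#' @param r_star Correlation threshold for graph edges.
#' @return A tibble of class `cluster_assignment`: `feature`, `cluster`
#'   (1, 2 or `NA`; cluster 1 is the larger); attributes `r_star` and
#'   `method`.
#' @export
two_cluster <- function(corr, r_star = 0.5) {
  r <- if (inherits(corr, "usage_correlation")) corr$r else corr
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  adj <- (r > r_star) & !is.na(r)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  ord <- order(-comp$csize, seq_along(comp$csize))
  cluster <- rep(NA_integer_, nrow(r))
  if (comp$no < 2 || comp$csize[ord[2]] < 2) {
    warning("fewer than two multi-feature components at r > ", r_star,
            "; returning a single cluster", call. = FALSE)
    cluster[comp$membership == ord[1]] <- 1L
  } else {
    cluster[comp$membership == ord[1]] <- 1L
    cluster[comp$membership == ord[2]] <- 2L
  }
  out <- tibble::tibble(feature = rownames(r), cluster = cluster)
  attr(out, "r_star") <- r_star
  attr(out, "method") <- "connected components of the r > r_star graph"
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Hydrophobic/hydrophilic grouping of amino acids from properties
#'
#' Computes the Spearman correlation between the 20 amino acids over their
#' z-score-normalized physicochemical property vectors, then cuts an
#' average-linkage dendrogram on the distance 1 - r_s into two groups. The
#' group containing leucine is labelled `"hydrophobic"` (leucine anchors
#' the hydrophobic side), the other `"hydrophilic"`.
#'
#' @param props A normalized property table (see [normalize_properties()]);
#'   unnormalized input is an error.
#' @return A tibble of class `cluster_assignment`: `amino_acid`, `group`;
#'   attribute `correlation` holds the 20 x 20 Spearman matrix.
#' @export
property_grouping <- function(props) {
  if (!is_normalized(props)) {
    stop("property table is not normalized; call normalize_properties() first",
         call. = FALSE)
  }
  mat <- property_matrix(props)
  if (ncol(mat) < 2) stop("need at least 2 properties", call. = FALSE)
  rs <- stats::cor(t(mat), method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rs), method = "average")
  cut <- stats::cutree(hc, k = 2)
  hydro_id <- cut[["L"]]
  out <- tibble::tibble(
    amino_acid = rownames(mat),
    group = ifelse(cut == hydro_id, "hydrophobic", "hydrophilic")
  )
  attr(out, "correlation") <- rs
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Crosstalk between amino-acid clusters and degenerate-codon clusters
#'
#' Asks whether the usage cluster of each amino acid agrees with the usage
#' cluster of its degenerate codon family (by default the family fixing
#' the first two bases, XYN). An amino acid whose families fall in both
#' codon clusters is reported as split; amino acids without both
#' assignments are dropped from the agreement. The agreement fraction is
#' computed under the best of the two possible cluster-label pairings.
#'
#' @param aa_clusters `cluster_assignment` over amino acids (from
#'   [two_cluster()] on amino-acid usage; column `feature` or
#'   `amino_acid`).
#' @param codon_clusters `cluster_assignment` over degenerate codon
#'   families (from [two_cluster()] on [aggregate_degenerate()] output).
#' @param pattern Degeneracy pattern that produced `codon_clusters`.
#' @return A list of class `crosstalk_summary`: `per_aa` tibble
#'   (`amino_acid`, `aa_cluster`, `codon_cluster`, `split`), `agreement`
#'   (fraction in \[0, 1\]), `contingency` (2 x 2 table), `n_compared`.
#' @export
crosstalk <- function(aa_clusters, codon_clusters,
                      pattern = c("XYN", "XNY", "NXY", "XNN", "NXN", "NNX")) {
  pattern <- match.arg(pattern)
  feat_col <- if ("feature" %in% names(aa_clusters)) "feature" else "amino_acid"
  aa_map <- stats::setNames(aa_clusters$cluster, aa_clusters[[feat_col]])
  fam_col <- if ("feature" %in% names(codon_clusters)) "feature" else
    names(codon_clusters)[1]
  fam_map <- stats::setNames(codon_clusters$cluster, codon_clusters[[fam_col]])
  code <- genetic_code()
  fixed <- which(strsplit(pattern, "")[[1]] != "N")
  per_aa <- purrr::map_dfr(amino_acids(), function(a) {
    cods <- code$codon[code$aa == a]
    fams <- unique(vapply(cods, function(cd) {
      out <- c("N", "N", "N")
      chars <- strsplit(cd, "")[[1]]
      out[fixed] <- chars[fixed]
      paste0(out, collapse = "")
    }, character(1)))
    fc <- unique(stats::na.omit(fam_map[fams]))
    tibble::tibble(
      amino_acid = a,
      aa_cluster = if (a %in% names(aa_map)) aa_map[[a]] else NA_integer_,
      codon_cluster = if (length(fc) == 1) fc else NA_integer_,
      split = length(fc) > 1
    )
  })
  cmp <- dplyr::filter(per_aa, !is.na(.data$aa_cluster),
                       !is.na(.data$codon_cluster))
  if (nrow(cmp) == 0) {
    agreement <- NA_real_
    contingency <- table(factor(integer(0), 1:2), factor(integer(0), 1:2))
  } else {
    contingency <- table(aa = factor(cmp$aa_cluster, 1:2),
                         codon = factor(cmp$codon_cluster, 1:2))
    direct <- sum(diag(contingency)) / nrow(cmp)
    flipped <- (contingency[1, 2] + contingency[2, 1]) / nrow(cmp)
    agreement <- max(direct, flipped)
  }
  structure(list(per_aa = per_aa, agreement = agreement,
                 contingency = contingency, n_compared = nrow(cmp),
                 pattern = pattern),
            class = "crosstalk_summary")
}

#' @export
print.crosstalk_summary <- function(x, ...) {
  cat("<crosstalk_summary> pattern ", x$pattern, ": agreement ",
      format(x$agreement, digits = 3), " over ", x$n_compared,
      " amino acids\n", sep = "")
  invisible(x)
}
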