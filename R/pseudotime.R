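#' Independent-component reduction of a usage matrix
#'
#' Reduces species to a low-dimensional coordinate system by independent
#' component analysis: the usage columns are log-transformed
#' (`log(frequency + 1e-6)`), centered, whitened by SVD, then unmixed by
#' the symmetric fixed-point FastICA iteration with the log-cosh contrast.
#' The random unmixing initialization is driven by `seed`, so the result
#' is deterministic given seed and input.
#'
#' @param usage Wide usage tibble: `species_id` plus numeric feature
#'   columns; needs at least `n_components + 1` species.
#' @param n_components Number of components (default 2).
#' @param seed Integer seed for the unmixing initialization.
#' @param log_transform Apply the log transform before reduction.
#' @param max_iter,tol FastICA iteration controls.
#' @return A tibble: `species_id` plus `IC1`, ..., `IC<n_components>`.
#' @export
reduce_ica <- function(usage, n_components = 2, seed = 1L,
                       log_transform = TRUE, max_iter = 500, tol = 1e-8) {
  mat <- usage_matrix(usage)
  n <- nrow(mat)
  if (n < n_components + 1) {
    stop("need at least n_components + 1 species", call. = FALSE)
  }
  x <- if (log_transform) log(mat + 1e-6) else mat
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = n_components, nv = 0)
  if (sv$d[n_components] < max(sv$d) * 1e-10) {
    stop("rank-deficient input: fewer informative directions than ",
         "n_components; reduce n_components or use method = \"pca\" in ",
         "order_pseudotime()", call. = FALSE)
  }
  # whitened scores: n x k with identity covariance
  z <- sv$u[, seq_len(n_components), drop = FALSE] * sqrt(n - 1)
  w <- with_local_seed(seed, {
    m <- matrix(stats::rnorm(n_components^2), n_components)
    qr.Q(qr(m))
  })
  sym_decor <- function(w) {
    s <- w %*% t(w)
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), n_components) %*% t(e$vectors) %*% w
  }
  w <- sym_decor(w)
  for (it in seq_len(max_iter)) {
    wx <- z %*% t(w)
    g <- tanh(wx)
    gp <- 1 - g^2
    w_new <- t(g) %*% z / n - diag(colMeans(gp), n_components) %*% w
    w_new <- sym_decor(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) break
  }
  s <- z %*% t(w)
  # orientation convention: make each component's largest-|value| entry positive
  for (j in seq_len(n_components)) {
    if (s[which.max(abs(s[, j])), j] < 0) s[, j] <- -s[, j]
  }
  colnames(s) <- paste0("IC", seq_len(n_components))
  dplyr::bind_cols(tibble::tibble(species_id = rownames(mat)),
                   tibble::as_tibble(s))
}

# PCA fallback with the same interface
reduce_pca <- function(usage, n_components = 2, log_transform = TRUE) {
  mat <- usage_matrix(usage)
  x <- if (log_transform) log(mat + 1e-6) else mat
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  s <- p$x
  colnames(s) <- paste0("IC", seq_len(ncol(s)))
  dplyr::bind_cols(tibble::tibble(species_id = rownames(mat)),
                   tibble::as_tibble(s))
}

#' Quasi-evolutionary time from codon usage
#'
#' Orders species along a trajectory: the codon-usage matrix is reduced to
#' two independent components ([reduce_ica()]), a Euclidean minimum
#' spanning tree is built over the reduced coordinates, and each species'
#' pseudotime is its geodesic (path) distance from the root along the
#' MST, min-max normalized to \[0, 1\]. The default root is the species
#' with the highest GC content (species early in quasi-evolution time
#' tend to high GC); alternatives are an explicit species id or the
#' endpoint of the MST diameter. Root-rule ties are broken by species id.
#'
#' @param usage Wide codon-usage tibble: `species_id` plus frequency
#'   columns.
#' @param gc_percent GC percentages, named by species id (or a
#'   `species_id`/`gc_percent` tibble); required for `root = "max_gc"`.
#' @param root `"max_gc"`, `"diameter"`, or a species id.
#' @param n_components,seed,log_transform Passed to the reduction.
#' @param method `"ica"` (default) or `"pca"` for rank-deficient input.
#' @return An object of class `pseudotime_result`: list with `times`
#'   (tibble `species_id`, `pseudotime`, `IC1`, `IC2`, `on_backbone`),
#'   `mst_edges` (tibble `from`, `to`, `weight`), `backbone` (species ids
#'   of the MST diameter path), `root`, `seed`.
#' @export
order_pseudotime <- function(usage, gc_percent = NULL, root = "max_gc",
                             n_components = 2, seed = 1L,
                             log_transform = TRUE,
                             method = c("ica", "pca")) {
  method <- match.arg(method)
  coords_tbl <- if (method == "ica") {
    reduce_ica(usage, n_components, seed, log_transform)
  } else {
    reduce_pca(usage, n_components, log_transform)
  }
  coords <- as.matrix(coords_tbl[, -1, drop = FALSE])
  rownames(coords) <- coords_tbl$species_id
  ids <- rownames(coords)
  n <- length(ids)
  if (n < 2) stop("need at least 2 species", call. = FALSE)
  if (!all(is.finite(coords))) stop("non-finite reduced coordinates", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mstg <- igraph::mst(g)
  diam <- igraph::get_diameter(mstg)
  backbone <- ids[as.integer(diam)]
  root_id <- if (identical(root, "max_gc")) {
    if (is.null(gc_percent)) {
      stop("root = \"max_gc\" needs gc_percent", call. = FALSE)
    }
    gc <- if (is.data.frame(gc_percent)) {
      stats::setNames(gc_percent$gc_percent, gc_percent$species_id)
    } else gc_percent
    gc <- gc[ids]
    if (anyNA(gc)) stop("missing GC values for some species", call. = FALSE)
    cand <- ids[gc == max(gc)]
    if (length(cand) > 1) {
      message("root tie at maximum GC broken by species id")
    }
    sort(cand)[1]
  } else if (identical(root, "diameter")) {
    backbone[1]
  } else {
    if (!root %in% ids) stop("root species '", root, "' not in usage", call. = FALSE)
    root
  }
  geo <- igraph::distances(mstg, v = match(root_id, ids))[1, ]
  pt <- if (max(geo) > 0) (geo - min(geo)) / (max(geo) - min(geo)) else geo
  el <- igraph::as_edgelist(mstg, names = FALSE)
  times <- tibble::tibble(
    species_id = ids,
    pseudotime = unname(pt),
    on_backbone = ids %in% backbone
  )
  times <- dplyr::bind_cols(times, tibble::as_tibble(coords))
  structure(list(times = times,
                 mst_edges = tibble::tibble(from = ids[el[, 1]],
                                            to = ids[el[, 2]],
                                            weight = igraph::E(mstg)$weight),
                 backbone = backbone, root = root_id, seed = seed,
                 method = method),
            class = "pseudotime_result")
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat("<pseudotime_result> ", nrow(x$times), " species, root ", x$root,
      " (", x$method, " + MST)\n", sep = "")
  invisible(x)
}

#' Gain/loss trends of amino-acid usage along pseudotime
#'
#' Ordinary least-squares regression of each amino acid's usage (percent
#' scale) on pseudotime. An amino acid is classified `"lost"` if its slope
#' is negative and the fit R-squared reaches `r2_threshold`, `"gained"` if
#' positive with the same fit quality, else `"neutral"`.
#'
#' @param aa_usage Wide amino-acid usage tibble (`species_id` + 20
#'   frequency columns).
#' @param pseudotime A `pseudotime_result`, or a numeric vector of
#'   pseudotimes named by species id.
#' @param r2_threshold Minimum R-squared for a gained/lost call
#'   (default 0.5, inclusive).
#' @return A tibble of class `aa_trends`: `amino_acid`, `slope`,
#'   `intercept`, `r_squared`, `class`. Attribute `data` keeps the long
#'   usage-vs-pseudotime table for plotting.
#' @export
fit_trends <- function(aa_usage, pseudotime, r2_threshold = 0.5) {
  mat <- usage_matrix(aa_usage) * 100
  pt <- if (inherits(pseudotime, "pseudotime_result")) {
    stats::setNames(pseudotime$times$pseudotime, pseudotime$times$species_id)
  } else pseudotime
  pt <- pt[rownames(mat)]
  if (anyNA(pt)) stop("pseudotime missing for some species", call. = FALSE)
  if (stats::sd(pt) == 0) stop("constant pseudotime: trends undefined", call. = FALSE)
  fits <- purrr::map_dfr(colnames(mat), function(a) {
    if (stats::sd(mat[, a]) == 0) {
      # constant usage: nothing to explain, no trend
      return(tibble::tibble(amino_acid = a, slope = 0,
                            intercept = mat[1, a], r_squared = 0,
                            class = "neutral"))
    }
    fit <- stats::lm(mat[, a] ~ pt)
    r2 <- summary(fit)$r.squared
    slope <- unname(stats::coef(fit)[2])
    tibble::tibble(
      amino_acid = a,
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      class = if (r2 >= r2_threshold && slope < 0) "lost"
      else if (r2 >= r2_threshold && slope > 0) "gained"
      else "neutral"
    )
  })
  attr(fits, "data") <- tibble::tibble(
    species_id = rep(rownames(mat), ncol(mat)),
    pseudotime = rep(unname(pt), ncol(mat)),
    amino_acid = rep(colnames(mat), each = nrow(mat)),
    usage_percent = as.vector(mat)
  )
  attr(fits, "r2_threshold") <- r2_threshold
  class(fits) <- c("aa_trends", class(fits))
  fits
}
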