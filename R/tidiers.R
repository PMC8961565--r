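#' Tidy a pseudotime result
#'
#' One row per species: pseudotime, reduced coordinates and whether the
#' species lies on the MST backbone (diameter path).
#'
#' @param x A `pseudotime_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pseudotime_result <- function(x, ...) {
  dplyr::arrange(x$times, .data$pseudotime)
}

#' Glance at a pseudotime result
#'
#' @param x A `pseudotime_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_species`, `root`, `method`,
#'   `n_backbone`, `mst_total_length`.
#' @export
glance.pseudotime_result <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$times),
    root = x$root,
    method = x$method,
    n_backbone = length(x$backbone),
    mst_total_length = sum(x$mst_edges$weight)
  )
}

#' Tidy a usage correlation matrix into long form
#'
#' @param x A `usage_correlation`.
#' @param ... Unused.
#' @return A tibble: `feature1`, `feature2`, `r` (each unordered pair
#'   once, diagonal excluded).
#' @export
tidy.usage_correlation <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    feature1 = x$features[idx[, 1]],
    feature2 = x$features[idx[, 2]],
    r = x$r[idx]
  )
}

#' Tidy a usage dendrogram
#'
#' @param x A `usage_dendrogram`.
#' @param ... Unused.
#' @return A tibble of merges: `step`, `height`, `member1`, `member2`
#'   (negative entries index species, positive entries earlier merges,
#'   the `hclust` convention).
#' @export
tidy.usage_dendrogram <- function(x, ...) {
  m <- x$hclust$merge
  tibble::tibble(
    step = seq_len(nrow(m)),
    height = x$hclust$height,
    member1 = m[, 1],
    member2 = m[, 2]
  )
}

#' Glance at a usage dendrogram
#'
#' @param x A `usage_dendrogram`.
#' @param ... Unused.
#' @return A one-row tibble: `n_species`, `n_features`, `dist_method`,
#'   `linkage`, `max_height`.
#' @export
glance.usage_dendrogram <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$labels),
    n_features = x$n_features,
    dist_method = x$dist_method,
    linkage = x$linkage,
    max_height = max(x$hclust$height)
  )
}

#' Tidy a recruitment model
#'
#' @param x A `recruitment_model`.
#' @param ... Unused.
#' @return A tibble, one row per amino acid: `amino_acid`, `status`
#'   (old/new), `property_group`, `route_position` (`NA` for old amino
#'   acids).
#' @export
tidy.recruitment_model <- function(x, ...) {
  pos <- stats::setNames(rep(NA_integer_, 20), amino_acids())
  for (route in x$routes) pos[route] <- seq_along(route)
  tibble::tibble(
    amino_acid = x$evidence$amino_acid,
    status = ifelse(x$evidence$amino_acid %in% x$old_set, "old", "new"),
    property_group = x$evidence$property_group,
    route_position = unname(pos[x$evidence$amino_acid])
  )
}

#' Glance at a recruitment model
#'
#' @param x A `recruitment_model`.
#' @param ... Unused.
#' @return A one-row tibble: counts and collapsed route strings.
#' @export
glance.recruitment_model <- function(x, ...) {
  tibble::tibble(
    n_old = length(x$old_set),
    n_new = length(x$new_set),
    routes = paste(vapply(x$routes, paste, character(1), collapse = ">"),
                   collapse = " | ")
  )
}
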