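#' Rank amino-acid usage within each species
#'
#' For every species the 20 amino acids are ranked by usage, the most used
#' getting rank 20 and the least used rank 1, so the per-species ranks are
#' always a permutation of 1..20 (sum 210). Ties in frequency are broken
#' deterministically: the amino acid with more codons ranks higher, then
#' the alphabetically earlier letter; a message reports how many ties were
#' resolved.
#'
#' @param aa_usage Wide usage tibble: `species_id` plus 20 amino-acid
#'   frequency columns (see [cohort_usage()]).
#' @return A long tibble: `species_id`, `amino_acid`, `frequency`, `rank`.
#' @export
rank_usage <- function(aa_usage) {
  mat <- usage_matrix(aa_usage)
  if (!setequal(colnames(mat), amino_acids())) {
    stop("aa_usage must have exactly the 20 amino-acid columns", call. = FALSE)
  }
  mat <- mat[, amino_acids(), drop = FALSE]
  deg <- degeneracy()
  n_ties <- 0L
  rows <- purrr::map(seq_len(nrow(mat)), function(i) {
    f <- mat[i, ]
    if (anyDuplicated(f)) n_ties <<- n_ties + 1L
    ord <- order(-f, -deg, amino_acids()) # position 1 = most used
    rank <- integer(20)
    rank[ord] <- 20:1
    tibble::tibble(species_id = rownames(mat)[i],
                   amino_acid = amino_acids(),
                   frequency = unname(f),
                   rank = rank)
  })
  if (n_ties > 0) {
    message("resolved frequency ties in ", n_ties,
            " species (codon count, then alphabetical)")
  }
  dplyr::bind_rows(rows)
}

#' Summed usage-rank scores per species group
#'
#' The group score of an amino acid is the sum, over the group's species,
#' of the per-species rank assigned by [rank_usage()]. With no grouping a
#' single `Total` group over all species is returned.
#'
#' @param ranks Long rank tibble from [rank_usage()].
#' @param grouping Optional named vector or two-column tibble
#'   (`species_id`, `group`) mapping species to groups (e.g. domains).
#' @return A tibble: `group`, `amino_acid`, `score`, `n_species`.
#' @export
rank_scores <- function(ranks, grouping = NULL) {
  stopifnot(all(c("species_id", "amino_acid", "rank") %in% names(ranks)))
  if (is.null(grouping)) {
    grp <- tibble::tibble(species_id = unique(ranks$species_id), group = "Total")
  } else if (is.data.frame(grouping)) {
    stopifnot(all(c("species_id", "group") %in% names(grouping)))
    grp <- grouping[, c("species_id", "group")]
  } else {
    grp <- tibble::tibble(species_id = names(grouping),
                          group = unname(as.character(grouping)))
  }
  dplyr::inner_join(ranks, grp, by = "species_id") |>
    dplyr::group_by(.data$group, .data$amino_acid) |>
    dplyr::summarise(score = sum(.data$rank),
                     n_species = dplyr::n_distinct(.data$species_id),
                     .groups = "drop")
}

#' Coefficient of variation of amino-acid usage across a species group
#'
#' CV = sd / mean of each amino acid's usage across the species of a group
#' (sample standard deviation). The CV is scale-free, so it is identical on
#' the fraction and percent scales; the `stable` flag marks amino acids
#' with CV below `cv_threshold` percent.
#'
#' @inheritParams rank_usage
#' @param grouping Optional species-to-group mapping as in [rank_scores()];
#'   every group needs at least 2 species.
#' @param cv_threshold Stability threshold on the percent scale
#'   (default 15: CV * 100 < 15).
#' @return A tibble: `group`, `amino_acid`, `mean`, `sd`, `cv`, `stable`.
#'   `cv` is `NA` where the mean usage is zero.
#' @export
usage_cv <- function(aa_usage, grouping = NULL, cv_threshold = 15) {
  mat <- usage_matrix(aa_usage)
  grp <- if (is.null(grouping)) {
    stats::setNames(rep("Total", nrow(mat)), rownames(mat))
  } else if (is.data.frame(grouping)) {
    stats::setNames(grouping$group, grouping$species_id)
  } else {
    stats::setNames(as.character(grouping), names(grouping))
  }
  grp <- grp[rownames(mat)]
  sizes <- table(grp)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 species: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(sort(unique(grp)), function(g) {
    sub <- mat[grp == g, , drop = FALSE]
    mu <- colMeans(sub)
    sd <- apply(sub, 2, stats::sd)
    tibble::tibble(group = g, amino_acid = colnames(sub),
                   mean = unname(mu), sd = unname(sd),
                   cv = unname(ifelse(mu > 0, sd / mu, NA_real_))) |>
      dplyr::mutate(stable = .data$cv * 100 < cv_threshold)
  })
}

#' GC-stratified fold change of codon usage
#'
#' Splits the cohort at a GC-content threshold (default 45%, the boundary
#' assigned to the high-GC stratum) and reports, per codon, the mean and
#' standard deviation of usage on the percent scale in each stratum and
#' their ratio `fc = mean_ge / mean_lt`. Stop codons are included. `fc` is
#' `NA` where the low-GC mean is zero.
#'
#' @param codon_usage Wide usage tibble: `species_id` plus 64 codon
#'   frequency columns.
#' @param gc_percent Named numeric vector (by species id) or two-column
#'   tibble (`species_id`, `gc_percent`) of GC percentages.
#' @param threshold GC threshold in percent.
#' @return A tibble of class `fc_table`: `codon`, `aa`, `is_stop`,
#'   `mean_lt`, `sd_lt`, `mean_ge`, `sd_ge`, `fc`; attributes `threshold`,
#'   `n_lt`, `n_ge`.
#' @export
fold_change <- function(codon_usage, gc_percent, threshold = 45) {
  mat <- usage_matrix(codon_usage) * 100
  gc <- if (is.data.frame(gc_percent)) {
    stats::setNames(gc_percent$gc_percent, gc_percent$species_id)
  } else gc_percent
  if (is.null(names(gc))) {
    stopifnot(length(gc) == nrow(mat))
    names(gc) <- rownames(mat)
  }
  gc <- gc[rownames(mat)]
  if (anyNA(gc)) stop("missing GC values for some species", call. = FALSE)
  hi <- gc >= threshold
  if (!any(hi)) stop("empty stratum: no species with GC >= ", threshold, call. = FALSE)
  if (all(hi)) stop("empty stratum: no species with GC < ", threshold, call. = FALSE)
  lo_m <- mat[!hi, , drop = FALSE]
  hi_m <- mat[hi, , drop = FALSE]
  code <- genetic_code()
  keep <- intersect(code$codon, colnames(mat))
  out <- tibble::tibble(
    codon = keep,
    aa = code$aa[match(keep, code$codon)],
    is_stop = code$is_stop[match(keep, code$codon)],
    mean_lt = unname(colMeans(lo_m)[keep]),
    sd_lt = unname(apply(lo_m, 2, stats::sd)[keep]),
    mean_ge = unname(colMeans(hi_m)[keep]),
    sd_ge = unname(apply(hi_m, 2, stats::sd)[keep])
  ) |>
    dplyr::mutate(fc = ifelse(.data$mean_lt > 0,
                              .data$mean_ge / .data$mean_lt, NA_real_))
  attr(out, "threshold") <- threshold
  attr(out, "n_lt") <- sum(!hi)
  attr(out, "n_ge") <- sum(hi)
  class(out) <- c("fc_table", class(out))
  out
}

#' Aggregate codon usage over degenerate codon families
#'
#' Sums codon frequencies over families sharing fixed base positions. With
#' two fixed positions (`"XYN"`, `"XNY"`, `"NXY"`) the 64 codons collapse
#' to 16 features; with one fixed position (`"XNN"`, `"NXN"`, `"NNX"`) to
#' 4. Total usage mass is conserved exactly.
#'
#' @param codon_usage Wide usage tibble: `species_id` plus codon columns.
#' @param pattern Degeneracy pattern; `X`/`Y` mark fixed positions, `N` the
#'   free one, e.g. `"XYN"` fixes the first two bases (family `GCN` =
#'   GCA + GCC + GCG + GCT).
#' @return A wide tibble: `species_id` plus one column per family, named
#'   with `N` at the free positions.
#' @export
aggregate_degenerate <- function(codon_usage,
                                 pattern = c("XYN", "XNY", "NXY", "XNN", "NXN", "NNX")) {
  pattern <- match.arg(pattern)
  mat <- usage_matrix(codon_usage)
  fixed <- which(strsplit(pattern, "")[[1]] != "N")
  fam <- vapply(colnames(mat), function(cd) {
    out <- c("N", "N", "N")
    chars <- strsplit(cd, "")[[1]]
    out[fixed] <- chars[fixed]
    paste0(out, collapse = "")
  }, character(1))
  agg <- t(rowsum(t(mat), group = fam))
  agg <- agg[, sort(colnames(agg)), drop = FALSE]
  dplyr::bind_cols(tibble::tibble(species_id = rownames(mat)),
                   tibble::as_tibble(agg))
}
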