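# Independent oracles: deliberately naive re-implementations used to verify
# the package's fast paths. They share no code with the package internals.

# frame-0 triplet counter: loop over substrings, keep pure-ACGT codons only
naive_codon_count <- function(seqs) {
  counts <- integer(0)
  for (s in seqs) {
    s <- toupper(gsub("U", "T", s, ignore.case = TRUE))
    n <- nchar(s) %/% 3
    if (n == 0) next
    for (k in seq_len(n)) {
      cod <- substr(s, 3 * k - 2, 3 * k)
      if (grepl("^[ACGT]{3}$", cod)) {
        counts[cod] <- if (cod %in% names(counts)) counts[[cod]] + 1L else 1L
      }
    }
  }
  counts
}

# residue counter over the 20 canonical letters only
naive_aa_count <- function(prots) {
  all_chars <- unlist(strsplit(toupper(paste(prots, collapse = "")), ""))
  keep <- all_chars[all_chars %in% amino_acids()]
  table(factor(keep, levels = amino_acids()))
}

# codon-table translation oracle: independent lookup, stop terminates,
# ambiguous codons emit nothing
naive_translate <- function(s) {
  map <- with(as.data.frame(genetic_code()), stats::setNames(aa, codon))
  s <- toupper(gsub("U", "T", s, ignore.case = TRUE))
  out <- character(0)
  for (k in seq_len(nchar(s) %/% 3)) {
    cod <- substr(s, 3 * k - 2, 3 * k)
    if (!grepl("^[ACGT]{3}$", cod)) next
    aa <- map[[cod]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# O(n^3) UPGMA agglomerator; returns heights and the leaf partition after
# each merge, for exact comparison with hclust's merge order
naive_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(0)
  partitions <- list()
  cd <- d
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in idx) for (j in idx) {
      if (i < j && cd[i, j] < best_d) {
        best_d <- cd[i, j]
        best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    # UPGMA: unweighted average over all leaf pairs
    merged <- c(clusters[[i]], clusters[[j]])
    clusters[[i]] <- merged
    active[j] <- FALSE
    for (k in which(active)) {
      if (k == i) next
      pairs <- expand.grid(merged, clusters[[k]])
      cd[i, k] <- cd[k, i] <- mean(d[cbind(pairs[, 1], pairs[, 2])])
    }
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1]] <-
      lapply(clusters[active], sort)
  }
  list(heights = heights, partitions = partitions)
}

# partition of leaves implied by an hclust object after each merge
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  members <- lapply(seq_len(n), identity)
  clusters <- as.list(seq_len(n))
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    get_m <- function(v) if (v < 0) -v else members[[n + v]]
    m <- sort(c(get_m(hc$merge[s, 1]), get_m(hc$merge[s, 2])))
    members[[n + s]] <- m
    clusters <- Filter(function(cl) !any(cl %in% m), clusters)
    clusters[[length(clusters) + 1]] <- m
    out[[s]] <- lapply(clusters, sort)
  }
  out
}

set_equal_partitions <- function(p1, p2) {
  key <- function(p) sort(vapply(p, function(cl) paste(cl, collapse = ","),
                                 character(1)))
  identical(key(p1), key(p2))
}

# two-pass stratified fold change on the percent scale
naive_fold_change <- function(mat_pct, gc, threshold = 45) {
  hi <- gc >= threshold
  vapply(colnames(mat_pct), function(cd) {
    mean(mat_pct[hi, cd]) / mean(mat_pct[!hi, cd])
  }, numeric(1))
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}
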