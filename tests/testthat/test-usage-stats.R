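make_aa_usage <- function(mat) {
  dplyr::bind_cols(
    tibble::tibble(species_id = rownames(mat)),
    tibble::as_tibble(mat)
  )
}

test_that("per-species ranks are a permutation of 1..20 summing to 210", {
  f <- sort(runif(20, 0.01, 0.1))
  f <- f / sum(f)
  mat <- matrix(f, nrow = 1, dimnames = list("s1", amino_acids()))
  ranks <- rank_usage(make_aa_usage(mat))
  expect_setequal(ranks$rank, 1:20)
  expect_equal(sum(ranks$rank), 210)
  # most used amino acid carries rank 20
  expect_equal(ranks$amino_acid[ranks$rank == 20],
               amino_acids()[which.max(f)])
})

test_that("group scores double when a species is duplicated", {
  set.seed(31)
  f <- runif(20); f <- f / sum(f)
  mat <- rbind(s1 = f, s2 = f)
  colnames(mat) <- amino_acids()
  scores2 <- rank_scores(rank_usage(make_aa_usage(mat)))
  scores1 <- rank_scores(rank_usage(make_aa_usage(mat[1, , drop = FALSE])))
  expect_equal(scores2$score, 2 * scores1$score)
})

test_that("group scores equal a brute-force sort-and-sum oracle", {
  set.seed(32)
  mat <- matrix(runif(200), nrow = 10,
                dimnames = list(paste0("s", 1:10), amino_acids()))
  mat <- mat / rowSums(mat)
  scores <- rank_scores(rank_usage(make_aa_usage(mat)),
                        grouping = stats::setNames(rep(c("g1", "g2"), each = 5),
                                                   rownames(mat)))
  oracle <- sapply(amino_acids(), function(a) {
    per_species <- apply(mat, 1, function(f) rank(f)[a]) # rank 20 = most used
    c(g1 = sum(per_species[1:5]), g2 = sum(per_species[6:10]))
  })
  for (g in c("g1", "g2")) {
    got <- scores$score[scores$group == g]
    names(got) <- scores$amino_acid[scores$group == g]
    expect_equal(got[amino_acids()], oracle[g, ],
                 ignore_attr = TRUE)
  }
})

test_that("ranking is invariant to positive rescaling of a species vector", {
  set.seed(33)
  f <- runif(20); f <- f / sum(f)
  mat1 <- matrix(f, 1, dimnames = list("s1", amino_acids()))
  mat2 <- mat1 * 7.3
  expect_equal(rank_usage(make_aa_usage(mat1))$rank,
               rank_usage(make_aa_usage(mat2))$rank)
})

test_that("rank ties resolve by codon count, then alphabetically", {
  f <- rep(0.05, 20)
  mat <- matrix(f, 1, dimnames = list("s1", amino_acids()))
  expect_message(ranks <- rank_usage(make_aa_usage(mat)), "ties")
  r <- stats::setNames(ranks$rank, ranks$amino_acid)
  # all tied: six-codon amino acids (L, R, S) outrank everything, alphabetical
  expect_equal(unname(r[c("L", "R", "S")]), c(20, 19, 18))
  # single-codon amino acids (M, W) come last
  expect_equal(unname(r[c("M", "W")]), c(2, 1))
})

test_that("CV follows the sample-sd convention", {
  mat <- rbind(s1 = rep(0.05, 20), s2 = rep(0.05, 20))
  colnames(mat) <- amino_acids()
  cv0 <- usage_cv(make_aa_usage(mat))
  expect_true(all(cv0$cv == 0))
  expect_true(all(cv0$stable))

  mat2 <- mat
  mat2[, "A"] <- c(0.04, 0.06) # percent-scale column {4, 6}
  cv <- usage_cv(make_aa_usage(mat2))
  expect_equal(cv$cv[cv$amino_acid == "A"], sqrt(2) / 5)
  expect_false(cv$stable[cv$amino_acid == "A"]) # CV% = 28.3 >= 15

  expect_error(usage_cv(make_aa_usage(mat[1, , drop = FALSE])), "fewer than 2")
})

test_that("fold change matches an independent two-pass oracle exactly", {
  cu <- small_codon_usage()
  gc <- small_gc()
  fc <- fold_change(cu, gc)
  mat_pct <- as.matrix(cu[, -1]) * 100
  rownames(mat_pct) <- cu$species_id
  oracle <- naive_fold_change(mat_pct, gc[cu$species_id])
  expect_equal(stats::setNames(fc$fc, fc$codon)[names(oracle)], oracle,
               tolerance = 1e-12)
  expect_equal(nrow(fc), 64) # stops included
})

test_that("identical strata give fold change one; empty strata error", {
  mat <- matrix(rep(c(0.25, 0.25, 0.25, 0.25), 3), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3),
                                c("ATG", "TAA", "GCG", "GCA")))
  usage <- dplyr::bind_cols(tibble::tibble(species_id = rownames(mat)),
                            tibble::as_tibble(mat))
  fc <- fold_change(usage, c(s1 = 30, s2 = 50, s3 = 60))
  expect_true(all(fc$fc == 1))
  expect_error(fold_change(usage, c(s1 = 50, s2 = 50, s3 = 60)), "GC < 45")
  expect_error(fold_change(usage, c(s1 = 30, s2 = 30, s3 = 30)), "GC >= 45")
})

test_that("planted GC drift enriches G/C-ending codons in the high-GC stratum", {
  fc <- fold_change(default_codon_usage(), default_gc())
  third <- substr(fc$codon, 3, 3)
  sense <- !fc$is_stop
  expect_true(all(fc$fc[sense & third %in% c("G", "C")] > 1))
  expect_true(all(fc$fc[sense & third %in% c("A", "T")] < 1))
})

test_that("threshold boundary species belong to the high-GC stratum", {
  mat <- matrix(c(0.5, 0.5, 0.2, 0.8), nrow = 2, byrow = TRUE,
                dimnames = list(c("lo", "hi"), c("ATG", "TAA")))
  usage <- dplyr::bind_cols(tibble::tibble(species_id = rownames(mat)),
                            tibble::as_tibble(mat))
  fc <- fold_change(usage, c(lo = 30, hi = 45)) # 45 exactly
  expect_equal(attr(fc, "n_ge"), 1)
  expect_equal(fc$fc[fc$codon == "ATG"], 0.2 / 0.5)
})

test_that("degenerate aggregation conserves mass and matches regex grouping", {
  cu <- small_codon_usage()
  agg <- aggregate_degenerate(cu, "XYN")
  expect_equal(ncol(agg), 17) # 16 families
  expect_equal(rowSums(as.matrix(agg[, -1])), rowSums(as.matrix(cu[, -1])))
  # definition: GCN = GCA + GCC + GCG + GCT
  gcn <- cu$GCA + cu$GCC + cu$GCG + cu$GCT
  expect_equal(agg$GCN, gcn)

  # independent regex-grouping oracle on every family of every pattern
  for (pat in c("XYN", "XNY", "NXY", "XNN", "NXN", "NNX")) {
    a <- aggregate_degenerate(cu, pat)
    nfeat <- if (nchar(gsub("N", "", pat)) == 2) 16 else 4
    expect_equal(ncol(a) - 1, nfeat)
    for (fam in setdiff(names(a), "species_id")) {
      rx <- paste0("^", gsub("N", "[ACGT]", fam), "$")
      members <- grep(rx, codons(), value = TRUE)
      expect_equal(a[[fam]], rowSums(as.matrix(cu[, members])),
                   ignore_attr = TRUE)
    }
  }
})
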