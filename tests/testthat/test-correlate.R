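usage_from_matrix <- function(mat) {
  dplyr::bind_cols(tibble::tibble(species_id = rownames(mat)),
                   tibble::as_tibble(mat))
}

test_that("usage correlation matches the direct covariance formula", {
  set.seed(41)
  mat <- matrix(rnorm(20), nrow = 5,
                dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  cr <- usage_correlation(usage_from_matrix(mat))
  for (i in 1:4) for (j in 1:4) {
    oracle <- cov(mat[, i], mat[, j]) / (sd(mat[, i]) * sd(mat[, j]))
    expect_equal(cr$r[i, j], oracle, tolerance = 1e-12)
  }
  expect_equal(diag(cr$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cr$r, t(cr$r))
  # a column against its own negation (after centering) is -1
  mat2 <- cbind(mat, f5 = -mat[, 1])
  cr2 <- usage_correlation(usage_from_matrix(mat2))
  expect_equal(cr2$r["f1", "f5"], -1)
})

test_that("usage correlation guards its preconditions", {
  mat <- matrix(runif(4), nrow = 2,
                dimnames = list(c("a", "b"), c("f1", "f2")))
  expect_error(usage_correlation(usage_from_matrix(mat)), "at least 3")
  mat3 <- matrix(c(1, 1, 1, 2, 3, 1), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("const", "f2")))
  expect_warning(cr <- usage_correlation(usage_from_matrix(mat3)), "const")
  expect_true(is.na(cr$r["const", "f2"]))
})

test_that("closed-form Spearman equals Pearson on ranks when tie-free", {
  set.seed(42)
  for (rep in 1:10) {
    x <- sample(rnorm(30)) # continuous: no ties
    y <- rnorm(30)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
  expect_message(r <- spearman_rho(c(1, 1, 2, 3), c(4, 3, 2, 1)), "tie")
  expect_equal(r, cor(c(1, 1, 2, 3), c(4, 3, 2, 1), method = "spearman"))
})

test_that("two-cluster extraction recovers a planted block structure", {
  r <- matrix(-0.9, 6, 6)
  r[1:3, 1:3] <- 0.9
  r[4:6, 4:6] <- 0.9
  diag(r) <- 1
  rownames(r) <- colnames(r) <- paste0("f", 1:6)
  cl <- two_cluster(r)
  expect_equal(sort(unique(cl$cluster)), c(1L, 2L))
  expect_length(unique(cl$cluster[1:3]), 1)
  expect_length(unique(cl$cluster[4:6]), 1)
  expect_false(cl$cluster[1] == cl$cluster[4])

  # feature-order invariance
  perm <- c(4, 1, 5, 2, 6, 3)
  cl2 <- two_cluster(r[perm, perm])
  m1 <- stats::setNames(cl$cluster, cl$feature)
  m2 <- stats::setNames(cl2$cluster, cl2$feature)
  agree <- mean(m1[names(m2)] == m2)
  expect_true(agree %in% c(0, 1)) # identical up to label swap
})

test_that("an edgeless correlation graph falls back to one cluster with warning", {
  r <- diag(4)
  rownames(r) <- colnames(r) <- paste0("f", 1:4)
  expect_warning(cl <- two_cluster(r), "single cluster")
  expect_true(all(is.na(cl$cluster) | cl$cluster == 1))
})

test_that("codon usage splits into G/C-ending and A/T-ending clusters", {
  cu <- small_codon_usage()
  sense <- cu[, !(names(cu) %in% stop_codons())]
  cl <- two_cluster(usage_correlation(sense))
  assigned <- !is.na(cl$cluster)
  expect_gt(mean(assigned), 0.8)
  third <- substr(cl$feature, 3, 3)
  ending <- ifelse(third %in% c("G", "C"), "GC", "AT")
  tab <- table(cl$cluster[assigned], ending[assigned])
  # each cluster is pure in ending base
  expect_true(all(apply(tab, 1, function(x) min(x) == 0)))
  expect_equal(nrow(tab), 2)
})

test_that("property grouping recovers the planted blocks and demands normalization", {
  props <- simulate_property_table(200, noise_sd = 0.3, seed = 3)
  expect_error(property_grouping(props), "normalize")
  pg <- property_grouping(normalize_properties(props))
  expect_equal(stats::setNames(pg$group, pg$amino_acid)[amino_acids()],
               aa_property_blocks()[amino_acids()])
})

test_that("property grouping is invariant to monotone column transforms", {
  props <- simulate_property_table(60, noise_sd = 0.2, seed = 9)
  g1 <- property_grouping(normalize_properties(props))
  warped <- props
  for (j in setdiff(names(warped), "amino_acid")) {
    warped[[j]] <- exp(warped[[j]] / 2) # strictly increasing transform
  }
  attr(warped, "normalized") <- FALSE
  g2 <- property_grouping(normalize_properties(warped))
  expect_equal(g1$group, g2$group)
})

test_that("identical property rows correlate perfectly", {
  set.seed(43)
  mat <- matrix(rnorm(20 * 8), nrow = 20,
                dimnames = list(amino_acids(), paste0("p", 1:8)))
  mat["V", ] <- mat["L", ] # V mirrors L
  props <- normalize_properties(as_property_table(mat))
  pg <- property_grouping(props)
  rs <- attr(pg, "correlation")
  expect_equal(rs["L", "V"], 1)
})

test_that("a real physicochemical property set places L, I, V, F together", {
  # independent real-data fixture: the curated AAindex collection shipped
  # with seqinr, parsed upstream of this package
  data("aaindex", package = "seqinr", envir = environment())
  three <- names(aaindex[[1]]$I)
  one <- stats::setNames(
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
      "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"))
  vals <- vapply(aaindex, function(e) unname(e$I[three]), numeric(20))
  rownames(vals) <- unname(one[three])
  mat <- vals[, !apply(is.na(vals), 2, any)]
  pg <- property_grouping(normalize_properties(as_property_table(mat)))
  groups <- stats::setNames(pg$group, pg$amino_acid)
  expect_length(unique(groups[c("L", "I", "V", "F")]), 1)
  expect_equal(unname(groups[["L"]]), "hydrophobic")
})

test_that("crosstalk is perfect for aligned clusters and near chance for random ones", {
  aa_cl <- tibble::tibble(feature = amino_acids(),
                          cluster = rep(c(1L, 2L), 10))
  # degenerate families inheriting each amino acid's cluster exactly
  code <- genetic_code()
  fams <- unique(substr(code$codon, 1, 2))
  fam_cluster <- vapply(fams, function(f) {
    aas <- unique(code$aa[substr(code$codon, 1, 2) == f & !code$is_stop])
    cl <- unique(aa_cl$cluster[match(aas, aa_cl$feature)])
    if (length(cl) == 1) cl else NA_integer_
  }, integer(1))
  fam_cl <- tibble::tibble(feature = paste0(fams, "N"),
                           cluster = fam_cluster)
  ct <- crosstalk(aa_cl, fam_cl, "XYN")
  expect_equal(ct$agreement, 1)

  # independent random assignments hover near the chance level
  set.seed(44)
  agreements <- replicate(50, {
    a <- tibble::tibble(feature = amino_acids(),
                        cluster = sample(c(1L, 2L), 20, TRUE))
    f <- tibble::tibble(feature = paste0(fams, "N"),
                        cluster = sample(c(1L, 2L), length(fams), TRUE))
    crosstalk(a, f, "XYN")$agreement
  })
  # best-pairing agreement of independent labels concentrates near 0.5-0.7
  expect_lt(mean(agreements), 0.75)
  expect_gt(mean(agreements), 0.5)
})

test_that("first-two-base degeneracy shows stronger crosstalk than single-base", {
  cu <- small_codon_usage()
  au <- small_aa_usage()
  aa_cl <- two_cluster(usage_correlation(au))
  agr <- vapply(c("XYN", "XNN", "NXN"), function(pat) {
    deg <- aggregate_degenerate(cu, pat)
    dcl <- suppressWarnings(two_cluster(usage_correlation(deg)))
    crosstalk(aa_cl, dcl, pat)$agreement
  }, numeric(1))
  expect_gte(agr[["XYN"]], agr[["XNN"]])
  expect_gte(agr[["XYN"]], agr[["NXN"]])
})
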