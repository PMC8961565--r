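usage_from_matrix <- function(mat) {
  dplyr::bind_cols(tibble::tibble(species_id = rownames(mat)),
                   tibble::as_tibble(mat))
}

test_that("ICA recovers a planted latent direction", {
  set.seed(61)
  n <- 80
  t <- seq(0, 1, length.out = n)
  loadings <- rnorm(12)
  mat <- outer(t, loadings) + matrix(rnorm(n * 12, 0, 0.05), n)
  rownames(mat) <- sprintf("s%02d", 1:n)
  colnames(mat) <- paste0("f", 1:12)
  red <- reduce_ica(usage_from_matrix(mat), n_components = 2, seed = 1,
                    log_transform = FALSE)
  r1 <- abs(cor(red$IC1, t))
  r2 <- abs(cor(red$IC2, t))
  expect_gt(max(r1, r2), 0.95)
})

test_that("ICA is deterministic given the seed and equivariant to row permutation", {
  cu <- small_codon_usage()
  r1 <- reduce_ica(cu, seed = 5)
  r2 <- reduce_ica(cu, seed = 5)
  expect_identical(r1, r2)

  perm <- sample(nrow(cu))
  r3 <- reduce_ica(cu[perm, ], seed = 5)
  merged <- dplyr::inner_join(r1, r3, by = "species_id")
  expect_equal(merged$IC1.x, merged$IC1.y, tolerance = 1e-6)
  expect_equal(merged$IC2.x, merged$IC2.y, tolerance = 1e-6)
})

test_that("rank-deficient input errors and suggests the PCA fallback", {
  mat <- matrix(rep(1:4, 3), nrow = 4,
                dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  expect_error(reduce_ica(usage_from_matrix(mat), log_transform = FALSE),
               "pca")
})

test_that("collinear points order positionally from the root end", {
  n <- 9
  mat <- cbind(x = seq_len(n), y = 2 * seq_len(n))
  rownames(mat) <- sprintf("s%d", seq_len(n))
  gc <- stats::setNames(seq_len(n), rownames(mat)) # s9 has max GC
  pt <- order_pseudotime(usage_from_matrix(mat), gc_percent = gc,
                         method = "pca", log_transform = FALSE)
  expect_equal(pt$root, "s9")
  times <- stats::setNames(pt$times$pseudotime, pt$times$species_id)
  expect_equal(unname(times[sprintf("s%d", n:1)]),
               seq(0, 1, length.out = n), tolerance = 1e-9)
})

test_that("two species get pseudotimes zero and one", {
  mat <- matrix(c(1, 2, 3, 5), 2, dimnames = list(c("a", "b"), c("x", "y")))
  pt <- order_pseudotime(usage_from_matrix(mat), gc_percent = c(a = 60, b = 40),
                         method = "pca", log_transform = FALSE)
  times <- stats::setNames(pt$times$pseudotime, pt$times$species_id)
  expect_equal(unname(times[c("a", "b")]), c(0, 1))
})

test_that("root ties break deterministically by species id", {
  mat <- matrix(c(1, 2, 3, 1, 5, 9), 3,
                dimnames = list(c("b", "c", "a"), c("x", "y")))
  expect_message(
    pt <- order_pseudotime(usage_from_matrix(mat),
                           gc_percent = c(b = 50, c = 50, a = 40),
                           method = "pca", log_transform = FALSE),
    "tie"
  )
  expect_equal(pt$root, "b")
})

test_that("flipping the root to the far extreme reverses a chain ordering", {
  n <- 12
  mat <- cbind(x = seq_len(n) + 0.01 * rnorm(n), y = rep(0, n))
  rownames(mat) <- sprintf("s%02d", seq_len(n))
  usage <- usage_from_matrix(mat)
  pt1 <- order_pseudotime(usage, root = "diameter", method = "pca",
                          log_transform = FALSE)
  far <- pt1$times$species_id[which.max(pt1$times$pseudotime)]
  pt2 <- order_pseudotime(usage, root = far, method = "pca",
                          log_transform = FALSE)
  m <- dplyr::inner_join(pt1$times, pt2$times, by = "species_id")
  expect_equal(m$pseudotime.y, 1 - m$pseudotime.x, tolerance = 1e-9)

  # slope signs flip, magnitudes and fit quality persist
  set.seed(62)
  aam <- matrix(abs(rnorm(n * 20, 0.05, 0.01)), n,
                dimnames = list(rownames(mat), amino_acids()))
  aam[, "A"] <- 0.05 + 0.02 * m$pseudotime.x[match(rownames(mat), m$species_id)]
  aau <- usage_from_matrix(aam / rowSums(aam))
  tr1 <- fit_trends(aau, pt1)
  tr2 <- fit_trends(aau, pt2)
  expect_equal(tr2$slope, -tr1$slope, tolerance = 1e-9)
  expect_equal(tr2$r_squared, tr1$r_squared, tolerance = 1e-9)
})

test_that("trend fitting is exact on noiseless linear usage", {
  n <- 30
  t <- seq(0, 1, length.out = n)
  ids <- sprintf("s%02d", seq_len(n))
  aam <- matrix(0.05, n, 20, dimnames = list(ids, amino_acids()))
  aam[, "R"] <- 0.08 - 0.03 * t
  aam[, "I"] <- 0.02 + 0.03 * t
  usage <- usage_from_matrix(aam)
  # noiseless fits trigger R's perfect-fit advisory; the point here is exactness
  tr <- suppressWarnings(fit_trends(usage, stats::setNames(t, ids)))
  r_row <- tr[tr$amino_acid == "R", ]
  expect_equal(r_row$r_squared, 1, tolerance = 1e-9)
  expect_equal(r_row$slope, -3, tolerance = 1e-9) # percent scale
  expect_equal(r_row$class, "lost")
  i_row <- tr[tr$amino_acid == "I", ]
  expect_equal(i_row$class, "gained")
  expect_equal(i_row$slope, 3, tolerance = 1e-9)
  # flat columns are neutral
  expect_true(all(tr$class[!tr$amino_acid %in% c("R", "I")] == "neutral"))

  expect_error(fit_trends(usage, stats::setNames(rep(0.5, n), ids)),
               "constant pseudotime")
})

test_that("the full pseudotime pipeline is deterministic and recovers latent time", {
  cu <- small_codon_usage()
  gc <- small_gc()
  pt1 <- order_pseudotime(cu, gc_percent = gc, seed = 7)
  pt2 <- order_pseudotime(cu, gc_percent = gc, seed = 7)
  expect_identical(pt1$times, pt2$times)
  expect_identical(pt1$mst_edges, pt2$mst_edges)

  latent <- small_cohort()$metadata$latent_time
  names(latent) <- small_cohort()$metadata$species_id
  rho <- cor(pt1$times$pseudotime, latent[pt1$times$species_id],
             method = "spearman")
  expect_gt(abs(rho), 0.9)
  # pseudotime of the root is zero; all values within [0, 1]
  expect_equal(pt1$times$pseudotime[pt1$times$species_id == pt1$root], 0)
  expect_true(all(pt1$times$pseudotime >= 0 & pt1$times$pseudotime <= 1))
})

test_that("pseudotime is non-decreasing along every root-to-leaf MST path", {
  cu <- small_codon_usage()
  pt <- order_pseudotime(cu, gc_percent = small_gc(), seed = 7)
  ids <- pt$times$species_id
  g <- igraph::graph_from_data_frame(pt$mst_edges, directed = FALSE,
                                     vertices = ids)
  times <- stats::setNames(pt$times$pseudotime, ids)
  paths <- igraph::shortest_paths(g, from = pt$root, to = ids)$vpath
  for (p in paths) {
    along <- times[names(p)]
    expect_true(all(diff(along) >= -1e-12))
  }
})
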