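#' Default physicochemical block assignment
#'
#' The hydrophobicity/hydrophilicity partition of the 20 amino acids used as
#' ground truth by the property-table simulator: hydrophobic
#' A, C, F, I, L, M, V, W, Y; hydrophilic D, E, G, H, K, N, P, Q, R, S, T.
#'
#' @return Named character vector, amino acid to `"hydrophobic"` or
#'   `"hydrophilic"`.
#' @export
aa_property_blocks <- function() {
  hydrophobic <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
  out <- stats::setNames(rep("hydrophilic", 20), amino_acids())
  out[hydrophobic] <- "hydrophobic"
  out
}

#' Simulate a property table with a planted two-block structure
#'
#' Each amino acid gets a positive latent score; hydrophilic amino acids
#' carry it with flipped sign. Each simulated property is the latent score
#' vector with a random overall sign plus Gaussian noise. With
#' `noise_sd = 0` the Spearman correlation between amino acids is exactly
#' +1 within a block and -1 across blocks, so two-way clustering recovers
#' the planted partition; noise degrades this gradually.
#'
#' @param n_properties Number of properties (columns), at least 2.
#' @param block_assignment Named character vector, amino acid to block label
#'   (exactly two distinct labels, both non-empty).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return A property table tibble (see [read_aaindex1()]), unnormalized.
#' @export
simulate_property_table <- function(n_properties,
                                    block_assignment = aa_property_blocks(),
                                    noise_sd = 0.3,
                                    seed = 1L) {
  if (n_properties < 2) stop("n_properties must be at least 2", call. = FALSE)
  stopifnot(noise_sd >= 0)
  if (!setequal(names(block_assignment), amino_acids())) {
    stop("block_assignment must cover exactly the 20 canonical amino acids",
         call. = FALSE)
  }
  blocks <- unique(block_assignment)
  if (length(blocks) != 2) {
    stop("block_assignment must define exactly two non-empty blocks", call. = FALSE)
  }
  block_assignment <- block_assignment[amino_acids()]
  with_local_seed(seed, {
    score <- stats::runif(20, 0.5, 1.5)
    latent <- ifelse(block_assignment == blocks[1], score, -score)
    sign_p <- sample(c(-1, 1), n_properties, replace = TRUE)
    vals <- outer(latent, sign_p) +
      matrix(stats::rnorm(20 * n_properties, 0, noise_sd), nrow = 20)
    colnames(vals) <- sprintf("SIM%04d", seq_len(n_properties))
    rownames(vals) <- amino_acids()
    out <- as_property_table(vals)
    attr(out, "block_assignment") <- block_assignment
    out
  })
}
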