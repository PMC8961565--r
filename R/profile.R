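# coerce input to a DNAStringSet-compatible character vector
as_dna_chars <- function(x) {
  if (inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("expected character sequences or an XStringSet",
                             call. = FALSE)
  if (length(x) == 0) stop("no sequences supplied", call. = FALSE)
  normalize_dna(x)
}

#' Codon usage profile of one species
#'
#' Tallies in-frame codons over a species' coding sequences: each CDS is
#' read from position 1 in steps of three, the trailing partial codon is
#' dropped, and codons containing any character outside A/C/G/T (ambiguity
#' codes N, R, Y, H, ...) are excluded from both the counts and the total.
#' Stop codons are counted: frequencies are relative to the total over all
#' 64 codons, so the 64 frequencies sum to 1 and the 61 sense-codon
#' frequencies to 1 minus the stop fraction.
#'
#' @param cds Character vector (or `DNAStringSet`) of coding sequences; U is
#'   read as T.
#' @param species_id Optional species label stored in the result.
#' @return A tibble with one row per codon (64 rows): `codon`, `aa`,
#'   `is_stop`, `count`, `frequency`; attributes `n_total` (codon total
#'   including stops) and `species_id`.
#' @export
#' @examples
#' profile_codons("ATGTAA") # ATG and TAA each at frequency 0.5
profile_codons <- function(cds, species_id = NULL) {
  seqs <- as_dna_chars(cds)
  counts <- codon_counts(seqs)
  n_total <- sum(counts)
  if (n_total == 0) {
    stop("no valid codons in any CDS: frequencies are undefined", call. = FALSE)
  }
  code <- genetic_code()
  out <- tibble::tibble(
    codon = code$codon,
    aa = code$aa,
    is_stop = code$is_stop,
    count = as.integer(counts[code$codon]),
    frequency = unname(counts[code$codon]) / n_total
  )
  attr(out, "n_total") <- n_total
  attr(out, "species_id") <- species_id
  # QC: CDSs profiled with 1-2 trailing bases dropped
  attr(out, "n_partial_cds") <- sum(nchar(seqs) %% 3 != 0)
  out
}

# named 64-vector of in-frame codon counts, ambiguous codons excluded
codon_counts <- function(seqs) {
  set <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(set, width = 3, step = 3)
  colSums(m)
}

#' Amino-acid usage profile of one species
#'
#' Counts residues over a species' protein sequences (or over translated
#' CDS via [translate_cds()]). Non-canonical residues (U, O, X, B, Z, J and
#' `*`) contribute to neither the per-amino-acid counts nor the total, so
#' the 20 frequencies always sum to 1.
#'
#' @param proteins Character vector (or `AAStringSet`) of protein sequences.
#' @param species_id Optional species label stored in the result.
#' @return A tibble with one row per amino acid (20 rows): `amino_acid`,
#'   `count`, `frequency`; attributes `n_total` and `species_id`.
#' @export
#' @examples
#' profile_amino_acids("ACDEFGHIKLMNPQRSTVWY") # uniform 0.05
profile_amino_acids <- function(proteins, species_id = NULL) {
  if (inherits(proteins, "XStringSet")) proteins <- as.character(proteins)
  if (!is.character(proteins) || length(proteins) == 0) {
    stop("no protein sequences supplied", call. = FALSE)
  }
  set <- Biostrings::AAStringSet(toupper(proteins))
  m <- Biostrings::letterFrequency(set, letters = amino_acids())
  counts <- colSums(m)
  n_total <- sum(counts)
  if (n_total == 0) {
    stop("all residues are non-canonical: usage is undefined", call. = FALSE)
  }
  out <- tibble::tibble(
    amino_acid = amino_acids(),
    count = as.integer(counts),
    frequency = unname(counts) / n_total
  )
  attr(out, "n_total") <- n_total
  attr(out, "species_id") <- species_id
  out
}

#' GC content of a set of coding sequences
#'
#' 100 * (G + C) / (A + C + G + T) over the concatenated sequences;
#' ambiguity characters count in neither numerator nor denominator.
#'
#' @inheritParams profile_codons
#' @return GC percentage in \[0, 100\].
#' @export
#' @examples
#' gc_content("ATGC") # 50
gc_content <- function(cds) {
  seqs <- as_dna_chars(cds)
  set <- Biostrings::DNAStringSet(seqs)
  counts <- colSums(Biostrings::letterFrequency(set, letters = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) stop("no unambiguous bases: GC content undefined", call. = FALSE)
  100 * sum(counts[c("C", "G")]) / denom
}

#' Species-by-feature usage matrix for a cohort
#'
#' Profiles every species of a cohort and assembles the wide usage table
#' that feeds correlation, clustering, trees and pseudotime: one row per
#' species, one numeric frequency column per feature. Codon usage includes
#' the three stop codons (64 columns); amino-acid usage uses the protein
#' sequences when the cohort has them, else the translated CDS.
#'
#' @param cohort A `species_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param features `"codon"` or `"aa"`.
#' @return A tibble: `species_id` plus 64 codon columns or 20 amino-acid
#'   columns of frequencies.
#' @export
cohort_usage <- function(cohort, features = c("codon", "aa")) {
  stopifnot(inherits(cohort, "species_cohort"))
  features <- match.arg(features)
  ids <- cohort$metadata$species_id
  if (features == "codon") {
    rows <- purrr::map(ids, function(id) {
      p <- profile_codons(cohort$cds[[id]], species_id = id)
      stats::setNames(p$frequency, p$codon)
    })
  } else {
    use_protein <- !is.null(cohort$protein)
    rows <- purrr::map(ids, function(id) {
      seqs <- if (use_protein) cohort$protein[[id]] else
        translate_cds(cohort$cds[[id]])
      p <- profile_amino_acids(seqs, species_id = id)
      stats::setNames(p$frequency, p$amino_acid)
    })
  }
  out <- dplyr::bind_cols(
    tibble::tibble(species_id = ids),
    tibble::as_tibble(do.call(rbind, rows))
  )
  if (features == "aa") {
    attr(out, "source") <- if (!is.null(cohort$protein)) "protein_fasta"
    else "translated_cds"
  }
  out
}

# wide usage tibble -> numeric matrix with species rownames
usage_matrix <- function(usage) {
  stopifnot("species_id" %in% names(usage))
  m <- as.matrix(usage[, setdiff(names(usage), "species_id"), drop = FALSE])
  rownames(m) <- usage$species_id
  storage.mode(m) <- "double"
  m
}
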