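#' The standard genetic code as a tibble
#'
#' Returns the genetic code as a codon-level table: one row per codon with the
#' encoded amino acid (one-letter code, `"*"` for stop). The standard code
#' (translation table 1) is the default for every analysis in this package;
#' other NCBI translation tables can be requested by id.
#'
#' @param table_id NCBI genetic-code table id as a character scalar
#'   (default `"1"`, the standard code).
#'
#' @return A tibble with columns `codon` (64 DNA triplets, uppercase, T not
#'   U), `aa` (one-letter amino acid or `"*"`), and `is_stop`.
#' @export
#' @examples
#' genetic_code()
genetic_code <- function(table_id = "1") {
  gc <- Biostrings::getGeneticCode(table_id)
  tibble::tibble(
    codon = names(gc),
    aa = unname(gc),
    is_stop = unname(gc) == "*"
  )
}

#' The twenty canonical amino acids, alphabetical one-letter codes
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' The 64 codons in lexicographic order
#' @return Character vector of length 64.
#' @export
codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
}

#' Stop codons of the standard code
#' @return Character vector `c("TAA","TAG","TGA")`.
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

# codon -> aa named vector, cached per table id
codon_map <- function(table_id = "1") {
  code <- genetic_code(table_id)
  stats::setNames(code$aa, code$codon)
}

#' Codon degeneracy of an amino acid
#'
#' Number of sense codons encoding each amino acid under the standard genetic
#' code: 1 for M and W, up to 6 for L, R and S; the 20 counts sum to 61.
#'
#' @param aa One-letter amino-acid codes (character vector). If `NULL`,
#'   returns the full named vector over all 20 amino acids.
#' @param table_id Genetic-code table id, see [genetic_code()].
#'
#' @return Integer vector of codon counts, named by amino acid.
#' @export
#' @examples
#' degeneracy("R") # 6
#' degeneracy()    # all 20, sums to 61
degeneracy <- function(aa = NULL, table_id = "1") {
  code <- genetic_code(table_id)
  counts <- table(factor(code$aa[!code$is_stop], levels = amino_acids()))
  full <- stats::setNames(as.integer(counts), amino_acids())
  if (is.null(aa)) return(full)
  bad <- setdiff(aa, amino_acids())
  if (length(bad) > 0) {
    stop("unknown amino acid letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full[aa]
}

#' Theoretical amino-acid usage from codon multiplicity
#'
#' The usage each amino acid would have if all 61 sense codons were used
#' uniformly: the codon count divided by 61. Arginine, with six codons, gets
#' 6/61 (about 9.8%); tryptophan 1/61. The 20 values form a probability
#' distribution.
#'
#' @inheritParams degeneracy
#' @return Numeric vector of theoretical frequencies, named by amino acid.
#' @export
#' @examples
#' theoretical_usage("R") * 100 # ~9.8
#' sum(theoretical_usage())     # 1
theoretical_usage <- function(aa = NULL, table_id = "1") {
  degeneracy(aa, table_id) / 61
}

#' Translate a coding sequence
#'
#' Frame-0 translation with this package's profiling semantics: the trailing
#' partial codon is ignored, a stop codon terminates translation, and codons
#' containing characters outside A/C/G/T (ambiguity codes such as N, R, Y, H)
#' emit no residue and translation continues. U is accepted and read as T;
#' lowercase input is accepted.
#'
#' @param cds A single DNA string (or a character vector, translated
#'   element-wise).
#' @param table_id Genetic-code table id, see [genetic_code()].
#'
#' @return Character vector of protein strings, same length as `cds`.
#' @export
#' @examples
#' translate_cds("ATGGCT")    # "MA"
#' translate_cds("ATGTAAGCT") # "M": stop terminates
translate_cds <- function(cds, table_id = "1") {
  if (length(cds) == 0) stop("empty input: no sequences to translate", call. = FALSE)
  map <- codon_map(table_id)
  vapply(cds, function(s) {
    if (is.na(s) || nchar(s) == 0) stop("empty input sequence", call. = FALSE)
    s <- normalize_dna(s)
    n_cod <- nchar(s) %/% 3
    if (n_cod == 0) return("")
    starts <- seq(1, by = 3, length.out = n_cod)
    cod <- substring(s, starts, starts + 2)
    aa <- unname(map[cod]) # NA for ambiguous codons
    stop_at <- which(!is.na(aa) & aa == "*")
    if (length(stop_at) > 0) aa <- aa[seq_len(stop_at[1] - 1)]
    paste(aa[!is.na(aa)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# uppercase, RNA -> DNA
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}
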