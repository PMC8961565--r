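#' Read coding sequences from a (multi-)FASTA file
#'
#' Reads a CDS multi-FASTA (plain or gzip-compressed), uppercases the
#' sequences and maps U to T so downstream codon profiling sees a pure DNA
#' alphabet. Ambiguity characters (N, R, Y, H, ...) are kept; they are
#' excluded at codon granularity by [profile_codons()].
#'
#' @param path Path to a FASTA file, optionally `.gz`.
#' @return Named character vector of DNA sequences (names from FASTA headers).
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("FASTA parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- normalize_dna(as.character(set))
  stats::setNames(seqs, names(set))
}

#' Read protein sequences from a (multi-)FASTA file
#'
#' All records are returned, including any isoforms present in the file;
#' [profile_amino_acids()] counts every record it is given.
#'
#' @inheritParams read_cds_fasta
#' @return Named character vector of protein sequences (uppercase).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("FASTA parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), length(seqs) > 0)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
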