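#' Reference GC-stratified codon usage summary
#'
#' The packaged reference table of codon usage stratified by GC content, as
#' printed by a published genome-wide survey across the three domains of
#' life: per codon, the mean and standard deviation of usage (percent, stop
#' codons included) among species with GC < 45% and GC >= 45%, and the
#' printed fold change. Used as worked-example input for [fold_change()]
#' and in regression tests.
#'
#' @return A tibble with columns `codon`, `aa`, `mean_lt45`, `sd_lt45`,
#'   `mean_ge45`, `sd_ge45`, `fc_printed`.
#' @export
reference_codon_strata <- function() {
  path <- system.file("extdata", "codon_usage_strata_reference.tsv",
                      package = "aarecruit", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(
                    codon = "c", aa = "c", .default = "d"
                  ))
}
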