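# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small cohort for unit tests: fast but structured
small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(cohort_spec(
      n_species = c(Bacteria = 16, Archaea = 4, Eukaryota = 4),
      n_genes = 40, seed = 42
    ))
  })
}

small_codon_usage <- function() {
  fixture("small_codon_usage", function() cohort_usage(small_cohort(), "codon"))
}

small_aa_usage <- function() {
  fixture("small_aa_usage", function() cohort_usage(small_cohort(), "aa"))
}

small_gc <- function() {
  m <- small_cohort()$metadata
  stats::setNames(m$gc_percent, m$species_id)
}

# full-size cohort at the default study conditions (shared with acceptance)
default_cohort <- function() {
  fixture("default_cohort", function() simulate_cohort(cohort_spec()))
}

default_codon_usage <- function() {
  fixture("default_codon_usage", function() cohort_usage(default_cohort(), "codon"))
}

default_aa_usage <- function() {
  fixture("default_aa_usage", function() cohort_usage(default_cohort(), "aa"))
}

default_gc <- function() {
  m <- default_cohort()$metadata
  stats::setNames(m$gc_percent, m$species_id)
}

aaindex_fixture_path <- function() {
  system.file("extdata", "aaindex1_sample.txt", package = "aarecruit",
              mustWork = TRUE)
}
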