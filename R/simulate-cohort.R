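# Typical across-species proteome composition used as the default base
# amino-acid frequency vector of the generator (values in fractions,
# renormalized at build time).
typical_proteome_freq <- function() {
  f <- c(A = 8.3, C = 1.4, D = 5.4, E = 6.2, F = 3.9, G = 7.1, H = 2.2,
         I = 5.9, K = 5.3, L = 9.7, M = 2.4, N = 4.0, P = 4.7, Q = 4.0,
         R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)
  f / sum(f)
}

# Planted usage-vs-time slopes (fraction per unit latent time). Losses and
# gains balance to zero so renormalization plants no spurious trend on the
# neutral amino acids.
default_trend_slopes <- function() {
  c(A = -0.015, G = -0.015, P = -0.015, R = -0.015, V = -0.015, W = -0.008,
    F = 0.018, I = 0.017, K = 0.018, N = 0.016, Y = 0.014)
}

#' Specify a synthetic species cohort
#'
#' Defines the ground truth for [simulate_cohort()]: a cohort of species with
#' a latent evolution-time coordinate on \[0, 1\], codon usage whose
#' G/C-ending mass drifts logistically along that coordinate, and designated
#' amino acids with planted linear usage trends of a controlled fit quality.
#'
#' Defaults describe the study conditions the package's recovery tests run
#' under: 60 species (40 Bacteria, 10 Archaea, 10 Eukaryota, assigned in
#' blocks along latent time so Bacteria are earliest), 200 genes per species
#' with log-normal lengths clipped to \[100, 1000\] codons, `gc_drift = -4`
#' (GC content declines along evolution time, so the earliest species have
#' the highest GC), and planted loss trends on A, G, P, R, V, W and gain
#' trends on F, I, K, N, Y with a target R-squared of 0.8.
#'
#' @param n_species Named integer vector of species counts per domain.
#' @param latent_time `"even"` for evenly spaced times on \[0, 1\], or a
#'   numeric vector of length `sum(n_species)`.
#' @param gc_drift Slope of the logit of G/C-ending codon mass versus latent
#'   time; negative means GC falls along evolution time.
#' @param trend_slopes Named numeric vector, amino acid to slope of usage
#'   (fraction) versus latent time.
#' @param r2_target Target R-squared of each planted trend, achieved by
#'   per-species Gaussian jitter on the target frequency.
#' @param base_freq Base amino-acid frequency vector (named, 20 entries;
#'   renormalized).
#' @param n_genes Genes per species.
#' @param length_meanlog,length_sdlog Log-normal gene-length parameters
#'   (codons); lengths are clipped to \[100, 1000\].
#' @param seed Integer seed; fully determines the generated cohort.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_species = c(Bacteria = 40, Archaea = 10, Eukaryota = 10),
                        latent_time = "even",
                        gc_drift = -4,
                        trend_slopes = default_trend_slopes(),
                        r2_target = 0.8,
                        base_freq = typical_proteome_freq(),
                        n_genes = 200,
                        length_meanlog = log(300),
                        length_sdlog = 0.45,
                        seed = 1L) {
  stopifnot(length(n_species) >= 1, !is.null(names(n_species)),
            all(n_species >= 1), n_genes >= 1, r2_target > 0, r2_target < 1)
  n_total <- sum(n_species)
  if (identical(latent_time, "even")) {
    latent_time <- if (n_total == 1) 0.5 else seq(0, 1, length.out = n_total)
  }
  stopifnot(is.numeric(latent_time), length(latent_time) == n_total,
            all(latent_time >= 0 & latent_time <= 1))
  if (!setequal(names(base_freq), amino_acids())) {
    stop("base_freq must be named by the 20 canonical amino acids", call. = FALSE)
  }
  base_freq <- base_freq[amino_acids()] / sum(base_freq)
  if (length(trend_slopes) > 0) {
    bad <- setdiff(names(trend_slopes), amino_acids())
    if (length(bad) > 0) {
      stop("trend_slopes names must be amino acids; unknown: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lo <- base_freq[names(trend_slopes)] + pmin(0, trend_slopes)
    if (any(lo <= 0)) {
      stop("invalid trend: planted frequency would be <= 0 at some t in [0,1] for ",
           paste(names(trend_slopes)[lo <= 0], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_species = n_species, latent_time = latent_time, gc_drift = gc_drift,
         trend_slopes = trend_slopes, r2_target = r2_target,
         base_freq = base_freq, n_genes = n_genes,
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# per-amino-acid (and stop) codon index sets split by G/C- vs A/T-ending
codon_ending_sets <- function() {
  code <- genetic_code()
  third <- substr(code$codon, 3, 3)
  gc_end <- third %in% c("G", "C")
  split_sets <- function(letters) {
    lapply(letters, function(a) {
      i <- which(code$aa == a)
      list(gc = i[gc_end[i]], at = i[!gc_end[i]])
    })
  }
  stats::setNames(split_sets(c(amino_acids(), "*")), c(amino_acids(), "*"))
}

#' Simulate a synthetic species cohort
#'
#' Generates, per species, an amino-acid sequence sampled from its planted
#' target frequency vector (base frequencies plus trend slope times latent
#' time, jittered to hit the planted R-squared, renormalized), then picks a
#' synonymous codon for each residue: the G/C-ending codon mass follows
#' `plogis(gc_drift * (t - 0.5))`, uniform within the G/C-ending and
#' A/T-ending subsets. Each gene ends with one stop codon, which is part of
#' the CDS and counted by the codon profiler. The protein sequences are the
#' residue-for-residue translation of the CDS.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `species_cohort`: a list with
#'   * `metadata`: tibble with `species_id`, `name`, `domain`, `phylum`,
#'     `gc_percent` (realized GC of the generated CDS) and the ground-truth
#'     `latent_time`;
#'   * `cds`, `protein`: named lists (by species) of per-gene sequence
#'     vectors;
#'   * `spec`: the input spec.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(spec$n_species)
  domains <- rep(names(spec$n_species), spec$n_species)
  ord <- order(spec$latent_time)
  t_sorted <- spec$latent_time[ord]
  ids <- sprintf("sp%03d", seq_len(n_total))
  sets <- codon_ending_sets()
  cod <- genetic_code()$codon # order matches the indices in `sets`
  cod_gc_frac <- (stringr::str_count(cod, "G") + stringr::str_count(cod, "C"))
  trend_aa <- names(spec$trend_slopes)
  var_t <- if (n_total > 1) stats::var(t_sorted) else 0
  jitter_sd <- abs(spec$trend_slopes) *
    sqrt(var_t * (1 - spec$r2_target) / spec$r2_target)

  with_local_seed(spec$seed, {
    cds <- vector("list", n_total)
    protein <- vector("list", n_total)
    gc_pct <- numeric(n_total)
    for (s in seq_len(n_total)) {
      t <- t_sorted[s]
      f <- spec$base_freq
      if (length(trend_aa) > 0) {
        f[trend_aa] <- f[trend_aa] + spec$trend_slopes * t +
          stats::rnorm(length(trend_aa), 0, jitter_sd)
        f <- pmax(f, 1e-4)
      }
      f <- f / sum(f)
      lens <- pmin(pmax(round(stats::rlnorm(spec$n_genes, spec$length_meanlog,
                                            spec$length_sdlog)), 100L), 1000L)
      n_res <- sum(lens)
      aa_idx <- sample.int(20L, n_res, replace = TRUE, prob = f)
      gcmass <- stats::plogis(spec$gc_drift * (t - 0.5))
      codon_id <- integer(n_res)
      use_gc <- stats::runif(n_res) < gcmass
      for (a in unique(aa_idx)) {
        set <- sets[[amino_acids()[a]]]
        i <- which(aa_idx == a)
        pick_gc <- if (length(set$gc) == 0) rep(FALSE, length(i)) else
          if (length(set$at) == 0) rep(TRUE, length(i)) else use_gc[i]
        if (any(pick_gc)) {
          codon_id[i[pick_gc]] <- set$gc[sample.int(length(set$gc),
                                                    sum(pick_gc), replace = TRUE)]
        }
        if (any(!pick_gc)) {
          codon_id[i[!pick_gc]] <- set$at[sample.int(length(set$at),
                                                     sum(!pick_gc), replace = TRUE)]
        }
      }
      stop_set <- sets[["*"]]
      stop_gc <- stats::runif(spec$n_genes) < gcmass
      stop_id <- ifelse(stop_gc,
                        stop_set$gc[sample.int(length(stop_set$gc), spec$n_genes,
                                               replace = TRUE)],
                        stop_set$at[sample.int(length(stop_set$at), spec$n_genes,
                                               replace = TRUE)])
      gene_of <- rep.int(seq_len(spec$n_genes), lens)
      cds_genes <- vapply(split(cod[codon_id], gene_of), paste0, character(1),
                          collapse = "")
      cds_genes <- paste0(cds_genes, cod[stop_id])
      prot_genes <- vapply(split(amino_acids()[aa_idx], gene_of), paste0,
                           character(1), collapse = "")
      names(cds_genes) <- names(prot_genes) <-
        sprintf("%s_gene%04d", ids[s], seq_len(spec$n_genes))
      cds[[s]] <- cds_genes
      protein[[s]] <- prot_genes
      all_id <- c(codon_id, stop_id)
      gc_pct[s] <- 100 * sum(tabulate(all_id, 64) * cod_gc_frac) /
        (3 * length(all_id))
    }
    names(cds) <- names(protein) <- ids
    phyla <- paste0(domains, "_phylum_", (seq_len(n_total) %% 2) + 1)
    metadata <- tibble::tibble(
      species_id = ids,
      name = paste0("Synthetic species ", seq_len(n_total)),
      domain = domains,
      phylum = phyla,
      gc_percent = gc_pct,
      latent_time = t_sorted
    )
    structure(list(metadata = metadata, cds = cds, protein = protein,
                   spec = spec),
              class = "species_cohort")
  })
}

#' @export
print.species_cohort <- function(x, ...) {
  cat("<species_cohort> ", nrow(x$metadata), " species, ",
      x$spec$n_genes, " genes/species\n", sep = "")
  print(dplyr::count(x$metadata, .data$domain))
  invisible(x)
}

#' Write a cohort to disk in the formats the readers consume
#'
#' Emits one CDS FASTA and one protein FASTA per species plus a
#' `metadata.tsv` in the simplified dialect, with `cds_path` /
#' `protein_path` columns pointing at the sequence files.
#'
#' @param cohort A `species_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param compress Write gzip-compressed FASTA files.
#' @return The metadata file path, invisibly.
#' @export
write_cohort <- function(cohort, dir, compress = FALSE) {
  stopifnot(inherits(cohort, "species_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".gz" else ""
  meta <- cohort$metadata
  meta$cds_path <- paste0(meta$species_id, "_cds.fna", ext)
  meta$protein_path <- paste0(meta$species_id, "_protein.faa", ext)
  for (i in seq_len(nrow(meta))) {
    id <- meta$species_id[i]
    write_fasta(cohort$cds[[id]], file.path(dir, meta$cds_path[i]))
    write_fasta(cohort$protein[[id]], file.path(dir, meta$protein_path[i]))
  }
  path <- file.path(dir, "metadata.tsv")
  write_species_metadata(meta, path)
  invisible(path)
}

#' Read a cohort from a metadata table and sequence files
#'
#' @param metadata_path Path to a metadata TSV whose rows carry `cds_path`
#'   and (optionally) `protein_path` columns, relative to the metadata file.
#' @return A `species_cohort` (with `latent_time` absent unless the metadata
#'   provides it).
#' @export
read_cohort <- function(metadata_path) {
  meta <- read_species_metadata(metadata_path)
  if (!"cds_path" %in% names(meta)) {
    stop("metadata has no cds_path column; cannot locate sequences", call. = FALSE)
  }
  base <- dirname(metadata_path)
  cds <- lapply(file.path(base, meta$cds_path), read_cds_fasta)
  names(cds) <- meta$species_id
  protein <- NULL
  if ("protein_path" %in% names(meta) && !anyNA(meta$protein_path)) {
    protein <- lapply(file.path(base, meta$protein_path), read_protein_fasta)
    names(protein) <- meta$species_id
  }
  if ("latent_time" %in% names(meta)) {
    meta$latent_time <- as.numeric(meta$latent_time)
  }
  structure(list(metadata = meta, cds = cds, protein = protein, spec = NULL),
            class = "species_cohort")
}
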