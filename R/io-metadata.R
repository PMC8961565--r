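#' Read a species metadata table
#'
#' Reads a tab-delimited species table in either of two dialects, detected
#' from the header row:
#'
#' * the simplified five-column schema `species_id`, `name`, `domain`,
#'   `phylum`, `gc_percent` (extra columns such as `cds_path` /
#'   `protein_path` are carried through);
#' * the NCBI genome-reports style, where `#Organism/Name` (or
#'   `Organism Name`) supplies the name, `Kingdom` or `Group` the domain,
#'   `SubGroup` the phylum and `GC%` the GC content.
#'
#' Domain and phylum strings are whitespace-trimmed; domains are normalized
#' to `Bacteria`, `Archaea` or `Eukaryota` case-insensitively. Rows whose GC
#' value does not parse as a number in \[0, 100\] are dropped with a warning:
#' downstream stratification and pseudotime rooting need a usable GC.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with columns `species_id`, `name`, `domain`, `phylum`,
#'   `gc_percent`, plus any extra columns from the simplified dialect.
#' @export
read_species_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) stop("metadata file has no rows: ", path, call. = FALSE)
  nm <- names(raw)
  pick <- function(cands) {
    hit <- nm[tolower(nm) %in% tolower(cands)]
    if (length(hit) > 0) hit[[1]] else NULL
  }
  name_col <- pick(c("name", "#Organism/Name", "Organism/Name", "Organism Name"))
  dom_col <- pick(c("domain", "Kingdom", "Group"))
  gc_col <- pick(c("gc_percent", "GC%"))
  phy_col <- pick(c("phylum", "SubGroup"))
  id_col <- pick(c("species_id", "assembly_accession", "Assembly Accession"))
  missing <- c(name = is.null(name_col), domain = is.null(dom_col),
               gc = is.null(gc_col))
  if (any(missing)) {
    stop("metadata schema error: no column found for ",
         paste(names(missing)[missing], collapse = ", "),
         " (header: ", paste(nm, collapse = ", "), ")", call. = FALSE)
  }
  out <- tibble::tibble(
    species_id = if (!is.null(id_col)) str_squish(raw[[id_col]]) else
      make.unique(gsub("[^A-Za-z0-9]+", "_", str_squish(raw[[name_col]]))),
    name = str_squish(raw[[name_col]]),
    domain = normalize_domain(raw[[dom_col]]),
    phylum = if (!is.null(phy_col)) str_squish(raw[[phy_col]]) else NA_character_,
    gc_percent = suppressWarnings(as.numeric(str_squish(raw[[gc_col]])))
  )
  extra <- setdiff(nm, c(id_col, name_col, dom_col, phy_col, gc_col))
  for (e in extra) out[[e]] <- raw[[e]]
  bad_gc <- is.na(out$gc_percent) | out$gc_percent < 0 | out$gc_percent > 100
  if (any(bad_gc)) {
    warning(sum(bad_gc), " row(s) dropped: unparseable or out-of-range GC% (",
            paste(utils::head(out$name[bad_gc], 5), collapse = ", "), ")",
            call. = FALSE)
    out <- out[!bad_gc, , drop = FALSE]
  }
  if (nrow(out) == 0) stop("no usable metadata rows in ", path, call. = FALSE)
  if (anyDuplicated(out$species_id)) {
    stop("duplicate species_id in metadata: ",
         paste(unique(out$species_id[duplicated(out$species_id)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write a species metadata table (simplified dialect)
#'
#' @param metadata A tibble as returned by [read_species_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

str_squish <- function(x) stringr::str_squish(as.character(x))

normalize_domain <- function(x) {
  x <- str_squish(x)
  key <- tolower(x)
  out <- dplyr::case_when(
    key %in% c("bacteria", "eubacteria") ~ "Bacteria",
    key == "archaea" ~ "Archaea",
    key %in% c("eukaryota", "eukaryote", "eukaryotes", "eukarya") ~ "Eukaryota",
    TRUE ~ x
  )
  out
}
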