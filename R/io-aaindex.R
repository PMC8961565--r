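# AAindex1 amino-acid order: first numeric line A R N D C Q E G H I,
# second line L K M F P S T W Y V.
aaindex1_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Read an AAindex1 flat file into a property table
#'
#' Parses the AAindex1 flat-file format: entries introduced by an `H`
#' (accession) line, with the numeric values in the `I` block as two
#' ten-value lines in the canonical A/R/N/D/C/Q/E/G/H/I then
#' L/K/M/F/P/S/T/W/Y/V order. Properties with any `NA` value are dropped
#' with a message, so the returned matrix is complete.
#'
#' @param path Path to an AAindex1 flat file.
#' @return A property table: tibble with column `amino_acid` (20 rows,
#'   alphabetical) and one numeric column per retained property, accession as
#'   column name. Attribute `normalized` is `FALSE`; see
#'   [normalize_properties()].
#' @export
read_aaindex1 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  h_idx <- grep("^H ", lines)
  if (length(h_idx) == 0) {
    stop("no AAindex1 entries (no 'H' lines) in ", path, call. = FALSE)
  }
  cols <- list()
  dropped <- character(0)
  for (h in h_idx) {
    acc <- str_squish(sub("^H ", "", lines[h]))
    i_rel <- grep("^I ", lines[h:length(lines)])[1]
    if (is.na(i_rel)) {
      stop("AAindex1 parse error: entry ", acc, " has no I block", call. = FALSE)
    }
    i_idx <- h + i_rel - 1L
    if (i_idx + 2L > length(lines)) {
      stop("AAindex1 parse error: truncated I block in entry ", acc, call. = FALSE)
    }
    vals <- unlist(lapply(lines[i_idx + 1:2], function(l) {
      strsplit(str_squish(l), " ")[[1]]
    }))
    if (length(vals) != 20) {
      stop("AAindex1 parse error: entry ", acc, " has ", length(vals),
           " values in its I block (expected 20)", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(vals))
    num[vals %in% c("NA", "NA.")] <- NA_real_
    if (anyNA(num)) {
      dropped <- c(dropped, acc)
      next
    }
    cols[[acc]] <- stats::setNames(num, aaindex1_order())[amino_acids()]
  }
  if (length(dropped) > 0) {
    message("dropped ", length(dropped),
            " propert", if (length(dropped) == 1) "y" else "ies",
            " with missing values: ", paste(dropped, collapse = ", "))
  }
  if (length(cols) == 0) {
    stop("no complete properties in ", path, call. = FALSE)
  }
  out <- tibble::as_tibble(cols)
  out <- dplyr::bind_cols(tibble::tibble(amino_acid = amino_acids()), out)
  attr(out, "normalized") <- FALSE
  out
}

#' Build a property table from a plain 20 x P matrix
#'
#' @param values Numeric matrix, 20 rows named by the one-letter amino-acid
#'   codes, one column per property.
#' @return A property table tibble (see [read_aaindex1()]).
#' @export
as_property_table <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (!setequal(rownames(values), amino_acids())) {
    stop("property matrix must have exactly the 20 canonical amino-acid rows",
         call. = FALSE)
  }
  values <- values[amino_acids(), , drop = FALSE]
  out <- dplyr::bind_cols(
    tibble::tibble(amino_acid = amino_acids()),
    tibble::as_tibble(values)
  )
  attr(out, "normalized") <- FALSE
  out
}

#' Z-score normalize a property table
#'
#' Centers and scales each property column to mean 0, standard deviation 1
#' (sample sd), the normalization applied before property correlation.
#' Constant columns cannot be scaled and are dropped with a message.
#'
#' @param props A property table from [read_aaindex1()],
#'   [as_property_table()] or [simulate_property_table()].
#' @return The property table with normalized columns and attribute
#'   `normalized = TRUE`.
#' @export
normalize_properties <- function(props) {
  mat <- property_matrix(props)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropped ", sum(sds == 0), " constant propert",
            if (sum(sds == 0) == 1) "y" else "ies", ": ",
            paste(colnames(mat)[sds == 0], collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (ncol(mat) == 0) stop("no non-constant properties to normalize", call. = FALSE)
  z <- scale(mat)
  out <- dplyr::bind_cols(
    tibble::tibble(amino_acid = rownames(mat)),
    tibble::as_tibble(z)
  )
  attr(out, "normalized") <- TRUE
  out
}

# tibble property table -> 20 x P matrix with aa rownames
property_matrix <- function(props) {
  stopifnot("amino_acid" %in% names(props))
  mat <- as.matrix(props[, setdiff(names(props), "amino_acid"), drop = FALSE])
  rownames(mat) <- props$amino_acid
  storage.mode(mat) <- "double"
  mat
}

is_normalized <- function(props) isTRUE(attr(props, "normalized"))
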