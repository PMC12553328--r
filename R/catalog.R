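#' Protein catalog
#'
#' An ordered list of unique protein identifiers, optionally annotated with
#' sequence lengths. Catalog order is stable and defines block assignment:
#' `block_partition()` slices the catalog contiguously in this order.
#'
#' @param ids Character vector of unique protein identifiers.
#' @param lengths Optional positive integer residue counts, same order as
#'   `ids`.
#' @return An object of class `protein_catalog`.
#' @seealso [read_catalog()], [block_partition()]
#' @export
protein_catalog <- function(ids, lengths = NULL) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("catalog must contain at least one protein",
                              call. = FALSE)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("catalog ids must be non-missing, non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein ids in catalog: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(lengths)) {
    if (length(lengths) != length(ids)) {
      stop("`lengths` must match `ids` in length", call. = FALSE)
    }
    lengths <- as.integer(lengths)
    if (anyNA(lengths) || any(lengths < 1L)) {
      stop("protein lengths must be positive integers", call. = FALSE)
    }
  }
  structure(list(ids = ids, lengths = lengths),
            class = "protein_catalog")
}

#' @export
length.protein_catalog <- function(x) length(x$ids)

#' @export
print.protein_catalog <- function(x, ...) {
  cat(sprintf("<protein_catalog> %d proteins", length(x)))
  if (!is.null(x$lengths)) {
    cat(sprintf("; lengths %d-%d aa", min(x$lengths), max(x$lengths)))
  }
  cat("\n")
  invisible(x)
}

#' Read a protein catalog from disk
#'
#' Accepts either a plain-text list (one identifier per line, blank lines and
#' `#` comments ignored) or a FASTA file. For FASTA input the identifier is
#' the first whitespace-delimited token of each header, sequence lengths are
#' recorded, and proteins longer than `max_length` residues are dropped —
#' the standard pre-filter for embedding-based PPI inference, whose models
#' cap input length.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"ids"` or `"fasta"`.
#' @param max_length Maximum protein length kept from FASTA input, in amino
#'   acids. Default 1000.
#' @return A [protein_catalog()].
#' @export
read_catalog <- function(path, format = c("auto", "ids", "fasta"),
                         max_length = 1000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa")) "fasta" else "ids"
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA catalogs requires the Biostrings package",
           call. = FALSE)
    }
    seqs <- Biostrings::readAAStringSet(path)
    ids <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1L)
    keep <- Biostrings::width(seqs) <= max_length
    if (!any(keep)) stop("no proteins pass the length filter", call. = FALSE)
    protein_catalog(ids[keep], Biostrings::width(seqs)[keep])
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    protein_catalog(lines)
  }
}

#' Write a catalog as a plain-text id list
#'
#' @param catalog A [protein_catalog()].
#' @param path Destination file, one id per line.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "protein_catalog"))
  writeLines(catalog$ids, path)
  invisible(path)
}
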