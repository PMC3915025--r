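#' Aligned sequence sets
#'
#' An `aln` object holds an aligned set of nucleotide sequences: a named
#' character vector of equal-length residue strings plus the common column
#' count. Residues are uppercased on ingest, `U` is normalized to `T`, and
#' `.` is normalized to the gap character `-`. IUPAC ambiguity codes are
#' retained; downstream distance and G+C computations treat them as missing.
#'
#' @param seqs Named character vector of aligned residue strings. Names are
#'   the record identifiers and must be nonempty and unique.
#' @return An object of class `aln` with elements `ids`, `seqs` (named
#'   character vector) and `width` (number of alignment columns).
#' @examples
#' a <- new_alignment(c(x = "AC-GT", y = "ACGGT"))
#' a$width
#' @export
new_alignment <- function(seqs) {
  if (length(seqs) == 0) stop("alignment must contain at least one record")
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop("every record must have a nonempty id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_residues(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    bad <- ids[widths != widths[1L]][1L]
    stop("unequal record lengths: record '", bad, "' has ", nchar(seqs[[bad]]),
         " columns, expected ", widths[1L])
  }
  bad_chars <- gsub(sprintf("[%s-]", paste(IUPAC_CODES, collapse = "")), "",
                    paste(seqs, collapse = ""))
  if (nzchar(bad_chars)) {
    stop("invalid residue characters: ",
         paste(unique(strsplit(bad_chars, "")[[1]]), collapse = " "))
  }
  structure(list(ids = ids, seqs = seqs, width = unname(widths[1L])),
            class = "aln")
}

# IUPAC nucleotide codes accepted after normalization (no U: mapped to T)
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

normalize_residues <- function(seqs) {
  out <- chartr("u.", "T-", toupper(seqs))
  out <- chartr("U", "T", out)
  names(out) <- names(seqs)
  out
}

#' @export
print.aln <- function(x, ...) {
  cat("Alignment:", length(x$ids), "records x", x$width, "columns\n")
  show <- utils::head(x$ids, 5L)
  for (id in show) {
    s <- x$seqs[[id]]
    cat(sprintf("  %-15s %s%s\n", id, substr(s, 1, 50),
                if (x$width > 50) "..." else ""))
  }
  if (length(x$ids) > 5L) cat("  ...", length(x$ids) - 5L, "more\n")
  invisible(x)
}

#' @export
length.aln <- function(x) length(x$ids)

#' Convert an alignment to a character matrix
#'
#' Rows are records (named by id), columns are alignment positions.
#'
#' @param x An `aln` object.
#' @param ... Ignored.
#' @return Character matrix of single residues.
#' @export
as.matrix.aln <- function(x, ...) {
  m <- matrix(unlist(strsplit(x$seqs, ""), use.names = FALSE),
              nrow = length(x$ids), ncol = x$width, byrow = TRUE)
  rownames(m) <- x$ids
  m
}

#' Read an aligned FASTA file
#'
#' All records must have identical lengths (it is an alignment, not a raw
#' sequence set). Lowercase letters are uppercased, `U` becomes `T`, and the
#' `.` gap convention is normalized to `-`.
#'
#' @param path Path to a FASTA file with one or more records.
#' @return An [new_alignment()] object.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  seqs <- as.character(set)
  # headers may carry descriptions after whitespace; the id is the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  new_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' Headers are the bare record ids; sequence lines wrap at 60 columns, so a
#' write/read round trip is exact.
#'
#' @param alignment An `aln` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "aln"))
  set <- Biostrings::BStringSet(alignment$seqs)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a per-record metadata table
#'
#' Tab-separated with a header row that must contain an `id` column. All
#' columns are kept as character; blank cells become `NA` (missing), never
#' the empty string, so records lacking metadata can be counted explicitly.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` keyed by unique `id`.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"), quote = "")
  if (!"id" %in% names(df)) stop("metadata table lacks an 'id' column: ", path)
  if (anyDuplicated(df$id)) {
    stop("duplicate ids in metadata table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if ("genome_gc" %in% names(df)) df$genome_gc <- as.numeric(df$genome_gc)
  df
}

#' Write a metadata table as TSV
#'
#' @param metadata A data.frame with an `id` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(metadata, path) {
  stopifnot(is.data.frame(metadata), "id" %in% names(metadata))
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a column mask
#'
#' A mask is a single line of `0`/`1` characters (optionally preceded by a
#' FASTA-style `>` header line), one per alignment column; `1` marks columns
#' retained for distance computation.
#'
#' @param path Path to the mask file.
#' @return Logical vector, `TRUE` for included columns.
#' @export
read_column_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  if (length(lines) == 0) stop("mask file contains no mask line: ", path)
  chars <- strsplit(paste(lines, collapse = ""), "")[[1]]
  if (!all(chars %in% c("0", "1"))) {
    stop("mask file must contain only 0/1 characters: ", path)
  }
  chars == "1"
}

#' Write a column mask
#'
#' @param mask Logical vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_column_mask <- function(mask, path) {
  stopifnot(is.logical(mask), !anyNA(mask))
  writeLines(paste(as.integer(mask), collapse = ""), path)
  invisible(path)
}

#' Map alignment columns to ungapped reference coordinates
#'
#' Positions are 1-based and counted over the ungapped residues of the
#' reference record, with position 1 the first base of the reference (for a
#' gene alignment, the first base of the start codon). Columns where the
#' reference carries a gap map to `NA`.
#'
#' @param alignment An `aln` object.
#' @param ref_id Id of the reference record within the alignment.
#' @return Integer vector of length `alignment$width`; `NA` at columns where
#'   the reference is gapped.
#' @examples
#' a <- new_alignment(c(ref = "AT--GC", frag = "ATCCGC"))
#' map_columns_to_reference(a, "ref")  # 1 2 NA NA 3 4
#' @export
map_columns_to_reference <- function(alignment, ref_id) {
  stopifnot(inherits(alignment, "aln"))
  if (!ref_id %in% alignment$ids) stop("reference id not in alignment: ", ref_id)
  chars <- strsplit(alignment$seqs[[ref_id]], "")[[1]]
  nongap <- chars != "-"
  if (!any(nongap)) stop("reference record is entirely gaps: ", ref_id)
  map <- cumsum(nongap)
  map[!nongap] <- NA_integer_
  as.integer(map)
}

#' Subset an alignment to masked-in columns
#'
#' @param alignment An `aln` object.
#' @param mask Logical vector, length equal to the alignment width; `TRUE`
#'   columns are retained in order.
#' @return A new `aln` of width `sum(mask)` (possibly 0).
#' @export
apply_mask <- function(alignment, mask) {
  stopifnot(inherits(alignment, "aln"))
  if (!is.logical(mask) || length(mask) != alignment$width || anyNA(mask)) {
    stop("mask must be a logical vector of length ", alignment$width)
  }
  if (all(mask)) return(alignment)
  m <- as.matrix(alignment)[, mask, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  if (sum(mask) == 0L) seqs <- stats::setNames(rep("", length(alignment$ids)), alignment$ids)
  out <- list(ids = alignment$ids,
              seqs = stats::setNames(as.character(seqs), alignment$ids),
              width = sum(mask))
  structure(out, class = "aln")
}
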