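#' G+C content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`: gaps and IUPAC ambiguity codes are
#' excluded from both numerator and denominator, so the value is invariant
#' under gap insertion or removal.
#'
#' @param record Residue string (or character vector of single residues).
#' @return Fraction in `[0, 1]`, or `NA` if the record has no unambiguous
#'   bases.
#' @examples
#' gc_content("ACG-N")  # 2/3
#' @export
gc_content <- function(record) {
  enc <- encode_bases(normalize_residues(record))
  n <- sum(!is.na(enc))
  if (n == 0L) return(NA_real_)
  sum(enc %in% c(2L, 3L)) / n
}

#' Per-fragment profile of an aligned collection
#'
#' For each non-reference record: the ungapped length, the start and stop
#' positions of its aligned span in ungapped reference coordinates, and its
#' G+C content. When a fragment's first (last) non-gap column falls in a
#' reference insertion, the start rounds forward (the stop rounds backward)
#' to the nearest reference base. Records that are entirely gaps are
#' excluded; their count is available as `attr(, "n_excluded")`.
#'
#' @param alignment An `aln` object containing `ref_id`.
#' @param ref_id Id of the reference record.
#' @return `data.frame` with columns `id`, `ungapped_length`, `start`,
#'   `stop`, `gc`.
#' @export
fragment_profile <- function(alignment, ref_id) {
  refmap <- map_columns_to_reference(alignment, ref_id)
  # start: nearest reference position at or after a column
  fwd <- rev(carry_forward(rev(refmap)))
  # stop: nearest reference position at or before a column
  bwd <- carry_forward(refmap)
  m <- as.matrix(alignment)
  keep <- setdiff(alignment$ids, ref_id)
  rows <- lapply(keep, function(id) {
    chars <- m[id, ]
    nongap <- which(chars != "-")
    if (length(nongap) == 0L) return(NULL)
    data.frame(id = id,
               ungapped_length = length(nongap),
               start = fwd[nongap[1L]],
               stop = bwd[nongap[length(nongap)]],
               gc = gc_content(chars))
  })
  n_excluded <- sum(vapply(rows, is.null, logical(1)))
  if (n_excluded > 0) {
    warning(n_excluded, " record(s) entirely gapped were excluded from the profile")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(id = character(), ungapped_length = integer(),
                      start = integer(), stop = integer(), gc = numeric())
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

# carry the last non-NA value forward; applied to a reversed vector this
# rounds forward into reference gaps
carry_forward <- function(x) {
  last <- NA_integer_
  out <- x
  for (i in seq_along(x)) {
    if (!is.na(x[i])) last <- x[i] else out[i] <- last
  }
  out
}

#' Modal value of a set of fragment lengths
#'
#' Most frequent value; ties are broken by the smallest value so the result
#' is deterministic.
#'
#' @param lengths Numeric/integer vector, nonempty.
#' @return The modal value.
#' @export
length_mode <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length vector")
  tab <- table(lengths)
  vals <- as.numeric(names(tab))
  vals[tab == max(tab)][1L]  # names(table) sort ascending: ties -> smallest
}

#' Histogram of fragment start or stop positions
#'
#' Exact integer counts per reference position, plus the two most frequent
#' positions and their spacing. In amplicon collections the top-2 spacing
#' equals the primer length when a fraction of deposited sequences retain
#' untrimmed primers, so the spacing is a trimming diagnostic.
#'
#' @param profile Output of [fragment_profile()].
#' @param which `"start"` or `"stop"`.
#' @return List with `counts` (data.frame of `position`, `count`), `top2`
#'   (the two most frequent positions, most frequent first; ties broken by
#'   smaller position) and `spacing` (absolute difference of `top2`, `NA`
#'   if fewer than two distinct positions).
#' @export
position_histogram <- function(profile, which = c("start", "stop")) {
  which <- match.arg(which)
  pos <- profile[[which]]
  if (length(pos) == 0L) stop("empty profile")
  tab <- table(pos)
  counts <- data.frame(position = as.integer(names(tab)),
                       count = as.integer(tab))
  ord <- order(-counts$count, counts$position)
  top2 <- counts$position[ord][seq_len(min(2L, nrow(counts)))]
  spacing <- if (length(top2) == 2L) abs(diff(top2)) else NA_integer_
  list(counts = counts, top2 = top2, spacing = spacing)
}

#' Split a G+C distribution at a threshold
#'
#' Counts values at or below the threshold (the low-G+C component of a
#' bimodal collection) and above it, and reports the overall mean.
#'
#' @param gc_values Numeric vector of G+C fractions.
#' @param threshold Inclusive upper bound of the low bin (default 0.53).
#' @return List with `n_low`, `n_high`, `mean_all`.
#' @export
gc_bimodal_split <- function(gc_values, threshold = 0.53) {
  gc_values <- gc_values[!is.na(gc_values)]
  if (length(gc_values) == 0L) stop("no G+C values")
  list(n_low = sum(gc_values <= threshold),
       n_high = sum(gc_values > threshold),
       mean_all = mean(gc_values))
}

#' Ordinary least-squares regression of gene G+C on genome G+C
#'
#' @param genome_gc,gene_gc Paired numeric vectors without missing values,
#'   n >= 3.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
genome_gene_gc_regression <- function(genome_gc, gene_gc) {
  if (length(genome_gc) != length(gene_gc)) stop("unequal vector lengths")
  ok <- !is.na(genome_gc) & !is.na(gene_gc)
  genome_gc <- genome_gc[ok]; gene_gc <- gene_gc[ok]
  if (length(genome_gc) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(genome_gc) == 0) stop("zero variance in genome G+C")
  fit <- stats::lm(gene_gc ~ genome_gc)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = length(genome_gc))
}

#' Tabulate a metadata field
#'
#' Counts per category with an explicit `"missing"` category for `NA`
#' cells, so records lacking metadata are accounted for rather than
#' silently dropped.
#'
#' @param metadata A data.frame from [read_metadata_table()].
#' @param field Column name to tabulate.
#' @return Named integer vector of counts (sorted decreasing, `missing`
#'   last when present).
#' @export
metadata_tabulate <- function(metadata, field) {
  if (!field %in% names(metadata)) stop("unknown metadata field: ", field)
  x <- metadata[[field]]
  if (length(x) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(x, useNA = "no")
  counts <- sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
  n_missing <- sum(is.na(x))
  if (n_missing > 0L) counts <- c(counts, missing = n_missing)
  counts
}
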