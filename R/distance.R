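#' Uncorrected pairwise distance between two aligned sequences
#'
#' The evolutionary distance used throughout the comparative analysis is the
#' uncorrected proportion of differing sites (p-distance) over columns where
#' both residues are unambiguous bases (A/C/G/T) and the column is included
#' by the mask. Gap and ambiguity columns are deleted pairwise, which keeps
#' fragment-heavy collections comparable.
#'
#' @param seqA,seqB Aligned residue strings of equal length.
#' @param mask Optional logical vector of the same length; `NULL` means all
#'   columns included.
#' @return List with `p` (mismatch fraction; `NA` if no comparable sites)
#'   and `n_sites` (number of sites compared).
#' @examples
#' p_distance("ACGT", "ACGA")$p      # 0.25
#' p_distance("AC-T", "ACGT")$n_sites # 3
#' @export
p_distance <- function(seqA, seqB, mask = NULL) {
  a <- encode_bases(seqA)
  b <- encode_bases(seqB)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ok <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) {
    if (!is.logical(mask) || length(mask) != length(a)) {
      stop("mask must be logical of length ", length(a))
    }
    ok <- ok & mask
  }
  n <- sum(ok)
  p <- if (n == 0L) NA_real_ else sum(a[ok] != b[ok]) / n
  list(p = p, n_sites = n)
}

# A,C,G,T -> 1..4; gaps and ambiguity codes -> NA
encode_bases <- function(x) {
  if (length(x) == 1L && is.character(x)) x <- strsplit(x, "")[[1]]
  match(x, c("A", "C", "G", "T"))
}

#' Jukes-Cantor correction of a p-distance
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`, the expected substitutions per site
#' under equal rates and base frequencies. Saturated distances
#' (`p >= 0.75`) are undefined and return `NA`.
#'
#' @param p Observed mismatch fraction(s) in `[0, 1]`.
#' @return Corrected distance(s); `NA` where undefined.
#' @examples
#' jc_distance(0.25)  # 0.3040988...
#' @export
jc_distance <- function(p) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}

#' Pairwise distance matrix under a column mask
#'
#' Computes all pairwise distances for an alignment with pairwise deletion
#' of gap/ambiguity sites. Pairs sharing fewer than `min_overlap` comparable
#' sites are marked undefined (`NA`) rather than reported as unreliable
#' numbers.
#'
#' @param alignment An `aln` object with at least 2 records.
#' @param model `"p"` (uncorrected; the comparative-analysis default) or
#'   `"jc"` (Jukes-Cantor corrected; used for tree building).
#' @param mask Optional logical column mask.
#' @param min_overlap Minimum comparable sites for a pair to be defined.
#' @return An `ed_dist` object: list with `ids`, `d` (symmetric numeric
#'   matrix, zero diagonal), `sites` (symmetric integer matrix of compared
#'   site counts), `model` and `min_overlap`.
#' @export
distance_matrix <- function(alignment, model = c("p", "jc"), mask = NULL,
                            min_overlap = 100L) {
  stopifnot(inherits(alignment, "aln"))
  model <- match.arg(model)
  n <- length(alignment$ids)
  if (n < 2L) stop("need at least 2 records for a distance matrix")
  if (!is.null(mask)) {
    if (!is.logical(mask) || length(mask) != alignment$width) {
      stop("mask must be logical of length ", alignment$width)
    }
  }
  enc <- matrix(encode_bases(unlist(strsplit(alignment$seqs, ""),
                                    use.names = FALSE)),
                nrow = n, byrow = TRUE)
  if (!is.null(mask)) enc <- enc[, mask, drop = FALSE]

  d <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  sites <- matrix(0L, n, n, dimnames = list(alignment$ids, alignment$ids))
  valid <- !is.na(enc)
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    vi <- valid[i, ]
    for (j in (i + 1L):n) {
      ok <- vi & valid[j, ]
      ns <- sum(ok)
      sites[i, j] <- sites[j, i] <- ns
      if (ns < min_overlap) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        p <- sum(ai[ok] != enc[j, ok]) / ns
        if (model == "jc") p <- jc_distance(p)
        d[i, j] <- d[j, i] <- p
      }
    }
    sites[i, i] <- sum(vi)
  }
  sites[n, n] <- sum(valid[n, ])
  structure(list(ids = alignment$ids, d = d, sites = sites, model = model,
                 min_overlap = as.integer(min_overlap)),
            class = "ed_dist")
}

#' @export
print.ed_dist <- function(x, ...) {
  nd <- x$d[upper.tri(x$d)]
  cat("Distance matrix (", x$model, "): ", length(x$ids), " ids, ",
      sum(is.na(nd)), " undefined pairs\n", sep = "")
  invisible(x)
}

#' Write a distance matrix
#'
#' Two text formats: square PHYLIP (`format = "phylip"`; undefined entries
#' written as -1) and long-form TSV (`format = "tsv"`) with one row per
#' unordered pair carrying the distance and the compared-site count.
#'
#' @param dm An `ed_dist` object.
#' @param path Output file path.
#' @param format `"phylip"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "tsv")) {
  stopifnot(inherits(dm, "ed_dist"))
  format <- match.arg(format)
  if (format == "phylip") {
    d <- dm$d
    d[is.na(d)] <- -1
    lines <- c(sprintf("%5d", length(dm$ids)),
               vapply(seq_along(dm$ids), function(i) {
                 paste0(formatC(dm$ids[i], width = -10),
                        paste(sprintf("%.8f", d[i, ]), collapse = " "))
               }, character(1)))
    writeLines(lines, path)
  } else {
    n <- length(dm$ids)
    idx <- which(upper.tri(dm$d), arr.ind = TRUE)
    df <- data.frame(idA = dm$ids[idx[, 1]], idB = dm$ids[idx[, 2]],
                     d = dm$d[idx], sites = dm$sites[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a long-form TSV distance matrix
#'
#' Reads the `idA`/`idB`/`d`/`sites` format written by
#' [write_distance_matrix()].
#'
#' @param path Path to the TSV file.
#' @param model Model label to attach (informational).
#' @return An `ed_dist` object.
#' @export
read_distance_tsv <- function(path, model = "p") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(idA = "character", idB = "character"))
  ids <- unique(c(df$idA, df$idB))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  ia <- match(df$idA, ids); ib <- match(df$idB, ids)
  d[cbind(ia, ib)] <- df$d; d[cbind(ib, ia)] <- df$d
  sites[cbind(ia, ib)] <- df$sites; sites[cbind(ib, ia)] <- df$sites
  structure(list(ids = ids, d = d, sites = sites, model = model,
                 min_overlap = NA_integer_), class = "ed_dist")
}
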