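# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: per-site scans, normal equations, direct RSS
# arithmetic, and explicit bipartition sets.

# position-by-position mismatch scan over unambiguous bases
oracle_p_distance <- function(seqA, seqB, mask = NULL) {
  a <- strsplit(seqA, "")[[1]]
  b <- strsplit(seqB, "")[[1]]
  keep <- if (is.null(mask)) rep(TRUE, length(a)) else mask
  mism <- 0L; n <- 0L
  for (i in seq_along(a)) {
    if (!keep[i]) next
    if (a[i] %in% c("A", "C", "G", "T") && b[i] %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (a[i] != b[i]) mism <- mism + 1L
    }
  }
  list(p = if (n == 0) NA_real_ else mism / n, n_sites = n)
}

# OLS by the normal equations
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  fitted <- intercept + slope * x
  rss <- sum((y - fitted)^2)
  tss <- sum((y - yb)^2)
  list(slope = slope, intercept = intercept, rss = rss,
       r_squared = 1 - rss / tss)
}

# slope-homogeneity F from direct RSS arithmetic: full model fits each
# group separately; reduced model shares the slope across groups
oracle_slope_f <- function(x1, y1, x2, y2) {
  rss_full <- oracle_ols(x1, y1)$rss + oracle_ols(x2, y2)$rss
  # common-slope model: minimize over (b, a1, a2) analytically
  xc1 <- x1 - mean(x1); xc2 <- x2 - mean(x2)
  yc1 <- y1 - mean(y1); yc2 <- y2 - mean(y2)
  b <- (sum(xc1 * yc1) + sum(xc2 * yc2)) / (sum(xc1^2) + sum(xc2^2))
  rss_red <- sum((yc1 - b * xc1)^2) + sum((yc2 - b * xc2)^2)
  n <- length(x1) + length(x2)
  f <- (rss_red - rss_full) / (rss_full / (n - 4))
  list(f = f, p = stats::pf(f, 1, n - 4, lower.tail = FALSE))
}

# set of internal bipartitions of an unrooted tree, each encoded as the
# lexicographically smaller side's sorted label string
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  out <- character(0)
  for (node in setdiff(unique(tree$edge[, 1]), ntip + 1L)) {
    tips <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    other <- setdiff(tree$tip.label, tips)
    side <- if (paste(sort(tips), collapse = ",") <
                paste(sort(other), collapse = ",")) tips else other
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

oracle_rf <- function(treeA, treeB) {
  a <- oracle_bipartitions(treeA)
  b <- oracle_bipartitions(treeB)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# random additive distance matrix from a random topology with known
# branch lengths; returns the matrix and the generating tree
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 1)
  list(d = cophenetic(tr)[tr$tip.label, tr$tip.label], tree = tr)
}

# small random gapped alignment for round-trip and mask tests
random_alignment <- function(n = 5, width = 40) {
  chars <- c("A", "C", "G", "T", "-", "N")
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(chars, width, replace = TRUE, prob = c(rep(0.22, 4), .08, .04)),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("t%02d", seq_len(n))
  new_alignment(seqs)
}
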