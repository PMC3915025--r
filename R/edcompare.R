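#' Matched taxon-pair table of distances for two genes
#'
#' Joins two distance matrices on their shared ids and labels each
#' unordered pair by comparison category: within the first group
#' (`intra-A`), within the second (`intra-B`), or between groups
#' (`inter`). This is the data structure behind gene-versus-gene
#' divergence scatter plots partitioned by cluster or domain.
#'
#' @param matX,matY `ed_dist` objects for the x-axis gene and y-axis gene.
#' @param labels Named character vector mapping ids to exactly two group
#'   labels (e.g. cluster or domain assignments).
#' @param groups Optional length-2 character vector fixing which label is
#'   group A and which group B; default: sorted unique labels.
#' @return `data.frame` with columns `idA`, `idB`, `dX`, `dY`, `sitesX`,
#'   `sitesY` (compared-site counts behind each distance) and `category`
#'   (factor with levels `intra-A`, `intra-B`, `inter`); attributes
#'   `groups` (named map A/B -> label), `n_dropped_ids` and
#'   `n_dropped_pairs` (ids/pairs dropped for missing matrix entries).
#' @export
build_pair_table <- function(matX, matY, labels, groups = NULL) {
  stopifnot(inherits(matX, "ed_dist"), inherits(matY, "ed_dist"))
  ids <- intersect(intersect(matX$ids, matY$ids), names(labels))
  n_dropped_ids <- length(union(matX$ids, matY$ids)) - length(ids)
  if (length(ids) < 3L) stop("fewer than 3 ids shared by both matrices and labels")
  labs <- labels[ids]
  if (anyNA(labs)) stop("missing group labels for some shared ids")
  uniq <- sort(unique(labs))
  if (is.null(groups)) groups <- uniq
  if (length(groups) != 2L || !setequal(uniq, groups)) {
    stop("labels must assign each id to exactly one of two groups; found: ",
         paste(uniq, collapse = ", "))
  }
  idx <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  ia <- idx[, 1L]; ib <- idx[, 2L]
  ix <- cbind(match(ids[ia], matX$ids), match(ids[ib], matX$ids))
  iy <- cbind(match(ids[ia], matY$ids), match(ids[ib], matY$ids))
  dX <- matX$d[ix]
  dY <- matY$d[iy]
  sitesX <- matX$sites[ix]
  sitesY <- matY$sites[iy]
  ok <- !is.na(dX) & !is.na(dY)
  n_dropped_pairs <- sum(!ok)
  if (n_dropped_pairs > 0) {
    message(n_dropped_pairs, " pair(s) dropped for undefined distances")
  }
  ga <- labs[ia]; gb <- labs[ib]
  category <- ifelse(ga == gb,
                     ifelse(ga == groups[1L], "intra-A", "intra-B"),
                     "inter")
  out <- data.frame(idA = ids[ia], idB = ids[ib], dX = dX, dY = dY,
                    sitesX = sitesX, sitesY = sitesY,
                    category = factor(category,
                                      levels = c("intra-A", "intra-B", "inter")))
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  for (cat in c("intra-A", "intra-B")) {
    if (sum(out$category == cat) < 1L) stop("no usable pairs in category ", cat)
  }
  attr(out, "groups") <- stats::setNames(groups, c("A", "B"))
  attr(out, "n_dropped_ids") <- n_dropped_ids
  attr(out, "n_dropped_pairs") <- n_dropped_pairs
  out
}

#' Per-category divergence regressions
#'
#' Ordinary least squares of `dY` on `dX` (with intercept) within each
#' comparison category that has at least 3 points.
#'
#' @param pairtable Output of [build_pair_table()].
#' @param categories Categories to fit (default: all present with n >= 3).
#' @return `data.frame` with one row per category: `category`, `slope`,
#'   `intercept`, `r_squared`, `rss`, `n`.
#' @export
fit_group_regressions <- function(pairtable,
                                  categories = levels(pairtable$category)) {
  rows <- lapply(categories, function(cat) {
    sub <- pairtable[pairtable$category == cat, , drop = FALSE]
    if (nrow(sub) < 3L) return(NULL)
    if (stats::var(sub$dX) == 0) stop("zero variance in dX for category ", cat)
    fit <- stats::lm(dY ~ dX, data = sub)
    data.frame(category = cat,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r_squared = suppressWarnings(summary(fit)$r.squared),
               rss = sum(stats::residuals(fit)^2),
               n = nrow(sub))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no category has the minimum 3 points")
  rownames(out) <- NULL
  out
}

#' Homogeneity-of-slopes F-test between two comparison categories
#'
#' ANCOVA-style comparison of the full model (separate slope and intercept
#' per category) against the reduced model (common slope, separate
#' intercepts):
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - 4))` on
#' `(1, n - 4)` degrees of freedom. A small p-value means the two
#' categories diverge at significantly different rates.
#'
#' @param pairtable Output of [build_pair_table()].
#' @param catA,catB The two categories to compare (each n >= 4).
#' @return List with `f_stat`, `df_num`, `df_den`, `p_value`, `n`,
#'   `slopes` (named per-category OLS slopes).
#' @export
slope_homogeneity_test <- function(pairtable, catA = "intra-A",
                                   catB = "intra-B") {
  sub <- pairtable[pairtable$category %in% c(catA, catB), , drop = FALSE]
  sub$grp <- factor(as.character(sub$category), levels = c(catA, catB))
  nA <- sum(sub$grp == catA); nB <- sum(sub$grp == catB)
  if (nA < 4L || nB < 4L) stop("each category needs at least 4 points")
  if (stats::var(sub$dX[sub$grp == catA]) == 0 ||
      stats::var(sub$dX[sub$grp == catB]) == 0) {
    stop("degenerate design: zero dX variance within a category")
  }
  full <- stats::lm(dY ~ dX * grp, data = sub)
  reduced <- stats::lm(dY ~ dX + grp, data = sub)
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  df_num <- 1L
  df_den <- full$df.residual
  # direct RSS arithmetic (an anova() table can return NA for an exactly
  # zero sum of squares through floating-point cancellation)
  f <- max(0, rss_red - rss_full) / (rss_full / df_den)
  co <- stats::coef(full)
  slopeA <- unname(co["dX"])
  slopeB <- slopeA + unname(co[grep("^dX:grp", names(co))][1L])
  list(f_stat = f,
       df_num = df_num,
       df_den = df_den,
       p_value = stats::pf(f, df_num, df_den, lower.tail = FALSE),
       n = nrow(sub),
       slopes = stats::setNames(c(slopeA, slopeB), c(catA, catB)))
}

#' Horizontal-transfer discontinuity score
#'
#' Fits a pooled OLS line to the union of the two intra-category point
#' clouds and standardizes the mean residual of the inter-category points
#' against it. A single-gene transfer between the groups pulls the
#' inter-group divergence of that gene below the within-group trend, so
#' the flag is one-sided: `flagged` iff `z <= -z_crit`.
#'
#' Two standardizations are computed. `z_iid` divides by
#' `sigma / sqrt(n_inter)` (`sigma` the residual SD of the pooled intra
#' fit), which treats inter residuals as independent. That is
#' anti-conservative for distance data: every inter pair's path crosses
#' the same two stem lineages, so the realized stem substitutions of each
#' gene shift all inter points together, and the inter points sit beyond
#' the intra x-range, adding extrapolation error. The calibrated score
#' `z` therefore uses a standard error with three components: (i) the
#' regression prediction error of the intra fit at the inter points
#' (including the `1/n_inter` averaging term), and, when the pair table
#' carries compared-site counts, (ii, iii) the site-sampling variance of
#' each gene's shared-path divergence, `p(1-p)/L` evaluated at the mean
#' inter distance — the component that does not average away over pairs.
#' `z` is used for `flagged`.
#'
#' @param pairtable Output of [build_pair_table()] with the candidate
#'   transfer gene on the y-axis and a control gene on the x-axis.
#' @param z_crit Flagging threshold on the standardized score (default 3).
#' @return List with `z` (calibrated), `z_iid`, `flagged`, `se`,
#'   `n_inter`, `pooled_slope`, `pooled_intercept`, `resid_sd`,
#'   `mean_inter_residual`.
#' @export
hgt_discontinuity <- function(pairtable, z_crit = 3) {
  intra <- pairtable[pairtable$category %in% c("intra-A", "intra-B"), ,
                     drop = FALSE]
  inter <- pairtable[pairtable$category == "inter", , drop = FALSE]
  if (nrow(intra) < 3L) stop("need at least 3 intra-category points")
  if (nrow(inter) < 3L) stop("need at least 3 inter-category points")
  fit <- stats::lm(dY ~ dX, data = intra)
  b <- unname(stats::coef(fit)[2L])
  sigma <- sqrt(sum(stats::residuals(fit)^2) / fit$df.residual)
  pred <- stats::predict(fit, newdata = inter)
  mres <- mean(inter$dY - pred)
  n_in <- nrow(intra); n_out <- nrow(inter)
  # prediction error of the intra line at the mean inter abscissa, plus
  # residual averaging over the inter points
  sxx <- sum((intra$dX - mean(intra$dX))^2)
  var_pred <- sigma^2 * (1 / n_in + (mean(inter$dX) - mean(intra$dX))^2 / sxx)
  var_mean <- sigma^2 / n_out
  # shared-path site-sampling variance (does not shrink with n_out)
  var_shared <- 0
  if (all(c("sitesX", "sitesY") %in% names(pairtable))) {
    pX <- min(max(mean(inter$dX), 0), 1)
    pY <- min(max(mean(inter$dY), 0), 1)
    var_shared <- pY * (1 - pY) / mean(inter$sitesY) +
      b^2 * pX * (1 - pX) / mean(inter$sitesX)
  }
  se <- sqrt(var_pred + var_mean + var_shared)
  z_iid <- if (sigma == 0) {
    if (mres == 0) 0 else sign(mres) * Inf
  } else {
    mres / (sigma / sqrt(n_out))
  }
  z <- if (se == 0) {
    if (mres == 0) 0 else sign(mres) * Inf
  } else {
    mres / se
  }
  list(z = z,
       z_iid = z_iid,
       flagged = z <= -z_crit,
       se = se,
       n_inter = n_out,
       pooled_slope = b,
       pooled_intercept = unname(stats::coef(fit)[1L]),
       resid_sd = sigma,
       mean_inter_residual = mres)
}

#' Marker divergence among near-identical 16S pairs
#'
#' Over taxon pairs whose 16S (or other slow-marker) distance is below the
#' species-delimitation threshold, summarizes how divergent a faster
#' functional marker can be: the number of qualifying pairs, the maximum
#' marker distance, and the fractions exceeding given marker-distance
#' cutoffs.
#'
#' @param mat16S `ed_dist` for the slow reference marker (e.g. 16S rRNA).
#' @param matMarker `ed_dist` for the functional marker gene.
#' @param threshold Strict upper bound on the 16S distance (default 0.03,
#'   the 97%-identity species proxy).
#' @param cutoffs Marker-distance cutoffs for the exceedance fractions
#'   (default 0.05 and 0.15).
#' @return List with `n_pairs`, `max_marker_distance`, `frac_above`
#'   (named by cutoff) and `pairs` (the qualifying pair table).
#' @export
threshold_divergence_analysis <- function(mat16S, matMarker, threshold = 0.03,
                                          cutoffs = c(0.05, 0.15)) {
  stopifnot(inherits(mat16S, "ed_dist"), inherits(matMarker, "ed_dist"))
  ids <- intersect(mat16S$ids, matMarker$ids)
  if (length(ids) < 2L) stop("fewer than 2 shared ids")
  idx <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  d16 <- mat16S$d[cbind(match(ids[idx[, 1]], mat16S$ids),
                        match(ids[idx[, 2]], mat16S$ids))]
  dM <- matMarker$d[cbind(match(ids[idx[, 1]], matMarker$ids),
                          match(ids[idx[, 2]], matMarker$ids))]
  ok <- !is.na(d16) & !is.na(dM)
  qual <- ok & d16 < threshold
  pairs <- data.frame(idA = ids[idx[qual, 1]], idB = ids[idx[qual, 2]],
                      d16S = d16[qual], dMarker = dM[qual])
  if (nrow(pairs) == 0L) {
    message("no pairs below the 16S threshold ", threshold)
    return(list(n_pairs = 0L, max_marker_distance = NA_real_,
                frac_above = stats::setNames(rep(NA_real_, length(cutoffs)),
                                             as.character(cutoffs)),
                pairs = pairs))
  }
  frac <- vapply(cutoffs, function(ct) mean(pairs$dMarker > ct), numeric(1))
  list(n_pairs = nrow(pairs),
       max_marker_distance = max(pairs$dMarker),
       frac_above = stats::setNames(frac, as.character(cutoffs)),
       pairs = pairs)
}
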