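# build a tiny ed_dist from a full symmetric matrix
make_ed <- function(d, ids = rownames(d)) {
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, sites = matrix(1000L, nrow(d), ncol(d)),
                 model = "p", min_overlap = 1L), class = "ed_dist")
}

# matrices whose pair distances are a deterministic function of index sums,
# convenient for checking the join
toy_matrices <- function(ids) {
  n <- length(ids)
  base <- outer(seq_len(n), seq_len(n), function(i, j) abs(i - j) / (2 * n))
  diag(base) <- 0
  list(x = make_ed(base, ids), y = make_ed(base * 1.2, ids))
}

test_that("pair tables enumerate unordered pairs with correct categories", {
  ids <- c("a1", "a2", "b1", "b2")
  labels <- stats::setNames(c("I", "I", "III", "III"), ids)
  tm <- toy_matrices(ids)
  pt <- build_pair_table(tm$x, tm$y, labels)
  expect_equal(nrow(pt), 6L)
  expect_equal(sum(pt$category == "intra-A"), 1L)
  expect_equal(sum(pt$category == "intra-B"), 1L)
  expect_equal(sum(pt$category == "inter"), 4L)
  expect_equal(attr(pt, "groups"), c(A = "I", B = "III"))
  # combinatorial identity at larger sizes
  ids2 <- c(sprintf("a%d", 1:7), sprintf("b%d", 1:5))
  labels2 <- stats::setNames(rep(c("I", "III"), c(7, 5)), ids2)
  tm2 <- toy_matrices(ids2)
  pt2 <- build_pair_table(tm2$x, tm2$y, labels2)
  expect_equal(sum(pt2$category == "intra-A"), 7 * 6 / 2)
  expect_equal(sum(pt2$category == "intra-B"), 5 * 4 / 2)
  expect_equal(sum(pt2$category == "inter"), 7 * 5)
  # ids missing from one matrix are dropped
  tm3 <- toy_matrices(ids2[c(1, 2, 8, 9)])
  pt3 <- build_pair_table(tm3$x, tm2$y, labels2)
  expect_equal(nrow(pt3), 6L)
  expect_equal(attr(pt3, "n_dropped_ids"), 8L)
})

test_that("per-category regressions match closed-form coefficients", {
  x <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  pt <- data.frame(idA = letters[1:6], idB = LETTERS[1:6],
                   dX = x, dY = 1.2 * x,
                   category = factor(rep("intra-A", 6),
                                     levels = c("intra-A", "intra-B", "inter")))
  fits <- fit_group_regressions(pt, "intra-A")
  expect_equal(fits$slope, 1.2, tolerance = 1e-12)
  expect_equal(fits$intercept, 0, tolerance = 1e-12)
  expect_equal(fits$r_squared, 1)
  set.seed(3)
  pt$dY <- 0.9 * x + 0.02 + rnorm(6, 0, 0.01)
  fits2 <- fit_group_regressions(pt, "intra-A")
  want <- oracle_ols(pt$dX, pt$dY)
  expect_equal(fits2$slope, want$slope, tolerance = 1e-10)
  expect_equal(fits2$rss, want$rss, tolerance = 1e-10)
})

test_that("slope-homogeneity F equals direct RSS arithmetic and is symmetric", {
  set.seed(19)
  x1 <- runif(8, 0, 0.3); y1 <- 1.0 * x1 + rnorm(8, 0, 0.02)
  x2 <- runif(9, 0, 0.3); y2 <- 1.6 * x2 + rnorm(9, 0, 0.02)
  pt <- data.frame(idA = paste0("p", 1:17), idB = paste0("q", 1:17),
                   dX = c(x1, x2), dY = c(y1, y2),
                   category = factor(rep(c("intra-A", "intra-B"), c(8, 9)),
                                     levels = c("intra-A", "intra-B", "inter")))
  got <- slope_homogeneity_test(pt)
  want <- oracle_slope_f(x1, y1, x2, y2)
  expect_equal(got$f_stat, want$f, tolerance = 1e-8)
  expect_equal(got$p_value, want$p, tolerance = 1e-8)
  expect_equal(got$df_num, 1L)
  expect_equal(got$df_den, 17L - 4L)
  sym <- slope_homogeneity_test(pt, "intra-B", "intra-A")
  expect_equal(sym$f_stat, got$f_stat, tolerance = 1e-10)
  expect_equal(sym$p_value, got$p_value, tolerance = 1e-10)
})

test_that("identical categories give F = 0", {
  x <- seq(0.05, 0.4, length.out = 6)
  y <- 1.1 * x + c(0.01, -0.01, 0.02, -0.02, 0, 0.01)
  pt <- data.frame(idA = paste0("p", 1:12), idB = paste0("q", 1:12),
                   dX = rep(x, 2), dY = rep(y, 2),
                   category = factor(rep(c("intra-A", "intra-B"), each = 6),
                                     levels = c("intra-A", "intra-B", "inter")))
  got <- slope_homogeneity_test(pt)
  expect_equal(got$f_stat, 0, tolerance = 1e-10)
  expect_equal(got$p_value, 1, tolerance = 1e-8)
})

test_that("slope test holds its size on independent equal-slope data", {
  # empirical type-I error at alpha = 0.05 over many iid replicates
  set.seed(2024)
  n_rep <- 1000L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    x1 <- runif(20, 0, 0.3); y1 <- 1.2 * x1 + rnorm(20, 0, 0.03)
    x2 <- runif(20, 0, 0.3); y2 <- 1.2 * x2 + 0.05 + rnorm(20, 0, 0.03)
    pt <- data.frame(idA = "a", idB = "b",
                     dX = c(x1, x2), dY = c(y1, y2),
                     category = factor(rep(c("intra-A", "intra-B"), each = 20),
                                       levels = c("intra-A", "intra-B", "inter")))
    if (slope_homogeneity_test(pt)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("transfer discontinuity flags shifted inter points, not null ones", {
  set.seed(55)
  mk_pt <- function(shift) {
    x_in <- runif(40, 0, 0.3)
    y_in <- x_in + rnorm(40, 0, 0.02)
    x_out <- runif(30, 0.3, 0.5)
    y_out <- x_out + shift + rnorm(30, 0, 0.02)
    data.frame(idA = "a", idB = "b",
               dX = c(x_in, x_out), dY = c(y_in, y_out),
               category = factor(rep(c("intra-A", "intra-B", "inter"),
                                     c(20, 20, 30)),
                                 levels = c("intra-A", "intra-B", "inter")))
  }
  # inter points 5 residual SDs below the trend -> flagged
  res <- hgt_discontinuity(mk_pt(shift = -0.1))
  expect_true(res$flagged)
  expect_lt(res$z, -3)
  # exact-fit inter points -> z = 0ish, not flagged
  pt0 <- mk_pt(0)
  pt0$dY[pt0$category == "inter"] <- NA
  fit <- stats::lm(dY ~ dX, data = pt0[pt0$category != "inter", ])
  pred <- stats::predict(fit, newdata = pt0[pt0$category == "inter", ])
  pt0$dY[pt0$category == "inter"] <- pred
  res0 <- hgt_discontinuity(pt0)
  expect_equal(res0$z, 0, tolerance = 1e-8)
  expect_false(res0$flagged)
  # false-positive calibration: same line and noise for inter as intra
  flags <- vapply(1:100, function(i) hgt_discontinuity(mk_pt(0))$flagged,
                  logical(1))
  expect_lte(sum(flags), 5L)
})

test_that("threshold-divergence analysis enumerates qualifying pairs", {
  ids <- c("a", "b", "c", "d")
  d16 <- matrix(c(0, .01, .2, .2,
                  .01, 0, .2, .2,
                  .2, .2, 0, .025,
                  .2, .2, .025, 0), 4)
  dM <- matrix(c(0, .23, .4, .4,
                 .23, 0, .4, .4,
                 .4, .4, 0, .04,
                 .4, .4, .04, 0), 4)
  td <- threshold_divergence_analysis(make_ed(d16, ids), make_ed(dM, ids))
  expect_equal(td$n_pairs, 2L)
  expect_equal(td$max_marker_distance, 0.23)
  expect_equal(unname(td$frac_above[["0.05"]]), 0.5)
  expect_equal(unname(td$frac_above[["0.15"]]), 0.5)
  # no qualifying pairs
  far <- make_ed(matrix(0.5, 4, 4) - diag(0.5, 4), ids)
  expect_message(td0 <- threshold_divergence_analysis(far, make_ed(dM, ids)),
                 "no pairs")
  expect_equal(td0$n_pairs, 0L)
  # brute-force enumeration on random decoupled matrices
  set.seed(31)
  for (rep in 1:10) {
    n <- 8
    r16 <- matrix(0, n, n); rM <- matrix(0, n, n)
    r16[upper.tri(r16)] <- runif(n * (n - 1) / 2, 0, 0.06)
    rM[upper.tri(rM)] <- runif(n * (n - 1) / 2, 0, 0.3)
    r16 <- r16 + t(r16); rM <- rM + t(rM)
    ids2 <- paste0("t", 1:n)
    td2 <- threshold_divergence_analysis(make_ed(r16, ids2), make_ed(rM, ids2))
    qual <- r16[upper.tri(r16)] < 0.03
    expect_equal(td2$n_pairs, sum(qual))
    if (sum(qual) > 0) {
      expect_equal(td2$max_marker_distance, max(rM[upper.tri(rM)][qual]))
      expect_equal(unname(td2$frac_above[["0.15"]]),
                   mean(rM[upper.tri(rM)][qual] > 0.15))
    }
  }
})
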