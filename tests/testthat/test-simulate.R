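test_that("two-clade trees are deterministic, labeled and monophyletic", {
  s1 <- simulate_tree(5, seed = 42)
  s2 <- simulate_tree(5, seed = 42)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_equal(ape::Ntip(s1$tree), 10L)
  expect_equal(sum(s1$labels == "A"), 5L)
  expect_equal(sum(s1$labels == "B"), 5L)
  expect_true(ape::is.monophyletic(s1$tree, names(s1$labels)[s1$labels == "A"]))
  expect_true(ape::is.monophyletic(s1$tree, names(s1$labels)[s1$labels == "B"]))
  # ultrametric at the configured root height
  depths <- ape::node.depth.edgelength(s1$tree)[1:10]
  expect_equal(depths, rep(0.5, 10), tolerance = 1e-8)
  expect_error(simulate_tree(2, seed = 1), "3")
})

test_that("F81 simulation hits its closed-form expected p-distance", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  ps <- vapply(1:50, function(i) {
    a <- evolve_gene(tr, gene_spec("g", 10000), seed = 1000 + i)
    p_distance(a$seqs[["a"]], a$seqs[["b"]])$p
  }, numeric(1))
  expected <- 0.75 * (1 - exp(-0.4))  # JC expectation at separation 0.3
  se <- stats::sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("zero branch lengths copy the root and frequencies are stationary", {
  tr <- ape::read.tree(text = "(a:0,(b:0,c:0):0);")
  a <- evolve_gene(tr, gene_spec("g", 500), seed = 3)
  expect_equal(a$seqs[["a"]], a$seqs[["b"]], ignore_attr = TRUE)
  expect_equal(a$seqs[["b"]], a$seqs[["c"]], ignore_attr = TRUE)
  # long branches converge to the stationary composition
  long <- ape::read.tree(text = "(a:4,b:4);")
  pi_skew <- c(0.1, 0.4, 0.4, 0.1)
  b <- evolve_gene(long, gene_spec("g", 20000, base_freqs = pi_skew), seed = 7)
  freqs <- table(factor(strsplit(b$seqs[["a"]], "")[[1]],
                        levels = c("A", "C", "G", "T"))) / 20000
  sds <- sqrt(pi_skew * (1 - pi_skew) / 20000)
  expect_true(all(abs(as.numeric(freqs) - pi_skew) < 4 * sds))
  expect_error(gene_spec("g", 100, base_freqs = c(0.5, 0.5, 0.2, 0.2)))
})

test_that("grafted transfers shorten inter-clade paths monotonically in depth", {
  sim <- simulate_tree(5, seed = 11)
  expect_error(graft_hgt(sim$tree, sim$labels, "A", "A", 0.5), "differ")
  expect_error(graft_hgt(sim$tree, sim$labels, "A", "Z", 0.5), "clade")
  prev <- -Inf
  for (depth in c(0.4, 0.6, 0.8)) {
    g <- graft_hgt(sim$tree, sim$labels, "A", "B", depth)
    pl <- cophenetic(g$tree)
    inter <- pl[names(sim$labels)[sim$labels == "A"],
                names(sim$labels)[sim$labels == "B"]]
    genome_pl <- cophenetic(sim$tree)
    genome_inter <- genome_pl[rownames(inter), colnames(inter)]
    expect_true(all(inter < genome_inter))
    expect_equal(max(inter), 2 * depth * 0.5, tolerance = 1e-6)
    expect_gt(min(inter), prev)
    prev <- max(inter)
  }
})

test_that("multigene datasets share ids, carry truth, and are reproducible", {
  cfg <- multigene_config(n_per_clade = 5, genes = list(
    gene_spec("marker16S", 300, rate = 0.25),
    gene_spec("geneH", 300, hgt = list(donor = "A", recipient = "B", depth = 0.5)),
    gene_spec("geneD", 300, clade_rates = c(A = 1, B = 2)),
    gene_spec("geneK", 300)))
  sim1 <- simulate_multigene_dataset(cfg, seed = 9)
  sim2 <- simulate_multigene_dataset(cfg, seed = 9)
  expect_identical(sim1$alignments$geneH$seqs, sim2$alignments$geneH$seqs)
  expect_identical(sim1$truth$genome_tree, sim2$truth$genome_tree)
  expect_length(sim1$alignments, 4L)
  idsets <- lapply(sim1$alignments, function(a) sort(a$ids))
  expect_true(all(vapply(idsets, identical, logical(1), idsets[[1]])))
  expect_equal(nrow(sim1$metadata), 10L)
  expect_true(all(c("id", "clade_label", "domain_label", "genome_gc") %in%
                  names(sim1$metadata)))
  # the recorded transfer event is recoverable from the emitted gene tree:
  # inter-clade path lengths shrink for the transferred gene only
  gH <- ape::read.tree(text = sim1$truth$gene_trees$geneH)
  gK <- ape::read.tree(text = sim1$truth$gene_trees$geneK)
  genome <- ape::read.tree(text = sim1$truth$genome_tree)
  A <- names(sim1$truth$labels)[sim1$truth$labels == "A"]
  B <- names(sim1$truth$labels)[sim1$truth$labels == "B"]
  expect_lt(max(cophenetic(gH)[A, B]), min(cophenetic(genome)[A, B]))
  expect_equal(cophenetic(gK)[A, B], cophenetic(genome)[A, B], tolerance = 1e-6)
  expect_equal(sim1$truth$hgt_events$geneH$depth, 0.5)
})

test_that("genome and gene G+C are linearly coupled in the default dataset", {
  sim <- simulate_multigene_dataset(multigene_config(), seed = 27)
  gg <- stats::setNames(sim$metadata$genome_gc, sim$metadata$id)
  gene_gc <- vapply(sim$alignments$geneK$seqs, gc_content, numeric(1))
  r <- genome_gene_gc_regression(gg[names(gene_gc)], gene_gc)
  expect_gt(r$r_squared, 0.8)
  expect_gt(r$slope, 0)
})

test_that("fragment databases reproduce their configured structure", {
  cfg <- fragment_config(n = 800)
  fd1 <- simulate_fragment_database(cfg, seed = 4)
  fd2 <- simulate_fragment_database(cfg, seed = 4)
  expect_identical(fd1$alignment$seqs, fd2$alignment$seqs)
  prof <- fragment_profile(fd1$alignment, fd1$ref_id)
  expect_equal(nrow(prof), 800L)
  # deposited start/stop positions recovered exactly from the alignment
  expect_equal(stats::setNames(prof$start, prof$id),
               stats::setNames(fd1$truth$start, fd1$truth$id))
  expect_equal(stats::setNames(prof$stop, prof$id),
               stats::setNames(fd1$truth$stop, fd1$truth$id))
  # untrimmed fraction 0 leaves a single dominant start
  fd0 <- simulate_fragment_database(fragment_config(n = 300, untrimmed_frac = 0),
                                    seed = 5)
  h0 <- position_histogram(fragment_profile(fd0$alignment, fd0$ref_id), "start")
  expect_equal(h0$counts$count[h0$counts$position == 114] / 300 > 0.8, TRUE)
  expect_error(fragment_config(windows = list(list(start = 5, stop = 900,
                                                   weight = 1))),
               "window")
})

test_that("equal-rate genes keep near-equal intra-clade slopes while the
           rate-variant gene recovers its multiplier", {
  cfg <- multigene_config(n_per_clade = 12, genes = list(
    gene_spec("geneH", 1200),
    gene_spec("geneD", 1200, clade_rates = c(A = 1, B = 2)),
    gene_spec("geneK", 1200)))
  ratios_null <- c(); ratios_2x <- c()
  for (s in 1:5) {
    sim <- simulate_multigene_dataset(cfg, seed = 100 + s)
    labels <- stats::setNames(sim$metadata$clade_label, sim$metadata$id)
    dH <- distance_matrix(sim$alignments$geneH, model = "jc", min_overlap = 50)
    dK <- distance_matrix(sim$alignments$geneK, model = "jc", min_overlap = 50)
    dD <- distance_matrix(sim$alignments$geneD, model = "jc", min_overlap = 50)
    stHK <- slope_homogeneity_test(build_pair_table(dH, dK, labels))
    stHD <- slope_homogeneity_test(build_pair_table(dH, dD, labels))
    ratios_null <- c(ratios_null, stHK$slopes[[2]] / stHK$slopes[[1]])
    ratios_2x <- c(ratios_2x, stHD$slopes[[2]] / stHD$slopes[[1]])
  }
  expect_lt(abs(mean(ratios_null) - 1), 0.15)
  expect_lt(abs(mean(ratios_2x) - 2) / 2, 0.15)
})
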