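#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Two modes: simulation
#' mode (a [multigene_config()] plus a seed generates the inputs) or file
#' mode (paths to per-gene aligned FASTA files and a metadata TSV).
#'
#' @param alignments Named character vector of per-gene FASTA paths, or
#'   `NULL` in simulation mode.
#' @param metadata Path to the metadata TSV, or `NULL` in simulation mode.
#' @param mask Optional path to a 0/1 column-mask file (applied to every
#'   gene alignment of matching width).
#' @param simulate A [multigene_config()] for simulation mode, or `NULL`.
#' @param seed Integer seed (simulation mode).
#' @param ref_gene Gene used for fragment characterization (default: first).
#' @param ref_id Reference record id for coordinate mapping; `NULL` uses
#'   the first record of the reference gene.
#' @param marker_16s Name of the slow marker gene for the
#'   threshold-divergence stage, if present.
#' @param label_field Metadata column holding the two-group partition.
#' @param ed_model Distance model for the comparative stage (`"p"`
#'   uncorrected, the default, or `"jc"`).
#' @param min_overlap Minimum comparable sites per pair.
#' @param gc_threshold Low-G+C split point.
#' @param s16_threshold 16S distance threshold.
#' @param z_crit Transfer-flag threshold.
#' @param alpha Significance level reported alongside slope tests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alignments = NULL, metadata = NULL, mask = NULL,
                            simulate = NULL, seed = 1,
                            ref_gene = NULL, ref_id = NULL,
                            marker_16s = "marker16S",
                            label_field = "clade_label",
                            ed_model = "p", min_overlap = 100L,
                            gc_threshold = 0.53, s16_threshold = 0.03,
                            z_crit = 3, alpha = 0.05) {
  if (is.null(simulate)) {
    if (is.null(alignments) || is.null(metadata)) {
      stop("file mode needs 'alignments' and 'metadata' paths")
    }
    missing <- alignments[!file.exists(alignments)]
    if (length(missing)) stop("alignment file(s) not found: ",
                              paste(missing, collapse = ", "))
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
    if (!is.null(mask) && !file.exists(mask)) stop("mask file not found: ", mask)
  } else {
    stopifnot(inherits(simulate, "multigene_config"))
  }
  stopifnot(ed_model %in% c("p", "jc"), min_overlap >= 1,
            gc_threshold > 0, gc_threshold < 1,
            s16_threshold > 0, s16_threshold < 1, z_crit > 0,
            alpha > 0, alpha < 1)
  structure(list(alignments = alignments, metadata = metadata, mask = mask,
                 simulate = simulate, seed = seed, ref_gene = ref_gene,
                 ref_id = ref_id, marker_16s = marker_16s,
                 label_field = label_field, ed_model = ed_model,
                 min_overlap = as.integer(min_overlap),
                 gc_threshold = gc_threshold, s16_threshold = s16_threshold,
                 z_crit = z_crit, alpha = alpha),
            class = "pipeline_config")
}

#' Run the full comparative-divergence pipeline
#'
#' Stages: (1) load or simulate the per-gene alignments and metadata;
#' (2) collection characterization (lengths, start/stop histograms,
#' G+C, genome-vs-gene G+C regression); (3) pairwise distance matrices
#' (uncorrected for the comparative stage, Jukes-Cantor for trees);
#' (4) neighbor-joining trees; (5) gene-vs-gene divergence comparison:
#' per-category regressions, slope-homogeneity F-tests, transfer
#' discontinuity flags, and the 16S-threshold divergence summary. Writes
#' `report.json`, a human-readable `report.txt`, newick trees, distance
#' TSVs and scatter plots into `outdir`, and logs dropped records to
#' `pipeline.log`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config, outdir = "multidiv_out") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "pipeline.log")
  cat("", file = logf)
  log_line <- function(level, ...) {
    msg <- paste0("[", level, "] ", ...)
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }

  # stage 1: inputs
  if (!is.null(config$simulate)) {
    log_line("INFO", "simulating multigene dataset, seed ", config$seed)
    sim <- simulate_multigene_dataset(config$simulate, seed = config$seed)
    alns <- sim$alignments
    metadata <- sim$metadata
    write_metadata_table(metadata, file.path(outdir, "metadata.tsv"))
    for (g in names(alns)) {
      write_aligned_fasta(alns[[g]], file.path(outdir, paste0(g, ".fasta")))
    }
    jsonlite::write_json(
      list(genome_tree = sim$truth$genome_tree,
           gene_trees = sim$truth$gene_trees,
           hgt_events = sim$truth$hgt_events,
           clade_rates = sim$truth$clade_rates,
           seed = sim$truth$seed),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    log_line("INFO", "reading ", length(config$alignments), " alignment(s)")
    alns <- lapply(config$alignments, read_aligned_fasta)
    if (is.null(names(alns))) names(alns) <- basename(config$alignments)
    metadata <- read_metadata_table(config$metadata)
  }
  mask <- NULL
  if (!is.null(config$mask)) mask <- read_column_mask(config$mask)

  genes <- names(alns)
  ref_gene <- if (is.null(config$ref_gene)) genes[[1L]] else config$ref_gene
  report <- list(config = list(ed_model = config$ed_model,
                               min_overlap = config$min_overlap,
                               gc_threshold = config$gc_threshold,
                               s16_threshold = config$s16_threshold,
                               z_crit = config$z_crit, alpha = config$alpha,
                               seed = config$seed))

  # stage 2: characterization on the reference gene
  ref_aln <- alns[[ref_gene]]
  ref_id <- if (is.null(config$ref_id)) ref_aln$ids[[1L]] else config$ref_id
  prof <- fragment_profile(ref_aln, ref_id)
  if (attr(prof, "n_excluded") > 0) {
    log_line("WARN", attr(prof, "n_excluded"), " all-gap record(s) excluded")
  }
  utils::write.table(prof, file.path(outdir, "fragment_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  starts <- position_histogram(prof, "start")
  stops <- position_histogram(prof, "stop")
  split <- gc_bimodal_split(prof$gc, config$gc_threshold)
  characterization <- list(
    gene = ref_gene, n_records = nrow(prof),
    mode_length = length_mode(prof$ungapped_length),
    start_top2 = starts$top2, start_spacing = starts$spacing,
    stop_top2 = stops$top2, stop_spacing = stops$spacing,
    mean_gc = split$mean_all, n_low_gc = split$n_low,
    low_gc_fraction = split$n_low / nrow(prof))
  # genome-vs-gene G+C regression per gene, when genome_gc is available
  if ("genome_gc" %in% names(metadata)) {
    gg <- stats::setNames(metadata$genome_gc, metadata$id)
    characterization$gc_regression <- lapply(genes, function(g) {
      a <- alns[[g]]
      gene_gc <- vapply(a$seqs, gc_content, numeric(1))
      ok <- a$ids[a$ids %in% names(gg)]
      genome_gene_gc_regression(gg[ok], gene_gc[ok])
    })
    names(characterization$gc_regression) <- genes
  }
  report$characterization <- characterization

  # stage 3: distances
  log_line("INFO", "computing distance matrices (", config$ed_model, " + jc)")
  use_mask <- function(a) if (!is.null(mask) && length(mask) == a$width) mask else NULL
  dmats <- lapply(alns, function(a) {
    distance_matrix(a, model = config$ed_model, mask = use_mask(a),
                    min_overlap = config$min_overlap)
  })
  for (g in genes) {
    write_distance_matrix(dmats[[g]], file.path(outdir, paste0(g, "_dist.tsv")),
                          format = "tsv")
  }

  # stage 4: neighbor-joining trees on JC distances
  trees <- list()
  for (g in genes) {
    jc <- distance_matrix(alns[[g]], model = "jc", mask = use_mask(alns[[g]]),
                          min_overlap = config$min_overlap)
    if (anyNA(jc$d[upper.tri(jc$d)])) {
      log_line("WARN", "gene ", g, ": undefined JC pairs, no tree built")
      next
    }
    trees[[g]] <- suppressWarnings(neighbor_joining(jc))
    write_tree_newick(trees[[g]], file.path(outdir, paste0(g, "_nj.nwk")))
  }

  # stage 5: comparative analysis over gene pairs
  labels <- stats::setNames(metadata[[config$label_field]], metadata$id)
  comp_genes <- setdiff(genes, config$marker_16s)
  pairs <- if (length(comp_genes) >= 2) utils::combn(comp_genes, 2, simplify = FALSE) else list()
  comparisons <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    pt <- build_pair_table(dmats[[pr[1L]]], dmats[[pr[2L]]], labels)
    if (attr(pt, "n_dropped_pairs") > 0) {
      log_line("WARN", key, ": ", attr(pt, "n_dropped_pairs"),
               " pair(s) dropped for undefined distances")
    }
    fits <- fit_group_regressions(pt)
    st <- slope_homogeneity_test(pt)
    # the discontinuity score asks whether the y-axis gene was transferred;
    # test both orientations so either gene of the pair can be the candidate
    hg_y <- hgt_discontinuity(pt, z_crit = config$z_crit)
    pt_flip <- build_pair_table(dmats[[pr[2L]]], dmats[[pr[1L]]], labels)
    hg_x <- hgt_discontinuity(pt_flip, z_crit = config$z_crit)
    utils::write.table(pt, file.path(outdir, paste0(key, "_pairs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    plot_path <- file.path(outdir, paste0(key, ".png"))
    tryCatch(save_pair_plot(pt, fits, pr[1L], pr[2L], plot_path),
             error = function(e) log_line("WARN", "plot failed: ",
                                          conditionMessage(e)))
    comparisons[[key]] <- list(
      gene_x = pr[1L], gene_y = pr[2L],
      fits = fits,
      slope_test = st[c("f_stat", "df_num", "df_den", "p_value")],
      slope_test_significant = st$p_value < config$alpha,
      slopes = as.list(st$slopes),
      hgt = list(
        candidate_y = c(gene = pr[2L],
                        hg_y[c("z", "z_iid", "se", "flagged", "n_inter")]),
        candidate_x = c(gene = pr[1L],
                        hg_x[c("z", "z_iid", "se", "flagged", "n_inter")]),
        flagged_gene = if (hg_y$flagged) pr[2L] else if (hg_x$flagged) pr[1L]
                       else NA_character_))
  }
  report$comparisons <- comparisons

  # threshold-divergence stage, when the slow marker is present
  if (config$marker_16s %in% genes && length(comp_genes) >= 1) {
    report$threshold_divergence <- lapply(comp_genes, function(g) {
      td <- threshold_divergence_analysis(dmats[[config$marker_16s]],
                                          dmats[[g]],
                                          threshold = config$s16_threshold)
      td[c("n_pairs", "max_marker_distance", "frac_above")]
    })
    names(report$threshold_divergence) <- comp_genes
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows", na = "null")
  writeLines(format_report(report), file.path(outdir, "report.txt"))
  log_line("INFO", "pipeline complete: ", outdir)
  invisible(report)
}

format_report <- function(report) {
  ch <- report$characterization
  out <- c("Comparative multigene divergence report",
           "=======================================",
           "",
           sprintf("Characterized gene: %s (%d records)", ch$gene, ch$n_records),
           sprintf("  mode fragment length : %d bases", as.integer(ch$mode_length)),
           sprintf("  top start positions  : %s (spacing %s)",
                   paste(ch$start_top2, collapse = ", "), ch$start_spacing),
           sprintf("  top stop positions   : %s (spacing %s)",
                   paste(ch$stop_top2, collapse = ", "), ch$stop_spacing),
           sprintf("  mean G+C             : %.1f%%", 100 * ch$mean_gc),
           sprintf("  low-G+C records      : %d (%.1f%%)", ch$n_low_gc,
                   100 * ch$low_gc_fraction))
  if (!is.null(ch$gc_regression)) {
    out <- c(out, "", "Genome vs gene G+C regression:")
    for (g in names(ch$gc_regression)) {
      r <- ch$gc_regression[[g]]
      out <- c(out, sprintf("  %-10s slope %.3f  intercept %.3f  R^2 %.3f  n %d",
                            g, r$slope, r$intercept, r$r_squared, r$n))
    }
  }
  for (key in names(report$comparisons)) {
    cmp <- report$comparisons[[key]]
    out <- c(out, "", sprintf("Comparison %s:", key))
    for (i in seq_len(nrow(cmp$fits))) {
      f <- cmp$fits[i, ]
      out <- c(out, sprintf("  %-8s y = %.3f x + %.3f  (R^2 %.3f, n %d)",
                            f$category, f$slope, f$intercept, f$r_squared, f$n))
    }
    out <- c(out,
             sprintf("  slope homogeneity: f = %.4g, P = %.4g%s",
                     cmp$slope_test$f_stat, cmp$slope_test$p_value,
                     if (isTRUE(cmp$slope_test_significant)) " (significant)" else ""),
             sprintf("  transfer discontinuity: z(y=%s) = %.2f, z(y=%s) = %.2f%s",
                     cmp$hgt$candidate_y$gene, cmp$hgt$candidate_y$z,
                     cmp$hgt$candidate_x$gene, cmp$hgt$candidate_x$z,
                     if (!is.na(cmp$hgt$flagged_gene))
                       paste0("  ** transfer signature: ",
                              cmp$hgt$flagged_gene, " **")
                     else ""))
  }
  for (g in names(report$threshold_divergence)) {
    td <- report$threshold_divergence[[g]]
    out <- c(out, "",
             sprintf("16S-threshold divergence for %s: %d pairs below threshold", g,
                     td$n_pairs),
             sprintf("  max marker distance %.3f; above cutoffs: %s",
                     td$max_marker_distance,
                     paste(sprintf("%s: %.0f%%", names(td$frac_above),
                                   100 * unlist(td$frac_above)), collapse = ", ")))
  }
  out
}

#' Scatter plot of a gene-vs-gene pair table
#'
#' Category-colored divergence scatter with per-category regression lines.
#'
#' @param pairtable Output of [build_pair_table()].
#' @param fits Output of [fit_group_regressions()].
#' @param xlab,ylab Axis labels (gene names).
#' @return A ggplot object.
#' @export
plot_pair_table <- function(pairtable, fits = fit_group_regressions(pairtable),
                            xlab = "gene X E_d", ylab = "gene Y E_d") {
  ggplot2::ggplot(pairtable, ggplot2::aes(x = .data$dX, y = .data$dY,
                                          colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(data = fits,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$category)) +
    ggplot2::labs(x = xlab, y = ylab, colour = "comparison") +
    ggplot2::theme_minimal()
}

save_pair_plot <- function(pairtable, fits, gx, gy, path) {
  p <- plot_pair_table(pairtable, fits, xlab = paste(gx, "E_d"),
                       ylab = paste(gy, "E_d"))
  ggplot2::ggsave(path, p, width = 6, height = 4.5, dpi = 120)
  invisible(path)
}
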