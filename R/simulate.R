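#' Specification of a simulated gene
#'
#' Describes one gene of a synthetic multigene dataset: its length,
#' stationary base frequencies, an overall rate scale, per-clade rate
#' multipliers, and an optional single inter-clade transfer event.
#'
#' @param name Gene name.
#' @param length Number of sites.
#' @param base_freqs Stationary frequencies (A, C, G, T), positive, summing
#'   to 1. Ignored for branches whose composition is tied to genome G+C
#'   (see [simulate_multigene_dataset()]).
#' @param rate Overall rate scale multiplying all branch lengths.
#' @param clade_rates Named numeric vector of per-clade rate multipliers
#'   (e.g. `c(A = 1, B = 2)`).
#' @param hgt Optional list `list(donor =, recipient =, depth =)` describing
#'   a single transfer event (see [graft_hgt()]).
#' @return A `gene_spec` list.
#' @export
gene_spec <- function(name, length, base_freqs = rep(0.25, 4), rate = 1,
                      clade_rates = c(A = 1, B = 1), hgt = NULL) {
  stopifnot(is.character(name), length >= 1)
  validate_freqs(base_freqs)
  if (any(clade_rates <= 0) || rate <= 0) stop("rates must be positive")
  if (!is.null(hgt)) {
    stopifnot(is.list(hgt), all(c("donor", "recipient", "depth") %in% names(hgt)))
  }
  structure(list(name = name, length = as.integer(length),
                 base_freqs = base_freqs, rate = rate,
                 clade_rates = clade_rates, hgt = hgt),
            class = "gene_spec")
}

validate_freqs <- function(pi) {
  if (length(pi) != 4 || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("base_freqs must be 4 positive values summing to 1")
  }
  invisible(pi)
}

#' Simulate a two-clade genome tree
#'
#' Draws a pure-birth (Yule) subtree for each of two clades, rescales each
#' to `clade_height` substitutions/site, and joins them by stem branches at
#' a root so that every root-to-tip path equals `root_height`. Tip labels
#' are `A01..` and `B01..`.
#'
#' @param n_per_clade Taxa per clade (>= 3).
#' @param seed Integer seed; identical seeds give identical trees.
#' @param clade_height Height of each clade subtree (substitutions/site).
#' @param root_height Root-to-tip path length; must exceed `clade_height`.
#' @return List with `tree` (ultrametric `phylo`), `labels` (named vector
#'   id -> "A"/"B"), `clade_height`, `root_height`.
#' @export
simulate_tree <- function(n_per_clade, seed = NULL, clade_height = 0.1,
                          root_height = 0.5) {
  if (n_per_clade < 3L) stop("need at least 3 taxa per clade")
  if (root_height <= clade_height) stop("root_height must exceed clade_height")
  if (!is.null(seed)) set.seed(seed)
  sub <- function(prefix) {
    tr <- ape::rphylo(n_per_clade, birth = 1, death = 0)
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * clade_height / h
    tr$tip.label <- sprintf("%s%02d", prefix, seq_len(n_per_clade))
    tr
  }
  ta <- sub("A"); tb <- sub("B")
  stem <- root_height - clade_height
  nwk <- sprintf("(%s:%.10f,%s:%.10f);",
                 sub_newick(ta), stem, sub_newick(tb), stem)
  tree <- ape::read.tree(text = nwk)
  labels <- stats::setNames(substr(tree$tip.label, 1, 1), tree$tip.label)
  list(tree = tree, labels = labels,
       clade_height = clade_height, root_height = root_height)
}

# newick string of a tree without the trailing semicolon, for composition
sub_newick <- function(tr) sub(";$", "", ape::write.tree(tr))

#' Graft a single-gene transfer into a genome tree
#'
#' Models a replacement transfer: for the transferred gene, the recipient
#' clade's subtree is detached from its genome position and re-attached on
#' the donor clade's stem lineage at height `depth * root_height` above the
#' tips. Ancient transfers (`depth` near 1) attach near the root and shrink
#' inter-clade gene distances least; recent transfers attach low and shrink
#' them most: after grafting, donor-recipient gene-tree path lengths are
#' `2 * depth * root_height` instead of `2 * root_height`.
#'
#' @param genome_tree Ultrametric two-clade `phylo` whose root splits the
#'   donor and recipient clades.
#' @param labels Named vector id -> clade label.
#' @param donor,recipient Distinct clade labels present in `labels`.
#' @param depth Attachment height as a fraction of root height, in (0, 1);
#'   must place the attachment on the donor stem (above the donor clade
#'   subtree) and above the recipient subtree height.
#' @return List with `tree` (the gene `phylo`) and `event` (donor,
#'   recipient, depth, attach_height).
#' @export
graft_hgt <- function(genome_tree, labels, donor, recipient, depth) {
  if (donor == recipient) stop("donor and recipient clades must differ")
  if (depth <= 0 || depth >= 1) stop("depth must be in (0, 1)")
  tips_d <- names(labels)[labels == donor]
  tips_r <- names(labels)[labels == recipient]
  if (length(tips_d) < 2L || length(tips_r) < 2L) {
    stop("unknown or singleton clade label: ", donor, " / ", recipient)
  }
  nde <- ape::node.depth.edgelength(genome_tree)  # distance from root
  H <- max(nde)
  mrca_d <- ape::getMRCA(genome_tree, tips_d)
  mrca_r <- ape::getMRCA(genome_tree, tips_r)
  sub_d <- ape::extract.clade(genome_tree, mrca_d)
  sub_r <- ape::extract.clade(genome_tree, mrca_r)
  if (!setequal(sub_d$tip.label, tips_d) || !setequal(sub_r$tip.label, tips_r)) {
    stop("clades are not monophyletic in the genome tree")
  }
  h_d <- H - nde[mrca_d]   # height of donor subtree root above tips
  h_r <- H - nde[mrca_r]
  h_att <- depth * H
  if (h_att <= h_d + 1e-12 || h_att <= h_r + 1e-12) {
    stop(sprintf(paste0("attachment height %.4f must exceed both clade ",
                        "subtree heights (donor %.4f, recipient %.4f); ",
                        "increase depth"), h_att, h_d, h_r))
  }
  nwk <- sprintf("(%s:%.10f,%s:%.10f);",
                 sub_newick(sub_d), h_att - h_d,
                 sub_newick(sub_r), h_att - h_r)
  list(tree = ape::read.tree(text = nwk),
       event = list(donor = donor, recipient = recipient, depth = depth,
                    attach_height = h_att))
}

#' Simulate sequences along a tree under F81
#'
#' Felsenstein-81: transition probability
#' `P(i -> j, t) = pi_j * (1 - exp(-beta t)) + [i == j] * exp(-beta t)`
#' with `beta = 1 / (1 - sum(pi^2))`, so branch lengths are expected
#' substitutions per site. With equal frequencies this reduces to
#' Jukes-Cantor. The root sequence is drawn from the stationary
#' frequencies. Optionally, per-branch frequencies are interpolated from
#' tip genome G+C values (`tip_gc`): each node's composition target is the
#' mean tip value over its descendants, with G and C (and A and T) split
#' evenly, coupling gene composition to genome composition along lineages.
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param spec A [gene_spec()]; `spec$rate` and `spec$clade_rates` scale
#'   branch lengths before simulation (a branch's clade is determined by
#'   the clade prefix shared by all its descendant tips, if any).
#' @param seed Optional integer seed.
#' @param tip_gc Optional named numeric vector of genome G+C per tip
#'   enabling composition coupling.
#' @param labels Optional named clade labels for the tips, required when
#'   `spec$clade_rates` are not all 1.
#' @return An [new_alignment()] with one ungapped sequence per tip.
#' @export
evolve_gene <- function(tree, spec, seed = NULL, tip_gc = NULL, labels = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(spec, "gene_spec"))
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  L <- spec$length
  bases <- c("A", "C", "G", "T")

  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length

  # clade of each branch: the unique clade label of its descendant tips
  scale <- rep(spec$rate, nrow(edge))
  if (!all(spec$clade_rates == 1)) {
    if (is.null(labels)) stop("labels required when clade_rates differ from 1")
    desc <- descendant_tips(tree)
    for (e in seq_len(nrow(edge))) {
      cl <- unique(labels[desc[[edge[e, 2L]]]])
      if (length(cl) == 1L && cl %in% names(spec$clade_rates)) {
        scale[e] <- scale[e] * spec$clade_rates[[cl]]
      }
    }
  }
  elen <- elen * scale

  # per-node composition targets
  if (!is.null(tip_gc)) {
    desc <- descendant_tips(tree)
    node_pi <- lapply(seq_len(nnode), function(nd) {
      gc <- mean(tip_gc[desc[[nd]]])
      c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    })
    root_pi <- node_pi[[ntip + 1L]]
  } else {
    node_pi <- NULL
    root_pi <- spec$base_freqs
  }

  states <- matrix(NA_integer_, nrow = nnode, ncol = L)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = root_pi)
  ord <- order(ape::node.depth.edgelength(tree)[edge[, 2L]])  # parents first
  for (e in ord) {
    par <- edge[e, 1L]; child <- edge[e, 2L]
    pi_b <- if (is.null(node_pi)) spec$base_freqs else node_pi[[child]]
    beta <- 1 / (1 - sum(pi_b^2))
    stay <- stats::runif(L) < exp(-beta * elen[e])
    s <- states[par, ]
    n_new <- sum(!stay)
    if (n_new > 0) s[!stay] <- sample.int(4L, n_new, replace = TRUE, prob = pi_b)
    states[child, ] <- s
  }
  seqs <- vapply(seq_len(ntip),
                 function(i) paste(bases[states[i, ]], collapse = ""),
                 character(1))
  names(seqs) <- tree$tip.label
  new_alignment(seqs)
}

# list: node index -> character vector of descendant tip labels
descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  ord <- rev(order(ape::node.depth.edgelength(tree)[tree$edge[, 2L]]))
  for (e in ord) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  desc
}

#' Default configuration for a synthetic multigene dataset
#'
#' Four linked genes on a shared two-clade genome phylogeny: a slow
#' ribosomal-like marker (`marker16S`), a transfer-bearing gene (`geneH`,
#' one inter-clade replacement transfer), a gene with clade-specific rate
#' variation (`geneD`, clade-B multiplier 2), and a clock-like control
#' (`geneK`). Genome G+C evolves as a bounded Brownian trait on the genome
#' tree and gene base composition tracks it.
#'
#' @param n_per_clade Taxa per clade.
#' @param clade_height,root_height Tree dimensions (substitutions/site).
#' @param genes List of [gene_spec()] objects.
#' @param gc_root,gc_sigma,gc_bounds Latent compositional-pressure trait
#'   parameters: root value, Brownian rate (per sqrt substitution/site),
#'   reflecting bounds.
#' @param gc_clade_sep Deterministic separation of the two clades' latent
#'   compositional pressure (applied as +/- half on the root stems),
#'   emulating the clade-structured bimodal G+C of real collections.
#' @param domains Named map clade label -> domain label.
#' @return A `multigene_config` list.
#' @export
multigene_config <- function(n_per_clade = 20,
                             clade_height = 0.1,
                             root_height = 0.5,
                             genes = list(
                               gene_spec("marker16S", 1500, rate = 0.25),
                               gene_spec("geneH", 1000,
                                         hgt = list(donor = "A", recipient = "B",
                                                    depth = 0.5)),
                               gene_spec("geneD", 1500,
                                         clade_rates = c(A = 1, B = 2)),
                               gene_spec("geneK", 1500)),
                             gc_root = 0.5, gc_sigma = 0.22,
                             gc_clade_sep = 0.3,
                             gc_bounds = c(0.25, 0.75),
                             domains = c(A = "Bacteria", B = "Archaea")) {
  stopifnot(n_per_clade >= 3, root_height > clade_height,
            all(vapply(genes, inherits, logical(1), "gene_spec")))
  names(genes) <- vapply(genes, `[[`, character(1), "name")
  structure(list(n_per_clade = n_per_clade, clade_height = clade_height,
                 root_height = root_height, genes = genes,
                 gc_root = gc_root, gc_sigma = gc_sigma,
                 gc_clade_sep = gc_clade_sep,
                 gc_bounds = gc_bounds, domains = domains),
            class = "multigene_config")
}

#' Simulate a linked multigene dataset with ground truth
#'
#' Generates a genome tree, a phylogenetically autocorrelated genome-G+C
#' trait, and one alignment per configured gene (applying per-clade rate
#' multipliers and any transfer event to that gene's tree), plus a
#' metadata table and a machine-readable truth record. All randomness
#' derives from `seed`: identical `(config, seed)` give identical output.
#'
#' @param config A [multigene_config()].
#' @param seed Integer master seed.
#' @return List with `alignments` (named list of `aln`), `metadata`
#'   (data.frame: id, clade_label, domain_label, genome_gc), `truth` (list:
#'   genome/gene newick strings, labels, rate multipliers, hgt events,
#'   genome_gc) and `trees` (named list of gene `phylo` objects).
#' @export
simulate_multigene_dataset <- function(config = multigene_config(), seed = 1) {
  stopifnot(inherits(config, "multigene_config"))
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, length(config$genes) + 2L)
  sim <- simulate_tree(config$n_per_clade, seed = subseeds[1L],
                       clade_height = config$clade_height,
                       root_height = config$root_height)
  set.seed(subseeds[2L])
  tip_gc <- brownian_trait(sim$tree, config$gc_root, config$gc_sigma,
                           config$gc_bounds, labels = sim$labels,
                           clade_sep = config$gc_clade_sep)
  # genome G+C as measured: the composition actually reached under the
  # lineage's compositional pressure at the genome-wide (neutral) rate
  genome_gc <- achieved_composition(sim$tree, tip_gc, rate = 1)

  alignments <- list(); trees <- list(); events <- list()
  for (k in seq_along(config$genes)) {
    spec <- config$genes[[k]]
    gtree <- sim$tree
    if (!is.null(spec$hgt)) {
      g <- graft_hgt(sim$tree, sim$labels, spec$hgt$donor, spec$hgt$recipient,
                     spec$hgt$depth)
      gtree <- g$tree
      events[[spec$name]] <- g$event
    }
    alignments[[spec$name]] <- evolve_gene(gtree, spec, seed = subseeds[k + 2L],
                                           tip_gc = tip_gc, labels = sim$labels)
    trees[[spec$name]] <- gtree
  }
  metadata <- data.frame(
    id = names(sim$labels),
    clade_label = paste0("cluster", unname(sim$labels)),
    domain_label = unname(config$domains[sim$labels]),
    genome_gc = round(unname(genome_gc[names(sim$labels)]), 4))
  truth <- list(
    genome_tree = ape::write.tree(sim$tree),
    gene_trees = lapply(trees, ape::write.tree),
    labels = sim$labels,
    clade_rates = lapply(config$genes, `[[`, "clade_rates"),
    gene_rates = vapply(config$genes, `[[`, numeric(1), "rate"),
    hgt_events = events,
    latent_gc_trait = tip_gc,
    genome_gc = genome_gc,
    seed = seed)
  list(alignments = alignments, metadata = metadata, truth = truth,
       trees = trees)
}

# Bounded Brownian motion of the latent compositional-pressure trait down
# the tree (reflection at the bounds). A deterministic clade offset
# (+/- clade_sep/2 on the two root stems, by descendant clade label)
# reproduces the clade-structured bimodal composition seen in real
# collections.
brownian_trait <- function(tree, root_value, sigma, bounds,
                           labels = NULL, clade_sep = 0) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  vals <- rep(NA_real_, nnode)
  root <- ntip + 1L
  vals[root] <- root_value
  desc <- if (clade_sep != 0) descendant_tips(tree) else NULL
  clades <- if (!is.null(labels)) sort(unique(labels)) else NULL
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2L]])
  for (e in ord) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    drift <- NA_real_
    if (par == root && clade_sep != 0) {
      cl <- unique(labels[desc[[child]]])
      if (length(cl) == 1L && length(clades) == 2L) {
        drift <- if (cl == clades[1L]) clade_sep / 2 else -clade_sep / 2
      }
    }
    # the clade regime shift is a fixed property of the clade (no noise on
    # the stem); Brownian wobble accumulates within clades
    x <- if (!is.na(drift)) vals[par] + drift else
      vals[par] + stats::rnorm(1L, 0, sigma * sqrt(tree$edge.length[e]))
    # reflect into bounds
    rng <- bounds[2L] - bounds[1L]
    x <- bounds[1L] + rng - abs(((x - bounds[1L]) %% (2 * rng)) - rng)
    vals[child] <- x
  }
  stats::setNames(vals[seq_len(ntip)], tree$tip.label)
}

#' Achieved G+C composition under lineage-specific pressure
#'
#' The expected G+C content reached at each tip when sites evolve under
#' F81 whose frequencies track a per-lineage compositional target (the
#' mean latent trait of each branch's descendant tips, as in
#' [evolve_gene()]). Because composition can only change through
#' substitution, the achieved value lags the latent pressure; this is the
#' quantity a genome-wide G+C measurement reports.
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param tip_gc Named latent trait values per tip.
#' @param rate Overall rate scale applied to branch lengths.
#' @return Named numeric vector of expected tip G+C fractions.
#' @export
achieved_composition <- function(tree, tip_gc, rate = 1) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  desc <- descendant_tips(tree)
  target <- vapply(desc, function(tp) mean(tip_gc[tp]), numeric(1))
  comp <- rep(NA_real_, nnode)
  root <- ntip + 1L
  comp[root] <- target[root]
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2L]])
  for (e in ord) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    gc_t <- target[child]
    pi_b <- c((1 - gc_t) / 2, gc_t / 2, gc_t / 2, (1 - gc_t) / 2)
    beta <- 1 / (1 - sum(pi_b^2))
    w <- exp(-beta * tree$edge.length[e] * rate)
    comp[child] <- comp[par] * w + gc_t * (1 - w)
  }
  stats::setNames(comp[seq_len(ntip)], tree$tip.label)
}

#' Default configuration for a synthetic fragment database
#'
#' Emulates an amplicon sequence collection: fragments cut from primer
#' windows on an ungapped reference, a fraction of records retaining
#' untrimmed primer bases (offsetting starts by the forward primer length
#' and stops by the reverse primer length), and a two-component
#' (bimodal) G+C mixture.
#'
#' @param n Number of fragment records.
#' @param ref_length Reference gene length (bases).
#' @param windows List of `list(start, stop, weight)` primer windows
#'   (1-based closed reference coordinates).
#' @param untrimmed_frac Fraction of records retaining primer bases.
#' @param primer_fwd,primer_rev Forward/reverse primer lengths (bases).
#' @param gc_means,gc_sds,gc_weights Two-component G+C mixture parameters
#'   (low component first).
#' @return A `fragment_config` list.
#' @export
fragment_config <- function(n = 1000,
                            ref_length = 870,
                            windows = list(list(start = 114, stop = 437,
                                                weight = 0.85),
                                           list(start = 19, stop = 850,
                                                weight = 0.15)),
                            untrimmed_frac = 0.3,
                            primer_fwd = 18, primer_rev = 17,
                            gc_means = c(0.47, 0.61),
                            gc_sds = c(0.025, 0.025),
                            gc_weights = c(0.29, 0.71)) {
  stopifnot(n >= 1, ref_length > 1,
            abs(sum(gc_weights) - 1) < 1e-9,
            untrimmed_frac >= 0, untrimmed_frac <= 1)
  for (w in windows) {
    if (w$start < 1 || w$stop > ref_length || w$start > w$stop) {
      stop("primer window outside reference: ", w$start, "-", w$stop)
    }
    if (w$start - primer_fwd < 1 || w$stop + primer_rev > ref_length) {
      stop("untrimmed primer window outside reference: ",
           w$start - primer_fwd, "-", w$stop + primer_rev)
    }
  }
  structure(list(n = n, ref_length = ref_length, windows = windows,
                 untrimmed_frac = untrimmed_frac, primer_fwd = primer_fwd,
                 primer_rev = primer_rev, gc_means = gc_means,
                 gc_sds = gc_sds, gc_weights = gc_weights),
            class = "fragment_config")
}

#' Simulate a fragment database with ground truth
#'
#' Builds a reference-length alignment containing a designated reference
#' record (`REF`, spanning all columns) and `n` fragment records, each
#' occupying one primer window (offset when its primers are untrimmed) and
#' filled i.i.d. at a G+C value drawn from the configured two-component
#' mixture. Columns outside a fragment's span are gaps.
#'
#' @param config A [fragment_config()].
#' @param seed Integer seed.
#' @return List with `alignment` (an `aln`; the reference record is
#'   `REF`), `ref_id`, and `truth` (data.frame: id, window start/stop as
#'   deposited, untrimmed flag, mixture component, drawn gc).
#' @export
simulate_fragment_database <- function(config = fragment_config(), seed = 1) {
  stopifnot(inherits(config, "fragment_config"))
  set.seed(seed)
  L <- config$ref_length
  bases <- c("A", "C", "G", "T")
  ref <- paste(sample(bases, L, replace = TRUE,
                      prob = c(0.23, 0.27, 0.27, 0.23)), collapse = "")
  wts <- vapply(config$windows, `[[`, numeric(1), "weight")
  win_idx <- sample.int(length(config$windows), config$n, replace = TRUE,
                        prob = wts)
  untrimmed <- stats::runif(config$n) < config$untrimmed_frac
  comp <- sample.int(2L, config$n, replace = TRUE, prob = config$gc_weights)
  gc <- stats::rnorm(config$n, config$gc_means[comp], config$gc_sds[comp])
  gc <- pmin(pmax(gc, 0.05), 0.95)

  ids <- sprintf("frag%05d", seq_len(config$n))
  seqs <- character(config$n)
  starts <- integer(config$n); stops <- integer(config$n)
  for (i in seq_len(config$n)) {
    w <- config$windows[[win_idx[i]]]
    s <- w$start; e <- w$stop
    if (untrimmed[i]) {
      s <- s - config$primer_fwd
      e <- e + config$primer_rev
    }
    starts[i] <- s; stops[i] <- e
    len <- e - s + 1L
    frag <- sample(bases, len, replace = TRUE,
                   prob = c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2,
                            (1 - gc[i]) / 2))
    seqs[i] <- paste0(strrep("-", s - 1L), paste(frag, collapse = ""),
                      strrep("-", L - e))
  }
  aln <- new_alignment(stats::setNames(c(ref, seqs), c("REF", ids)))
  truth <- data.frame(id = ids, start = starts, stop = stops,
                      untrimmed = untrimmed, component = comp, gc = gc)
  list(alignment = aln, ref_id = "REF", truth = truth)
}
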