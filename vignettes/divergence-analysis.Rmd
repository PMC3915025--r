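---
title: "Comparative multigene divergence analysis with multidiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative multigene divergence analysis with multidiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

`multidiv` implements a comparative framework for asking whether the genes
of a multigene system share one evolutionary history. Its unit of data is
a set of aligned nucleotide sequences per gene, sharing record identifiers
across genes (one genome per identifier), together with a two-group
partition of the genomes (phylogenetic clusters, or domains). The
analysis proceeds in five stages:

1. **Collection characterization** — fragment lengths, start/stop
   positions in reference-gene coordinates, G+C content and its
   bimodality, and the regression of gene G+C on genome G+C.
2. **Pairwise evolutionary distances** (`E_d`) — the uncorrected
   proportion of differing sites over mask-included columns where both
   sequences have unambiguous bases. Jukes–Cantor corrected distances,
   `d = -(3/4) ln(1 - (4/3) p)`, are computed for tree building.
3. **Neighbor-joining trees** from the corrected distances.
4. **Gene-versus-gene divergence comparison** — matched taxon-pair
   scatter of `E_d` for two genes, partitioned into intra-group and
   inter-group comparisons, with per-category regressions, a
   homogeneity-of-slopes F-test, and a one-sided discontinuity score that
   flags single-gene horizontal transfer.
5. **Divergence-threshold analysis** — how divergent a fast marker gene
   can be among genome pairs that are nearly identical in a slow marker
   (16S rRNA below a 3% dissimilarity proxy for conspecificity).

The package also contains a synthetic multigene generator used to
validate every stage against known ground truth.

## Distances: conventions and parameters

- **Pairwise deletion.** A site contributes to a pair's distance only if
  both residues are unambiguous bases (A/C/G/T) and the column is
  mask-included. Amplicon collections are fragment-heavy with wildly
  varying spans, so complete deletion would leave no columns; pairwise
  deletion keeps every overlapping pair usable.
- **`min_overlap` (default 100 sites).** Pairs sharing fewer comparable
  sites are *undefined*, never zero. With modal fragment lengths around
  320 bases, 100 sites is a conservative floor below which a proportion
  estimated from so few Bernoulli trials is too noisy to regress on.
- **Saturation.** The Jukes–Cantor transform is undefined at `p >= 0.75`
  and such pairs are marked undefined. The comparative stage deliberately
  uses *uncorrected* distances: the gene-versus-gene scatter is a
  descriptive comparison of observed divergence, and correction near
  saturation amplifies noise asymmetrically across genes.
- **Ambiguity codes** are retained in the data model but treated as
  missing by distances and G+C (their base assignment is unknown; any
  imputation would bias composition).
- **Gap conventions.** `-` and `.` are both gaps (database exports mix
  the two), `U` is normalized to `T`, case is folded on ingest.

Reference coordinates are 1-based over the ungapped reference record,
position 1 being the first base of the start codon; fragment start/stop
are closed. A fragment whose first aligned residue falls in a reference
insertion takes the next reference base as its start (and symmetrically
the previous one as its stop) — positions are then always statements
about the reference frame.

## Characterization details

`length_mode()` breaks frequency ties toward the smaller value so reports
are deterministic. `position_histogram()` returns exact integer counts
plus the two most frequent positions and their spacing: when a fraction
of deposited sequences retain untrimmed primers, deposited starts pile up
at the primer site and at one forward-primer-length upstream of it, so
the top-2 spacing reads out the primer length directly. The G+C split
counts values `<= 0.53` inclusively as the low bin. Blank metadata cells
are explicit missing values and every tabulation reports a `missing`
category, so dropped information is always visible.

## The slope-homogeneity test

For two comparison categories the test contrasts a full model (separate
slope and intercept per category) with a reduced model (common slope,
separate intercepts):

```
F = (RSS_reduced - RSS_full) / (RSS_full / (n - 4)),  df = (1, n - 4)
```

computed by direct RSS arithmetic on the two `lm()` fits. Regressions
keep their intercepts: divergence comparisons between genes with
different saturation behavior produce gene-specific offsets that an
origin-forced line would fold into the slope.

**Limitation: pairwise points are not independent.** With `m` taxa per
group the regression sees `m(m-1)/2` points but only `O(m)` independent
branches; points sharing a taxon (and, worse, a deep branch) are strongly
correlated. The F-test treats the points as independent — as this style
of divergence-plot analysis conventionally does — so its p-values are
anti-conservative on real or tree-simulated data. In practice this means
(i) the test's size is exact on independent points (the package's
calibration checks this at `alpha = 0.05` over a thousand replicates),
but (ii) on tree data even equal-rate gene pairs are declared
"significant" in a large share of datasets. Conclusions about rate
variation should therefore rest on the *magnitude* of the slope ratio,
not the p-value alone; the validation suite asserts that equal-rate
genes give slope ratios near 1 while a gene evolved twice as fast in one
clade gives a ratio near 2.

## The transfer-discontinuity score

A single-gene transfer between the two groups makes that gene's
inter-group divergence smaller than the within-group trend predicts. The
score fits one pooled OLS line to the union of the two intra-group point
clouds and takes the mean residual of the inter-group points below it.

Standardizing that mean residual needs care. Dividing by
`sigma / sqrt(n_inter)` (`sigma` = residual SD of the pooled fit)
treats inter residuals as independent, which they are not, for two
reasons:

- every inter pair's path crosses the same two stem lineages, so the
  realized substitutions of each gene on those stems shift *all* inter
  points together — a site-sampling noise component of variance about
  `p(1-p)/L` per gene that does not shrink as pairs accumulate;
- the inter points necessarily sit beyond the intra x-range, so the
  fitted line's extrapolation error adds further shared variance.

`hgt_discontinuity()` reports the naive standardization as `z_iid` and
flags on a calibrated `z` whose squared standard error is the sum of the
intra-fit prediction variance at the inter points (including the
`1/n_inter` averaging term) and the shared-path site-sampling variance of
both genes, `p(1-p)/L` evaluated at the mean inter distance using the
pair table's compared-site counts. The flag is one-sided
(`z <= -z_crit`, default `z_crit = 3`): only a *deficit* of inter-group
divergence is the transfer signature; an excess has other explanations.
On no-transfer simulations the naive score flags roughly a third of
datasets while the calibrated score holds the false-positive rate at the
nominal level, without any change to the threshold; a grafted transfer
shifts the inter cloud by many multiples of either standard error and is
flagged by both.

The score assumes the two genes share clade-homogeneous *relative* rates:
a gene with a clade-specific rate multiplier (like the simulated `geneD`)
violates the pooled-line assumption and belongs in the slope test, not
the discontinuity test.

## The synthetic generator

The generator is first-class, tested code: it is the source of every
ground-truth validation in the package.

- **Genome tree.** Two pure-birth clades of `n_per_clade >= 3` taxa,
  each rescaled to `clade_height` (default 0.1 substitutions/site),
  joined by stems so every root-to-tip path is `root_height` (default
  0.5). The defaults put within-clade divergence in the regime where
  uncorrected and corrected distances nearly agree, and between-clade
  divergence deep enough to show saturation — the structure the
  comparative analysis is designed for.
- **Sequence evolution** is Felsenstein-81:
  `P(i -> j, t) = pi_j (1 - e^(-beta t)) + [i = j] e^(-beta t)`,
  `beta = 1 / (1 - sum(pi^2))`, so branch lengths are expected
  substitutions per site; with equal frequencies this is exactly
  Jukes–Cantor, which makes the simulator's calibration checkable in
  closed form (`E[p] = (3/4)(1 - e^(-4t/3))`). F81 is the minimal model
  whose composition can be steered; richer models would add parameters
  the analyses never exercise.
- **Rate structure.** Each gene has an overall rate and per-clade
  multipliers applied to branch lengths before simulation (a branch
  belongs to a clade when all its descendant tips do). The default
  dataset gives `geneD` a clade-B multiplier of 2 — the rate-variation
  scenario — and `marker16S` an overall rate of 0.25, a slow ribosomal
  marker.
- **Transfer events** are modeled as replacement transfers: for the
  affected gene the recipient clade's subtree is re-attached on the
  donor stem at height `depth * root_height`. Inter-clade path lengths
  for that gene become `2 * depth * root_height` instead of
  `2 * root_height`, so `depth` near 1 is an ancient transfer (smallest
  discontinuity) and the effect is monotone in `depth`. The default
  `geneH` event uses `depth = 0.5`.
- **G+C coupling.** A latent compositional-pressure trait evolves on the
  genome tree: a deterministic regime shift of `+/- gc_clade_sep / 2`
  (default 0.3 total) on the two stems — composition structure between
  major clades is a fixed property of the groups, mirroring the
  clade-associated low- and high-G+C fractions of real collections —
  plus Brownian wobble (`gc_sigma = 0.22` per sqrt substitution/site)
  reflected into `[0.25, 0.75]` within clades. Each branch of a gene
  tree uses F81 frequencies targeting the mean latent value of its
  descendant tips (G/C and A/T split evenly). Because composition can
  only move through substitution, the metadata's `genome_gc` is the
  *achieved* composition — the closed-form propagated expectation of the
  same process at the genome-wide rate — which is what a genome G+C
  measurement reports. Gene G+C then differs from genome G+C only by
  site-sampling noise, producing the strong linear genome-gene G+C
  relationship with slope near 1 that characterizes real multigene
  collections.
- **Fragment databases.** Fragments are cut from configurable primer
  windows on an ungapped reference (defaults: window 114–437, so the
  modal ungapped length is 324; a 15% minority of near-full-length
  records), with an untrimmed fraction (default 0.3) offsetting starts
  by the 18-base forward primer and stops by the 17-base reverse primer,
  and a two-component G+C mixture (means 0.47/0.61, weights 0.29/0.71).
  Each record's true window, trimming state and mixture component are
  emitted as ground truth.
- **Determinism.** All randomness flows from one master seed;
  per-component seeds are derived from it, so identical `(config, seed)`
  give byte-identical output.

**What the generator does not emulate.** No indels (multigene alignments
are gap-free; real alignments lose columns to the homology mask instead),
no within-gene recombination, no codon structure or selection, no more
than two clades, and fragment records are i.i.d. draws rather than
phylogenetically related. Passing the validation suite therefore shows
the *methods* behave as designed under the stated statistical structure;
it does not certify behavior under alignment error or recombination.

## Numerical and degenerate-case choices

- Neighbor joining requires a fully defined matrix and at least 3 taxa;
  undefined pairs raise an error telling the caller to prune or lower
  `min_overlap` expectations, rather than silently imputing. Negative NJ
  branch lengths are clamped to zero with the total deficit reported.
- Q-criterion ties (fully symmetric matrices) resolve deterministically;
  the final join is emitted as a trifurcation (unrooted convention).
- `F` is computed as `max(0, RSS_red - RSS_full) / (RSS_full / df)`:
  floating-point cancellation can make the bracketed difference a tiny
  negative number when the categories are identical, where the correct
  answer is exactly 0.
- A zero-residual pooled fit with zero mean inter residual gives
  `z = 0`; with a nonzero residual it gives a signed infinity rather
  than NaN.
- Mode ties break to the smallest value; top-2 histogram ties break to
  the smaller position.
- The 16S threshold is strict (`< 0.03` dissimilarity, the 97%-identity
  species proxy); the G+C split is inclusive (`<= 0.53`).

## Validation problem sizes

The test suite validates each stage at sizes chosen to keep the whole
suite around a minute while leaving the statistical checks well-powered:
distance scans on 1,000 random pairs; NJ on 50 random 8-taxon additive
matrices and 20 Jukes–Cantor simulations of 16 taxa x 5,000 sites;
simulator calibration at 50 replicates of 10,000 sites; slope-test size
on 1,000 independent replicates; rate-multiplier recovery on 20
replicates of 20 taxa/clade x 2,000 sites; transfer detection on 100
transfer and 100 no-transfer replicates of 10 taxa/clade x 800 sites;
fragment recovery on a 5,000-record database. `scripts/acceptance.R`
re-runs the full analysis from scratch at the default study conditions
and writes every headline quantity as JSON.

## Known limitations

- All pairwise-point analyses inherit the non-independence caveat above.
- The discontinuity score detects *presence* of a single-gene transfer
  between the two groups; it does not infer direction, donor lineage, or
  reconcile tree topologies.
- `E_d` comparisons assume the two matrices share enough defined pairs;
  heavily fragmented inputs with little overlap degrade to fewer usable
  points (always logged, never silent).
- The NJ stage reports whatever topology the corrected distances
  support; with shallow clades and finite genes, near-zero internal
  branches are not expected to be recovered.
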