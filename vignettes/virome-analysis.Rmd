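---
title: "Quantitative lung virome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative lung virome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

viromescope is a reads-to-ecology pipeline for quantitative DNA virome
analysis of low-biomass respiratory samples, built around a synthetic-data
generator so that every stage can be exercised and validated without access
to raw sequencing data. This vignette explains the underlying models, the
parameters that matter, the choices made where the design was genuinely
open, and what the validation suite does and does not establish.

## The quantification model

Shotgun reads from acellular bronchoalveolar lavage fluid are dominated by
host genomic DNA; the viral signal is a small minority of reads mapped
against a reference database of viral genomes. The pipeline processes each
sample as:

1. **Quality trimming** — bases are trimmed from both read ends while their
   Phred quality is below `phred_min` (default 10); trimmed reads shorter
   than `min_length` (default 50 bp) are dropped.
2. **De-duplication** — exact-sequence duplicates (PCR/optical copies) are
   removed, keeping first occurrences. De-duplication is sequence-based,
   not alignment-based, because it precedes mapping.
3. **Host decontamination** — reads with any hit to the host genome at
   $\geq 95\%$ identity are removed. The number of reads surviving all
   three stages is the sample's *decontaminated read count*, the
   normalising denominator for abundances.
4. **Mapping** — the built-in mapper indexes all reference `seed_k`-mers
   (default 21) and aligns each read ungapped at every exact-seed diagonal
   on both strands, scoring percent identity as matching bases over the
   aligned (overlapping) length. Each read's best hit (highest identity,
   then longest alignment, ties broken by lexicographically smallest
   `(genome_id, start)`) is flagged; only best hits contribute to coverage,
   so one read never counts towards two genomes. External alignments can be
   supplied as SAM instead; identity is then
   $100\,(L_{aln}-\mathrm{NM})/L_{aln}$ over non-clipped bases, with a
   fallback to `=`/`X` CIGAR operators when the NM tag is absent. SAM's
   1-based coordinates are converted to the package's single internal
   convention, 0-based half-open.
5. **Presence rule** — a viral population is *present* in a sample when
   reads at $\geq 95\%$ identity cover at least one **consecutive** run of
   `min_run` genome positions (default 200 bp, inclusive boundary).
   Disjoint covered islands do not add up: two 150 bp islands are absent.
   The run is computed on the union coverage of qualifying best hits.
6. **Abundance** — the median read depth over *all* genome positions
   (zeros included; an even-length median averages the two central order
   statistics), scaled per million decontaminated reads. Populations
   failing the presence rule get abundance 0 before any matrix is built.
   Whether the median should instead be taken over covered positions only
   is genuinely ambiguous; the default penalises fragmentary coverage,
   which is the stricter and more common convention in quantitative virome
   work, and `zeros = FALSE` exposes the alternative.
7. **Host aggregation** — phage abundances are summed by the host genus
   (or phylum) of their reference genome; eukaryotic viruses form their own
   class. Aggregation conserves each sample's total mass exactly.

The per-million scale is an arbitrary choice — any fixed scale cancels when
rows are closed to relative abundances, which is the default matrix mode.

## Ecological and statistical machinery

* **Alpha diversity**: richness $S$, Shannon $H=-\sum p_i \ln p_i$ in nats,
  and Pielou $J = H/\ln S$ ($J = 0$ for $S \le 1$), so $J \le 1$ with
  equality at uniform composition.
* **Beta diversity**: Bray–Curtis $d(x,y)=\sum|x_i-y_i|/\sum(x_i+y_i)$
  (via vegan), with an explicit sample-exclusion list standing in for
  multivariate outlier removal. Metabolite intensities are autoscaled
  (per-feature mean 0, sample SD 1) and, because autoscaling produces
  negative values, min-shifted per feature to non-negativity before
  Bray–Curtis; Euclidean distance on the autoscaled data is used for the
  Mantel regressions.
* **Ordination**: classical PCoA (Gower double-centering of
  $-\tfrac12 D^2$). Only positive-eigenvalue axes are retained; negative
  eigenvalues are reported. Axis signs are fixed so the largest-magnitude
  loading on each axis is positive, making coordinates reproducible across
  platforms.
* **Permutation fits**: `factor_fit()` measures
  $r^2 = 1 - SS_{within}/SS_{total}$ of group centroids over the first
  `n_axes` (default 2, matching 2-D ordination plots) coordinates;
  `vector_fit()` regresses a continuous variable on those coordinates and
  reports $r^2$ plus the unit coefficient direction. `mantel_test()`
  Spearman-correlates distance upper triangles, permuting one matrix's
  rows and columns simultaneously. All permutation p-values use the
  add-one estimator $p = (1+\#\{stat_{perm} \ge stat_{obs}\})/(1+B)$,
  which never returns 0 and has floor $1/(B+1)$; defaults are $B=9999$
  for fits and Mantel tests and $B=1000$ for differential abundance.
  Bonferroni correction is applied per declared family (the vector-fit
  family, the Mantel family) via `adjust_fits()`.
* **Two-group tests**: Mann–Whitney U uses exact enumeration for combined
  samples of at most 12 without ties, otherwise the normal approximation
  with tie and continuity correction (the two branches agree to within
  about 0.015 at $n=6+6$, the worst case sitting at mid-range p-values).
  The 2×2 chi-squared test uses the *uncorrected* Pearson statistic by
  default — this reproduces printed cohort-table p-values exactly — with
  Yates correction behind a flag.
* **Differential abundance** (`metastats_test()`): a two-part procedure.
  Features detected in at least `sparse_min_nonzero` (default 4) samples
  get an unequal-variance t statistic with a label-permutation p-value,
  two-sided on $|t|$; sparser features get Fisher's exact test on the
  2×2 detection-by-group table; features undetected everywhere are `NA`.
  The permutation p is invariant to feature scaling, so relative
  abundances and counts give identical inference.
* **Association networks**: rows are closed to proportions (making the
  CLR transform exactly invariant to per-sample scale), a pseudocount
  (default half the smallest non-zero proportion) is added, and each
  feature is L1-regressed on all others (Meinshausen–Bühlmann
  neighborhood selection, glmnet backend, standardised predictors). Edges
  are OR-symmetrised by default. When no penalty is given, a 10-value
  log-spaced grid from $\lambda_{max}=\max|X^\top y|/n$ down two decades
  is fitted and the penalty minimising the extended BIC
  ($\gamma = 0.5$) summed over the per-feature regressions is chosen. An
  edge-count knee heuristic was considered first and rejected: on null
  data the largest jump in edge count sits at the dense end of the grid,
  so the knee selects spurious edges, while eBIC keeps null graphs empty
  (mean false edges $\le 1$ at $n=200$, $p=10$) and still recovers planted
  chains. Clusters are connected components with at least two features;
  isolated features are noise.

## What the synthetic generator emulates

The generator reproduces the *structure* of a two-group lower-airway
virome study: 20 vs 10 samples, a few hundred candidate viral populations
with sparse detection, host contamination, planted group differences in
viral composition and diversity, planted metabolite shifts, and a
bacteriome with *no* group effect.

* **Reference database**: 200 genomes of 1.5–8 kb with uniform base
  composition; host phyla drawn at 37% Proteobacteria, 36% Firmicutes,
  23% Actinobacteria, 3% Bacteriodetes, 1% Fusobacteria, with genus
  weights concentrated on dominant airway genera (78% of Actinobacteria
  phages infecting *Propionibacterium*, 60% of Firmicutes phages
  *Streptococcus*). About 1% of genomes are eukaryotic viruses.
* **Communities**: per-genome log-means $\mu_j \sim N(0,1)$ shared across
  samples give a consistent composition; each sample draws
  $x_{sj} = \exp(\mu_j + \sigma_g \varepsilon_{sj})$ and keeps a
  Poisson-distributed number of taxa (mean 35 for smokers, 60 for
  nonsmokers — calibrated only to "~250 populations across 30 samples" as
  an order of magnitude). Presence is an *occupancy* draw, uniform and
  independent of conditional abundance; this is deliberate, because
  abundance-weighted sparsification truncates sparse communities to their
  upper tail and makes the low-richness group *more* even, cancelling the
  evenness contrast the design is supposed to plant. With occupancy
  sampling, the dispersion contrast $\sigma = 2.0$ (smokers) vs $0.8$
  (nonsmokers) maps directly onto lower Shannon and Pielou values in
  smokers; the values were chosen once so that the planted effect is
  unambiguous at the study's sample sizes, as in the motivating data.
* **Planted fold changes**: by default *Lactobacillus* and *Gardnerella*
  phages 10-fold enriched in nonsmokers and *Prevotella* phages 2-fold in
  smokers. Planted taxa have their baseline log-mean deflated by
  $\ln(\text{fold})$ so that enrichment restores them to typical
  abundance: the planted contrast is a rare-taxon fold change (the
  expected group mean ratio still equals the fold), and the enriched
  group's evenness is not distorted by a dominant planted block.
  `deflate_planted = FALSE` plants dominance instead.
* **Reads**: 50,000 per sample, 150 bp, drawn from genomes with
  probability proportional to abundance × length at uniform positions and
  random strand; substitution errors at 0.5% (no indels, so the ungapped
  mapper is exact); 30% of reads from a 100 kb random host genome; 5%
  exact duplicate copies. Each sample's reads derive from a per-sample
  sub-seed, so streaming samples one at a time reproduces a joint run
  byte-for-byte. The host fraction is far below the real-data regime
  (where well under 1% of reads are viral); that regime is reachable by
  setting `host_contamination_fraction` near 1, but the validation suite
  runs at 30% so that per-sample viral depth supports recovery checks at
  desk scale.
* **Omics**: metabolites and cytokines are Gaussian log-intensities with
  a mean shift (2 SD and 1 SD respectively, on 70% of features) added to
  the smoker group; the bacteriome is a log-normal relative-abundance
  matrix with no group effect. A dropout parameter feeds the ≥50%
  presence reporting filter (inclusive boundary: 15/30 is kept, 14/30 is
  not).

### What the generator does *not* emulate

Realistic read-quality profiles, indels and platform error models;
strain-level microdiversity and database incompleteness; compositional
coupling between occupancy and abundance; batch effects; covariate
structure (age, race) correlated with group. Passing tests therefore show
that the pipeline's algorithms are correct and calibrated under the
designed data-generating process, not that the pipeline is robust to every
artefact of real sequencing data — real data should enter through the SAM
interface after a production aligner.

## Validation suite and problem sizes

The test suite validates each stage against independent oracles: a
brute-force longest-run scanner for the presence rule (1,000 random
coverage tracks), hand double-centering for PCoA (to $10^{-9}$), an exact
coordinate-descent lasso for the network regressions, hand-computed
3-leaf UPGMA trees, and vegan's `envfit`/`mantel` statistics for the
permutation fits. Parameter recovery runs the full reads-to-abundance
pipeline on 30 samples × 50k reads against 200 genomes (per-sample
Spearman correlation between estimated and designed abundances ≥ 0.9;
presence sensitivity ≥ 0.95 for populations at ≥ 1% abundance). Type-I
calibration uses 200 null replicates per test at 199–499 permutations;
planted-effect power uses 50 design seeds against one fixed database.
These sizes were chosen so the whole suite completes in a few minutes on a
single core while keeping Monte-Carlo error well inside the asserted
margins.

Two power limitations are worth knowing (the acceptance script reports
the corresponding rates). First, a 10-fold enrichment of a genus
represented by only a handful of database genomes (e.g. *Gardnerella* at
its ~3% genus weight) is detected at genus level in far fewer designs
than the larger *Lactobacillus* genus — the genus abundance is the sum
of very few occupancy draws and is intrinsically noisy. Second, the
2-fold *Prevotella* plant is close to undetectable at $n = 20+10$ with a
rare-taxon design; it is kept in the defaults for structural
faithfulness, not as a power target. Similarly, a 2 SD metabolite shift
under a Bonferroni family of ~80 features is detected for a majority,
but not nearly all, of the shifted features at these sample sizes.

## Numerical and convention choices

* Identity thresholds and the presence run length are inclusive
  ($\geq 95.0$, $\geq 200$).
* Coordinates are 0-based half-open internally; SAM input is converted.
* Shannon entropy in nats, matching $J = H/\ln S$.
* Permutation tests are seeded explicitly; every random operation in the
  pipeline derives its seed from the single configured master seed, and
  re-running a configuration reproduces identical artifacts.
* UPGMA sorts labels lexicographically before clustering so exact
  distance ties resolve deterministically; trees are ultrametric with
  two leaves at distance $d$ joined at height $d/2$. The linkage choice
  itself (average) is a convention for abundance dendrograms.
* Degenerate inputs are defined, not crashed: all-zero diversity rows
  warn and return 0; all-zero distance pairs are 0 with a warning;
  constant features are dropped by `autoscale()` with a warning; a D = 0
  configuration yields an empty ordination.
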