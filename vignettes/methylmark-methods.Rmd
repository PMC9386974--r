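---
title: "Methods: DMR calling, marker selection and validation in methylmark"
author: "methylmark authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR calling, marker selection and validation in methylmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methylmark)
```

# Scope and data model

`methylmark` analyses per-CpG methylomes of sorted immune-cell
populations measured by whole-genome bisulfite sequencing in unicates
(one methylome per population, no replicates).  A CpG is a strand-merged
motif keyed by the plus-strand C position (0-based); every on-disk format
with 1-based coordinates (GTF) is converted on read, and all internal
intervals are 0-based half-open.  A `MethylMatrix` holds the union CpG
catalog with per-sample methylation fractions (`NA` where uncovered) and
read coverages; a missing level always implies coverage 0, and any
operation that averages over CpGs skips missing values rather than
imputing them.

Only CpGs with read coverage of at least 5 in at least one sample enter
the analysis (`filter_by_coverage()`, defaults `min_cov = 5`,
`min_samples = 1`).

# DMR segmentation

A DMR between two samples is a contiguous run of CpGs satisfying, on its
own members:

* at least `min_cpgs = 3` CpGs,
* absolute mean per-CpG methylation difference at least `min_diff = 0.25`,
* boundary CpGs that are *individually* differential — |difference| at
  least `min_diff` with the sign of the region mean.  This boundary rule
  makes regions well-delimited: a run like (0, 0.9, 0.9, 0) yields no
  region, because only two CpGs are differential, even though a 3-CpG
  window spanning them would pass the mean threshold.

Chromosomes are pre-split into blocks wherever adjacent covered CpGs lie
more than `max_cpg_gap = 500` bp apart, so regions never span CpG
deserts; the gap is configurable because no single value suits every
genome.  Within a block the search is recursive best-window selection:

1. among all windows with qualifying boundaries, take the one maximizing
   |mean difference| (ties: longer window, then leftmost);
2. absorb adjacent same-sign CpGs that individually reach `min_diff`
   (so no returned region can be extended by an adjacent qualifying CpG);
3. recurse into both flanks;
4. finally, merge adjacent same-sign segments of the block whenever the
   combined span — including the intervening CpGs — still meets the mean
   criterion.  Without this pass, long differential regions fragment
   around their local maxima, because a short intense sub-window always
   outranks the full region on |mean|.

Numerical conventions: differences are rounded to 4 decimals before
segmentation (far below the resolution of count-ratio methylation
levels), and window means are compared by cross-multiplied sums with a
1e-10 tolerance, so an independent naive implementation of the same
rules reproduces the output exactly — the test suite and the acceptance
script both carry such an oracle.  For blocks beyond 5,000 CpGs the
search splits at the weakest central CpG first; at the package's default
scales blocks are far smaller.

Each region is scored by a two-sided two-sample Kolmogorov–Smirnov test
(exact when tie-free) on the two samples' per-CpG level vectors — the
same family of statistic the established DMR segmentation tools embed.
`pairwise_dmr_tables()` drops regions with p > 0.05 by default
(`max_p`, set 1 to disable): at 20x coverage, minimal three-CpG regions
whose mean difference barely clears 25% arise from binomial sampling
noise alone, and every downstream consumer applies a significance
threshold anyway.  No multiple-testing correction is applied at this
stage; downstream filters impose their own cutoffs (the enrichment stage
uses p ≤ 0.01).

# Genomic annotation

The representative transcript of a gene is its longest annotated
transcript (length = summed exon widths); its 5' end in transcript
orientation is the gene TSS, so minus-strand genes take their maximum
coordinate.  Signed TSS distances are measured from the nearest TSS to
the nearest DMR edge in transcript orientation: downstream positive,
upstream negative, zero when the DMR overlaps the TSS.  The nearest gene
minimizes |distance|, ties broken by lexicographic gene id for
deterministic reruns.

The promoter is TSS ± 1,000 bp.  "1 kb around the TSS" admits two
readings; the symmetric 1-kb-radius window is the default and
`promoter_halfwidth = 500` selects the 1-kb-total alternative.
Precedence is promoter > intragenic > intergenic.

# Marker regions

Marker candidates for a population are DMRs in which that population is
hypomethylated by more than `min_diff = 0.40` in at least one pairwise
comparison.  Each candidate is extended by adjacent same-sign CpGs with
|difference| ≥ 0.25 — the extension threshold defaults to the DMR
calling threshold because it is the only differential threshold the
procedure defines.  A candidate must be associable with a gene: within
the gene body, the promoter window, or within 5 kb of a TSS; the final
selection in a real study also involves expert judgement, which we
formalize as the composite ranking key

> exclusivity (minimum over other populations of their region mean minus
> the target's), then member CpG count, then maximal pairwise
> |difference| — all descending.

Exclusivity is judged against the populations appearing in the supplied
pairwise tables, not against unrelated samples that share the matrix.
The default panel size is 12 markers per population, within the 7–14
range a curated panel would use.

Locus profiles are produced by a coverage-weighted Gaussian-kernel local
mean (bandwidth 500 bp, support ± 3 bandwidths).  This smoother serves
visualization and distance computation only; it is a convex combination
of raw levels, so constants stay constant and values stay within the
range of their contributing CpGs.  A local-likelihood smoother would be
a drop-in refinement but is deliberately avoided in favour of an easily
testable estimator.

# Sample distances

The most variable unique DMRs (duplicate spans merged keeping the larger
variance; default top 1,000) are summarized as region means on smoothed
levels, missing entries imputed with the region's across-sample mean,
and samples compared by Euclidean distance and agglomerative clustering.
The linkage is unspecified in the source procedure; `complete` is the
default as the standard deterministic choice for sample-level heatmaps,
with single/average/ward.D2 selectable.  Dendrograms export to Newick
via `ape`.

# Expression integration

Counts are normalized by median-of-ratios size factors (computed on the
natural scale over genes with nonzero counts everywhere).  Group log2
fold-changes use a pseudocount of 1 so zero counts stay bounded.  The
internal differential-expression stage is a Welch t-test on
log2(normalized + 1) with Benjamini–Hochberg adjustment — deliberately
simple, since the correlation analysis only consumes fold-changes, and
externally computed DE tables can be substituted.  The conservative DE
filter keeps |log2FC| ≥ 2 and adjusted p ≤ 0.05.

The methylation–expression correlation pairs, per marker gene, the
region methylation difference with the expression log2 fold-change of
the same comparison, reporting Pearson R (and R², since the source
convention reports both), a two-sided p-value and the regression line.
Strength bins follow the half-open convention: negligible (|R| ≤ 0.3),
low (≤ 0.5), moderate (≤ 0.7), high (≤ 0.9), very high (≤ 1) — so
R = −0.82 is "high" and R = −0.49 is "low"; boundary values belong to
the weaker bin.

# Group contrast ledger

"Differential in all comparisons" is implemented by recomputing region
means for every cross-group sample pair and requiring |difference| ≥ 0.5
with a consistent sign in every pair, rather than relying on each
pairwise caller having emitted the region — this makes the universal
quantifier checkable.  TSS proximity (≤ 5 kb) uses the DMR edge
(midpoint mode selectable), and "canonical gene name" means a non-empty
name not matching `^(Gm\d+|.*Rik)$`, the mouse placeholder conventions.
The ledger reports the top 75 entries per direction sorted by absolute
group-mean difference, and the plot table carries one row per
(DMR, sample): a gene with k DMRs and n samples contributes k × n rows.

# Pathway enrichment

Genes are assigned from DMRs passing |mean difference| ≥ 0.25 and
p ≤ 0.01; the universe is the set of genes with at least one assayed CpG
in the gene body or promoter window (configurable to all annotated
genes) — this avoids trivially enriching long genes that could never
have been observed.  The p-value is the exact hypergeometric upper tail
P(X ≥ k); the odds ratio comes from the 2 × 2 table with a Haldane 0.5
correction when a cell is zero.  The consensus panel keeps pathways
significant (p ≤ 0.01, uncorrected by design; a BH column is emitted for
information) in *every* comparison, ranked by the conservative minimum
odds ratio across comparisons, truncated to 40.

# Motif discovery

DMR sequences (± 10 nt flanks) are scanned on both strands by an
expectation-maximization mixture model in the any-number-of-repetitions
spirit: every width-w window is a potential site with prior λ estimated
by EM, the background is the 0th-order strand-symmetric input
composition, and initialization comes from the most frequent w-mers.
The EM objective is the standard independent-window mixture likelihood,
non-decreasing across iterations (asserted by the tests).  Discovered
sites (posterior > 0.5) are masked before the next motif is sought.

Significance is an empirical E-value.  For each shuffle replicate the
input sequences are letter-shuffled within sequence (preserving
composition and length) and refit at *every* candidate width; the null
statistic is the maximum across widths of the z-scored log-likelihood
ratio, which accounts for the width search the observed fit performs.
The observed motif's z-score is ranked against this max-null
(`p = (1 + #{null ≥ obs}) / (M + 1)`, M = 99 shuffles by default) and
multiplied by the number of widths tested.  A per-width null would flag
~5% of pure-noise runs at the 0.05 threshold by construction; the
max-null keeps noise runs clean while a planted motif, which dominates
every shuffle, still reaches E ≈ (number of widths)/(M + 1).  The search
stops early once a motif's E-value reaches `stop_at_e = 0.05` (that
motif is still reported), mirroring the usual E-value stopping rule of
EM motif finders.

Low-complexity motifs are removed when one base dominates more than 70%
of consensus columns (the poly(A/T) class) or a period-2 pattern covers
more than 80%; surviving motifs with E < 0.05 are matched against a
JASPAR-style PWM database by the best ungapped alignment over both
orientations, scored by the *sum* of aligned-column Pearson
correlations (a mean score lets a four-column coincidence tie a
full-width identity match), with an empirical p from column-order
shuffles of the query.

# The synthetic study

The generator emulates the statistical structure of a multi-population
WGBS/RNA-seq study at desk scale; its defaults are the package's study
conditions:

* genome: 2 chromosomes × 2 Mb with CpG dinucleotides placed at density
  0.005 (≈ 20,000 CpGs; incidental CG occurrences are removed first so
  the catalog is exact), genes tiled every 20 kb (6 kb bodies, three
  exons, alternating strands, every 10th gene carrying a placeholder
  Gm-name);
* methylomes: five ILC-like populations plus three Th-like populations,
  in unicates; background levels Beta(0.6, 0.2) shared across
  populations (bimodal, mean ≈ 0.75 — a mostly methylated genome),
  per-population Gaussian jitter (sd 0.03), coverage Poisson(20),
  observed level Binomial(coverage, level)/coverage with missing entries
  at coverage 0;
* planted signal: 25 population-exclusive hypomethylated blocks per ILC
  population, 5–20 CpGs long, at depths ∆ ~ U(0.4, 0.8) on a high
  baseline (U(0.85, 0.98)) — so every pair of populations carries 50
  planted differential blocks; 12 of the 25 are gene-associated *marker*
  blocks in promoter windows at ∆ ~ U(0.5, 0.85), the other 13 are
  intergenic (> 5 kb from any TSS, outside bodies); 15 extra blocks are
  shared by the ILC3/LTi sister pair; 30 blocks per direction
  discriminate the ILC and Th super-groups near TSSs of canonically
  named genes at ∆ ~ U(0.5, 0.8).  Planted blocks sit in locally
  CpG-dense stretches (internal gaps ≤ 500 bp) so that a caller with the
  package's gap rule can see each block as one region;
* expression: negative-binomial counts (dispersion 0.05), three
  replicates per ILC population; a marker gene of population P is
  upregulated in P by `4 × ∆ + Normal(0, 0.25)` log2 units — slope and
  noise chosen so that the population-level correlation between marker
  methylation differences and fold-changes is ≈ −0.8, the strength the
  marker concept presumes;
* motifs: the consensus TGACTCAG (an AP-1-like 8-mer with no CpG, so
  planting does not disturb the catalog) or its reverse complement is
  written into 80% of the ILC2-like population's blocks, within the
  central ≤ 400 bp of the block — a binding site centred in its
  demethylation footprint.

Everything is deterministic under the master seed; each stage derives
its own sub-seed.

What the generator does *not* emulate — and what green tests therefore
do not establish about real data: bisulfite conversion errors and
strand-asymmetric coverage, CpG-island structure and covariation of
methylation with local CpG density, replicate-level biological variance
in methylomes (unicates only, as in the motivating study design),
isoform complexity (one transcript per gene), batch effects, and the
correlation structure of real transcriptomes.  Recovery rates measured
here are upper bounds for comparably powered real studies.

# Validation scales

The shipped tests and the acceptance script run the generator at the
default scale above (and a reduced 1 × 2 Mb configuration for unit
fixtures), 100 random tracks of up to 200 CpGs against the exhaustive
segmentation oracle, 1,000 random DMRs against the brute-force
annotation oracle, 1,000 null draws for hypergeometric calibration, 100
seeded replicates for correlation recovery, and 20 seeded null runs for
motif discovery — sizes at which every check completes in minutes on a
single CPU while keeping the Monte-Carlo error well below the asserted
margins.

# Known limitations

* The segmentation is deterministic greedy recursion, not an exhaustive
  optimum over all region partitions; the oracle asserts equivalence to
  the stated rule, not global optimality.
* With unicates, the per-region KS p-value has coarse resolution at
  small CpG counts (a 3-CpG region cannot reach p ≤ 0.01); group-mode
  statistics over replicates are out of scope.
* The EM finder fits one motif at a time with masking; overlapping or
  correlated motifs are found greedily, and the analytic E-values of
  mature motif suites are replaced by an explicit, slower shuffle null.
* Conditional (hierarchy-aware) gene-set testing, which decorrelates
  nested sets, is not implemented; sets are treated as flat.
* The marker ranking formalizes a partly curatorial decision; on real
  data the top-k list should be reviewed, not consumed blindly.
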