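# methylmark

Epigenetic marker-region discovery from whole-genome bisulfite (WGBS)
methylomes of immune-cell populations.

## The problem

Innate lymphoid cells (ILC1, ILC2, ILC3, LTi, NK) are rare, and their
lineage identity is imprinted in DNA methylation: each lineage carries a
small set of genomic regions that are selectively *demethylated* in that
lineage only.  Given one per-CpG methylome per population (bedGraph-style
tables of methylation fractions with read coverages), this package

1. calls **differentially methylated regions (DMRs)** for every pair of
   populations — a DMR is a run of at least 3 CpGs whose mean methylation
   difference is at least 25%, delimited by CpGs that are individually
   differential, with a two-sample Kolmogorov–Smirnov p-value per region;
2. **annotates** DMRs as promoter (TSS ± 1 kb), intragenic or intergenic,
   with signed distances to the nearest transcription start site
   (downstream positive, upstream negative, overlap = 0);
3. distills DMRs into ranked **epigenetic marker regions** per population:
   candidates with > 40% difference are extended by adjacent differential
   CpGs, associated with a gene, and ranked by *exclusivity* — the
   smallest methylation gap between the target population and every other
   one;
4. clusters samples on **Euclidean distances** over the most variable
   region means (with Gaussian-kernel smoothing of CpG levels);
5. **integrates expression**: median-of-ratios normalization, log2
   fold-changes, RPKM, a conservative DE filter (|log2FC| ≥ 2,
   adjusted p ≤ 0.05), and the Pearson correlation between marker
   methylation differences and expression changes, binned as
   negligible / low / moderate / high / very high;
6. builds the between-lineage **contrast ledger** (unique DMRs with ≥ 0.5
   difference in *all* cross-group comparisons, within 5 kb of a TSS of a
   canonically named gene; top 75 hyper- and hypomethylated);
7. tests **pathway overrepresentation** of DMR-associated genes by the
   exact hypergeometric upper tail, with a consensus panel of the top-40
   odds ratios across comparisons;
8. discovers **sequence motifs** inside DMRs (± 10 nt flanks) with an
   expectation-maximization mixture finder on both strands, an empirical
   shuffle-null E-value, low-complexity filtering, and PWM matching
   against a transcription-factor database.

A seeded synthetic-data generator (`simulate_ilc_study()`) produces
genomes, gene models, multi-population methylomes with planted
hypomethylated blocks, coupled expression counts, and planted motif
occurrences — the ground truth all of the above is validated against.

## Worked example

```r
library(methylmark)

sim <- simulate_ilc_study(simulation_config(seed = 11))
mat <- filter_by_coverage(sim$matrix)          # coverage >= 5 in >= 1 sample
tables <- pairwise_dmr_tables(mat, samples = sim$config$populations)
sapply(tables, nrow)
#> ILC1_vs_ILC2  ILC1_vs_ILC3 ... (10 tables, ~50-80 DMRs each)

markers <- select_markers(tables, mat, sim$genome$genes, "ILC2")
head(markers$gene)                              # planted ILC2 marker genes

rep <- run_pipeline(pipeline_config(seed = 11))
print(rep)
#> methylmark pipeline report
#>   assayed CpGs: 20000
#>   DMR tables: 10 (total 586 DMRs)
#>   composition: 6% intragenic / 49% intergenic / 44% promoter
#>   correlation ILC1_vs_ILC2: R = -0.76 (high)
#>   correlation ILC3_vs_ILC2: R = -0.87 (high)
#>   correlation LTi_vs_ILC2: R = -0.84 (high)
#>   correlation NK_vs_ILC2: R = -0.87 (high)
#>   top motif: ACATGATTCA (E = 0.03)
```

The printed numbers are the stage summaries: per-pair DMR counts, the
promoter/intragenic/intergenic split of the unique DMR set, the Pearson
correlation between marker methylation differences and expression log2
fold-changes for each comparison against the ILC2 reference (strongly
negative: demethylation tracks up-regulation), and the most significant
motif found in ILC2-demethylated regions with its empirical E-value.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/methylmark simulate --seed 1 --out simdir/
Rscript inst/scripts/methylmark run --seed 1 --out rundir/
```

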