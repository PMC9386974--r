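cfg_tiny <- function(seed = 77, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 1L, chrom_length = 4e5,
         exclusive_blocks_per_pop = 5L, n_marker_genes = 3L,
         shared_blocks = 3L, group_blocks = 4L),
    list(...))
  do.call(simulation_config, args)
}

test_that("genome simulation is deterministic and hits the CpG density", {
  g1 <- simulate_genome(cfg_tiny())
  g2 <- simulate_genome(cfg_tiny())
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$cpgs, g2$cpgs)

  L <- 4e5; dens <- 0.005
  expect_lt(abs(nrow(g1$cpgs) - dens * L) / (dens * L), 0.05)
  # the catalog equals the realized CG dinucleotide positions
  cg <- Biostrings::start(Biostrings::matchPattern(
    "CG", g1$sequences[[1]]))
  expect_equal(g1$cpgs$pos, cg - 1L)
  # every gene lies within the sequence bounds
  expect_true(all(g1$genes$start >= 0 &
                    g1$genes$end <= Biostrings::width(g1$sequences[1])))
})

test_that("gtf round-trips through the annotation reader", {
  g <- simulate_genome(cfg_tiny())
  p <- tempfile(fileext = ".gtf")
  write_gtf(g$genes, p)
  back <- read_gene_annotation(p)
  expect_equal(nrow(back), nrow(g$genes))
  o <- match(g$genes$gene_id, back$gene_id)
  expect_equal(back$start[o], g$genes$start)
  expect_equal(back$end[o], g$genes$end)
  expect_equal(back$tss[o], g$genes$tss)
  expect_equal(back$strand[o], g$genes$strand)
})

test_that("methylome backgrounds match their Beta moments", {
  cfg <- cfg_tiny()
  g <- simulate_genome(cfg)
  mm <- simulate_methylomes(g, cfg)
  # outside planted blocks the mean level matches alpha/(alpha+beta)
  planted <- unlist(mapply(seq, mm$truth$cpg_from, mm$truth$cpg_to))
  bg_rows <- setdiff(seq_len(nrow(mm$matrix$levels)), planted)
  lv <- mm$matrix$levels[bg_rows, ]
  a <- cfg$background_alpha; b <- cfg$background_beta
  mu <- a / (a + b)
  v <- a * b / ((a + b)^2 * (a + b + 1))
  se <- sqrt(v / length(bg_rows))
  expect_lt(abs(mean(lv, na.rm = TRUE) - mu), max(4 * se, 0.02))
})

test_that("planted blocks realize their depth at the observed level", {
  cfg <- cfg_tiny()
  g <- simulate_genome(cfg)
  mm <- simulate_methylomes(g, cfg)
  tr <- mm$truth
  for (k in head(seq_len(nrow(tr)), 10)) {
    idx <- tr$cpg_from[k]:tr$cpg_to[k]
    aff <- strsplit(tr$populations[k], ",")[[1]][1]
    unaff <- setdiff(cfg$populations, strsplit(tr$populations[k], ",")[[1]])[1]
    realized <- mean(mm$matrix$levels[idx, unaff], na.rm = TRUE) -
      mean(mm$matrix$levels[idx, aff], na.rm = TRUE)
    expect_lt(abs(realized - min(tr$delta[k],
                                 mean(pmin(tr$delta[k], 0.96)))), 0.12)
  }
})

test_that("a zero-depth configuration produces a null methylome", {
  cfg <- cfg_tiny(seed = 78, exclusive_blocks_per_pop = 0L,
                  n_marker_genes = 0L, shared_blocks = 0L,
                  group_blocks = 0L)
  g <- simulate_genome(cfg)
  mm <- simulate_methylomes(g, cfg)
  expect_equal(nrow(mm$truth), 0)
  d <- mm$matrix$levels[, "ILC1"] - mm$matrix$levels[, "ILC2"]
  d <- d[!is.na(d)]
  win <- stats::filter(d, rep(1 / 100, 100), sides = 1)
  expect_lt(max(abs(win), na.rm = TRUE), 0.05)
  # and the DMR caller stays silent
  tr <- per_cpg_difference(filter_by_coverage(mm$matrix), "ILC1", "ILC2")
  expect_lte(nrow(segment_dmrs(tr)), 1)
})

test_that("expression couples planted markers and little else", {
  cfg <- cfg_tiny(seed = 79, marker_noise_sd = 0, marker_slope = 4)
  g <- simulate_genome(cfg)
  mm <- simulate_methylomes(g, cfg)
  ex <- simulate_expression(g, mm$truth, cfg)
  nm <- normalize_counts(ex$counts)
  for (k in seq_len(nrow(ex$marker_effects))) {
    me <- ex$marker_effects[k, ]
    gid <- g$genes$gene_id[match(me$gene, g$genes$gene_name)]
    other <- setdiff(cfg$populations, me$population)[1]
    lfc <- log2_fold_change(nm$normalized, ex$groups, me$population, other)
    expect_lt(abs(lfc[gid] - 4 * me$delta), 0.75)
  }
  # non-marker genes stay near zero fold-change
  lfc_all <- log2_fold_change(nm$normalized, ex$groups, "ILC1", "ILC2")
  mk_ids <- g$genes$gene_id[match(ex$marker_effects$gene,
                                  g$genes$gene_name)]
  expect_lt(median(abs(lfc_all[setdiff(names(lfc_all), mk_ids)])), 0.3)
  # deterministic under the seed
  ex2 <- simulate_expression(g, mm$truth, cfg)
  expect_identical(ex$counts, ex2$counts)
})

test_that("motif planting records exactly what it writes", {
  cfg <- cfg_tiny(seed = 80)
  g <- simulate_genome(cfg)
  mm <- simulate_methylomes(g, cfg)
  pm <- plant_motifs(g, mm$truth, cfg)
  w <- nchar(cfg$motif_consensus)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cfg$motif_consensus)))
  for (k in seq_len(nrow(pm$sites))) {
    s <- pm$sites[k, ]
    got <- as.character(Biostrings::subseq(
      pm$sequences[[s$chrom]], start = s$start + 1L, width = w))
    expect_equal(got, s$seq)
    expect_true(got %in% c(cfg$motif_consensus, rc))
  }
  own <- mm$truth[mm$truth$populations == cfg$motif_population &
                    mm$truth$type %in% c("marker", "exclusive"), ]
  expect_lt(abs(nrow(pm$sites) / nrow(own) - cfg$motif_fraction), 0.35)

  # zero fraction leaves the genome untouched
  cfg0 <- cfg_tiny(seed = 80, motif_fraction = 0)
  pm0 <- plant_motifs(g, mm$truth, cfg0)
  expect_identical(as.character(pm0$sequences), as.character(g$sequences))
  expect_equal(nrow(pm0$sites), 0)
})

test_that("the full study is deterministic and internally consistent", {
  a <- simulate_ilc_study(cfg_tiny(seed = 81))
  b <- simulate_ilc_study(cfg_tiny(seed = 81))
  expect_identical(as.character(a$genome$sequences),
                   as.character(b$genome$sequences))
  expect_identical(a$matrix$levels, b$matrix$levels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$motif_sites, b$motif_sites)

  # pairwise truth is the symmetric difference of affected populations
  tp <- truth_for_pair(a$truth, "ILC3", "LTi")
  expect_false(any(tp$type == "shared"))
  tp2 <- truth_for_pair(a$truth, "ILC3", "NK")
  expect_true(all(a$truth$type[a$truth$populations == "ILC3,LTi"] ==
                    "shared"))
  expect_true(any(tp2$populations == "ILC3,LTi"))
})

test_that("generator outputs feed every reader without adapters", {
  st <- small_study()
  dir <- tempfile()
  write_simulation(st, dir)
  m <- read_methyl_dir(file.path(dir, "methylomes"), min_cov = 5)
  expect_equal(m$pos, filter_by_coverage(st$matrix)$pos)
  genes <- read_gene_annotation(file.path(dir, "genes.gtf"))
  expect_equal(nrow(genes), nrow(st$genome$genes))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_gt(length(sets), 0)
  db <- read_pwm_database(file.path(dir, "pwm_db.txt"))
  expect_true("PLANTED_TF" %in% names(db))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(Biostrings::width(fa),
               Biostrings::width(st$genome$sequences))
  counts <- utils::read.table(file.path(dir, "counts.tsv"), header = TRUE,
                              sep = "\t", row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(counts), st$expression$counts)
})
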