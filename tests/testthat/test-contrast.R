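test_that("unique_dmrs merges overlapping spans across tables", {
  t1 <- data.frame(chrom = "chr1", start = 100L, end = 200L, n_cpgs = 5L,
                   mean_diff = 0.5)
  t2 <- data.frame(chrom = "chr1", start = c(100L, 500L),
                   end = c(200L, 600L), n_cpgs = c(5L, 4L),
                   mean_diff = c(-0.7, 0.3))
  u <- unique_dmrs(list(a = t1, b = t2, c = t1))
  expect_equal(nrow(u), 2)
  expect_equal(u$mean_diff[1], -0.7)    # max |mean_diff| kept, signed

  # interval-union oracle on random tables
  set.seed(71)
  tabs <- lapply(1:5, function(i) {
    s <- sort(sample.int(10000L, 30)) * 10L
    data.frame(chrom = "chr1", start = s, end = s + sample(50:400, 30,
                                                           replace = TRUE),
               n_cpgs = 3L, mean_diff = runif(30, -1, 1))
  })
  u2 <- unique_dmrs(tabs)
  # oracle: sweep-line union of intervals
  all <- do.call(rbind, tabs)
  all <- all[order(all$start), ]
  merged <- list()
  for (k in seq_len(nrow(all))) {
    m <- length(merged)
    if (m && all$start[k] < merged[[m]][2])
      merged[[m]][2] <- max(merged[[m]][2], all$end[k])
    else merged[[m + 1]] <- c(all$start[k], all$end[k])
  }
  expect_equal(u2$start, vapply(merged, `[`, numeric(1), 1))
  expect_equal(u2$end, vapply(merged, `[`, numeric(1), 2))
  expect_true(all(u2$start[-1] >= u2$end[-nrow(u2)]))
})

test_that("contrast filter applies all three rules exactly", {
  st <- small_study()
  m <- st$matrix
  genes <- st$genome$genes
  ilc <- st$config$populations
  th <- st$config$th_populations
  cross <- pairwise_dmr_tables(filter_by_coverage(m), samples = c(ilc, th))
  cross <- cross[grepl("ILC|LTi|NK", names(cross)) &
                   grepl("Th", names(cross))]
  uni <- unique_dmrs(cross)
  filt <- filter_contrast(uni, m, genes, ilc, th)
  # brute-force check of every surviving and rejected row
  means <- sapply(c(ilc, th), function(s)
    vapply(seq_len(nrow(uni)), function(i)
      region_mean_methylation(m, uni$chrom[i], uni$start[i], uni$end[i], s),
      numeric(1)))
  td <- tss_distance(uni, genes)
  for (i in seq_len(nrow(uni))) {
    dif <- as.vector(outer(means[i, ilc], means[i, th], `-`))
    ok_diff <- all(!is.na(dif)) && min(abs(dif)) >= 0.5 &&
      length(unique(sign(dif))) == 1
    nm <- td$nearest_gene_name[i]
    ok <- ok_diff && abs(td$tss_distance[i]) <= 5000 &&
      !is.na(nm) && nm != "" && !grepl("^(Gm[0-9]+|.*Rik)$", nm)
    expect_equal(any(filt$start == uni$start[i] &
                       filt$chrom == uni$chrom[i]), ok)
  }
})

test_that("contrast filter example rules hold on constructed cases", {
  # one CpG block differential only between two of the groups
  m <- methyl_matrix(rep("chr1", 6), seq(1000L, 1500L, by = 100L),
                     cbind(A1 = c(.9, .9, .9, .9, .9, .9),
                           A2 = c(.9, .9, .9, .9, .9, .9),
                           B1 = c(.3, .3, .3, .9, .9, .9)),
                     matrix(10L, 6, 3), c("A1", "A2", "B1"))
  genes <- data.frame(gene_id = "G1", gene_name = "Alpha", chrom = "chr1",
                      strand = "+", start = 900L, end = 3000L, tss = 900L,
                      tx_length = 2100L)
  dmrs <- data.frame(chrom = "chr1", start = 1000L, end = 1250L,
                     n_cpgs = 3L, mean_diff = 0.6)
  ok <- filter_contrast(dmrs, m, genes, c("A1", "A2"), "B1")
  expect_equal(nrow(ok), 1)
  expect_equal(ok$gene, "Alpha")

  # diff below 0.5 in one comparison -> excluded
  m2 <- m; m2$levels[1:3, "A2"] <- 0.6
  expect_equal(nrow(filter_contrast(dmrs, m2, genes, c("A1", "A2"), "B1")),
               0)
  # placeholder gene name -> excluded
  g2 <- genes; g2$gene_name <- "Gm01234"
  expect_equal(nrow(filter_contrast(dmrs, m, g2, c("A1", "A2"), "B1")), 0)
  # too far from the TSS -> excluded
  g3 <- genes; g3$tss <- 900L + 7000L; g3$start <- 7000L; g3$end <- 9000L
  expect_equal(nrow(filter_contrast(dmrs, m, g3, c("A1", "A2"), "B1")), 0)
})

test_that("top ledgers split by sign and expand genes to k x n rows", {
  filt <- data.frame(
    chrom = "chr1", start = c(1L, 2L, 3L, 4L), end = c(10L, 12L, 13L, 14L),
    n_cpgs = 3L, mean_diff = c(.6, -.7, .8, -.55),
    mean_diff_groups = c(.6, -.7, .8, -.55),
    tss_distance = 0, gene = c("g1", "g2", "g1", "g3"),
    mean_s1 = c(.9, .1, .95, .2), mean_s2 = c(.8, .2, .85, .1),
    stringsAsFactors = FALSE)
  led <- top_hyper_hypo(filt, samples = c("s1", "s2"), n = 75)
  expect_equal(led$hyper$mean_diff_groups, c(.8, .6))
  expect_equal(led$hypo$mean_diff_groups, c(-.7, -.55))
  expect_true(all(led$hyper$mean_diff_groups > 0))
  expect_true(all(led$hypo$mean_diff_groups < 0))
  # gene g1 has two DMRs and 2 samples -> 4 plot rows
  expect_equal(sum(led$plot_table$gene == "g1"), 4)
  # ranked by |difference| with deterministic ties
  expect_equal(order(abs(led$hyper$mean_diff_groups), decreasing = TRUE),
               seq_len(nrow(led$hyper)))
})

test_that("group-discriminating blocks surface in the hypo ledger", {
  st <- small_study()
  m <- filter_by_coverage(st$matrix)
  genes <- st$genome$genes
  ilc <- st$config$populations
  th <- st$config$th_populations
  cross <- list()
  for (a in ilc) for (b in th) {
    track <- per_cpg_difference(m, a, b)
    cross[[paste0(a, "_vs_", b)]] <- segment_dmrs(track)
  }
  filt <- filter_contrast(unique_dmrs(cross), m, genes, ilc, th)
  led <- top_hyper_hypo(filt, samples = c(ilc, th), n = 75)
  planted_hypo <- st$truth$gene[st$truth$type == "ilc_hypo"]
  planted_hyper <- st$truth$gene[st$truth$type == "th_hypo"]
  # strongly planted blocks (depth well above the 0.5 filter) must appear
  strong_hypo <- st$truth$gene[st$truth$type == "ilc_hypo" &
                                 st$truth$delta >= 0.65]
  expect_true(all(strong_hypo %in% led$hypo$gene))
  expect_gte(length(intersect(led$hyper$gene, planted_hyper)), 1)
  # no cross-contamination between directions
  expect_length(intersect(led$hypo$gene, planted_hyper), 0)
})
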