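test_that("methylation tables parse with direct field mapping", {
  p <- write_meth_lines("chr1\t100\t101\t0.80\t8\t10")
  tab <- read_methylation_table(p, "s1")
  expect_equal(tab$chrom, "chr1")
  expect_equal(tab$pos, 100L)
  expect_equal(tab$meth_level, 0.8)
  expect_equal(tab$meth_count, 8L)
  expect_equal(tab$total_count, 10L)

  empty <- read_methylation_table(write_meth_lines(character(0)), "s1")
  expect_equal(nrow(empty), 0)

  pct <- write_meth_lines("chr1\t100\t101\t80")
  expect_equal(read_methylation_table(pct, "s1",
                                      percent_scale = TRUE)$meth_level, 0.8)
})

test_that("malformed and invalid tables are rejected with line numbers", {
  bad <- write_meth_lines(c("chr1\t100\t101\t0.5\t5\t10", "chr1\t200"))
  expect_error(read_methylation_table(bad, "s"), "line 2")
  oob <- write_meth_lines("chr1\t100\t101\t1.5")
  expect_error(read_methylation_table(oob, "s"), "outside")
  unsorted <- write_meth_lines(c("chr1\t300\t301\t0.5",
                                 "chr1\t100\t101\t0.2"))
  expect_message(tab <- read_methylation_table(unsorted, "s"), "sorted")
  expect_equal(tab$pos, c(100L, 300L))
})

test_that("build_matrix takes the sorted union and marks missing CpGs", {
  a <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                  meth_level = c(.1, .2, .3), meth_count = 1:3,
                  total_count = c(10L, 10L, 10L))
  b <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                  meth_level = c(.4, .5, .6, .7), meth_count = 4:7,
                  total_count = rep(10L, 4))
  m <- build_matrix(list(A = a, B = b))
  expect_equal(length(m$pos), 4)
  expect_true(is.na(m$levels[4, "A"]))
  expect_equal(unname(m$coverage[4, "A"]), 0L)

  single <- build_matrix(list(A = a))
  expect_equal(single$levels[, "A"], a$meth_level)

  dup <- rbind(a, a[1, ])
  expect_error(build_matrix(list(A = dup)), "duplicate")
})

test_that("union catalog equals brute-force set union on random input", {
  set.seed(7)
  tabs <- lapply(1:100, function(i) {
    pos <- sort(sample.int(5000L, sample(5:40, 1)))
    data.frame(chrom = "chr1", pos = pos,
               meth_level = runif(length(pos)),
               meth_count = 0L, total_count = 10L)
  })
  names(tabs) <- sprintf("s%03d", seq_along(tabs))
  tabs <- lapply(tabs, function(t) {
    t$meth_count <- as.integer(round(t$meth_level * 10)); t$meth_level <- t$meth_count / 10; t
  })
  m <- build_matrix(tabs)
  brute <- sort(Reduce(union, lapply(tabs, `[[`, "pos")))
  expect_equal(m$pos, brute)
})

test_that("coverage filter keeps exactly the qualifying CpGs", {
  m <- methyl_matrix(rep("chr1", 3), c(10L, 20L, 30L),
                     cbind(c(.5, .5, .5), c(.5, .5, .5)),
                     cbind(c(5L, 3L, 10L), c(0L, 4L, 10L)), c("A", "B"))
  f <- filter_by_coverage(m, min_cov = 5, min_samples = 1)
  # (5, 0) retained, (3, 4) removed
  expect_equal(f$pos, c(10L, 30L))

  # brute-force row-scan oracle on a random matrix, plus idempotence
  set.seed(11)
  n <- 1000
  cv <- matrix(rpois(n * 4, 5), n, 4)
  lv <- matrix(runif(n * 4), n, 4)
  mr <- methyl_matrix(rep("chr1", n), seq_len(n) * 2L, lv, cv,
                      paste0("s", 1:4))
  fr <- filter_by_coverage(mr, min_cov = 5, min_samples = 2)
  keep <- vapply(seq_len(n), function(i) sum(cv[i, ] >= 5) >= 2, logical(1))
  expect_equal(fr$pos, mr$pos[keep])
  expect_equal(filter_by_coverage(fr, 5, 2)$pos, fr$pos)
})

test_that("write/read round-trip preserves levels and coverage", {
  st <- small_study()
  m <- filter_by_coverage(st$matrix)
  dir <- tempfile()
  write_methyl_matrix(m, dir)
  back <- read_methyl_dir(dir)
  expect_equal(back$samples[order(back$samples)],
               sort(m$samples))
  expect_equal(back$pos, m$pos)
  expect_equal(back$levels[, m$samples], m$levels, tolerance = 1e-6)
  expect_equal(back$coverage[, m$samples], m$coverage)
})

test_that("build_matrix is order-invariant up to column permutation", {
  a <- data.frame(chrom = "chr1", pos = c(10L, 30L), meth_level = c(0, 1),
                  meth_count = c(0L, 10L), total_count = c(10L, 10L))
  b <- data.frame(chrom = "chr1", pos = c(10L, 20L), meth_level = c(.5, .5),
                  meth_count = c(5L, 5L), total_count = c(10L, 10L))
  m1 <- build_matrix(list(A = a, B = b))
  m2 <- build_matrix(list(B = b, A = a))
  expect_equal(m1$pos, m2$pos)
  expect_equal(m1$levels[, c("A", "B")], m2$levels[, c("A", "B")])
})

test_that("GTF coordinate and strand conventions hold on read", {
  gtf <- tempfile(fileext = ".gtf")
  at <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  writeLines(c(
    sprintf("chr1\tx\tgene\t1001\t2000\t.\t+\t.\t%s", at("gp", "gp.t")),
    sprintf("chr1\tx\ttranscript\t1001\t2000\t.\t+\t.\t%s", at("gp", "gp.t")),
    sprintf("chr1\tx\texon\t1001\t2000\t.\t+\t.\t%s", at("gp", "gp.t")),
    sprintf("chr1\tx\tgene\t1001\t2000\t.\t-\t.\t%s", at("gm", "gm.t")),
    sprintf("chr1\tx\ttranscript\t1001\t2000\t.\t-\t.\t%s", at("gm", "gm.t")),
    sprintf("chr1\tx\texon\t1001\t2000\t.\t-\t.\t%s", at("gm", "gm.t")),
    # multi-transcript gene: the longer transcript defines the TSS
    sprintf("chr1\tx\tgene\t5001\t9000\t.\t+\t.\t%s", at("g3", "g3.t1")),
    sprintf("chr1\tx\ttranscript\t5001\t6000\t.\t+\t.\t%s", at("g3", "g3.t1")),
    sprintf("chr1\tx\texon\t5001\t6000\t.\t+\t.\t%s", at("g3", "g3.t1")),
    sprintf("chr1\tx\ttranscript\t6001\t9000\t.\t+\t.\t%s", at("g3", "g3.t2")),
    sprintf("chr1\tx\texon\t6001\t9000\t.\t+\t.\t%s", at("g3", "g3.t2"))),
    gtf)
  g <- read_gene_annotation(gtf)
  gp <- g[g$gene_id == "gp", ]
  expect_equal(c(gp$start, gp$end, gp$tss), c(1000L, 2000L, 1000L))
  gm <- g[g$gene_id == "gm", ]
  expect_equal(gm$tss, 1999L)
  g3 <- g[g$gene_id == "g3", ]
  expect_equal(g3$tss, 6000L)       # 5' end of the longest transcript
  expect_equal(g3$tx_length, 3000L)
})
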