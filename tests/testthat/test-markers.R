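test_that("extension absorbs adjacent qualifying CpGs stepwise", {
  d <- c(.05, .05, .10, .30, .6, .6, .6, .6, .6, .05)
  track <- structure(
    data.frame(chrom = "chr1", pos = seq_along(d) * 100L, diff = d),
    class = c("MethDiffTrack", "data.frame"))
  dmr <- data.frame(chrom = "chr1", start = 500L, end = 901L,
                    mean_diff = 0.6)
  ext <- extend_region(dmr, track)
  expect_equal(c(ext$start, ext$end), c(400L, 901L))  # CpG 4 joins, 3 not
  expect_equal(ext$n_cpgs, 6L)

  # no qualifying neighbours: unchanged; idempotent re-extension
  d2 <- c(.05, .6, .6, .6, .05)
  t2 <- structure(
    data.frame(chrom = "chr1", pos = seq_along(d2) * 100L, diff = d2),
    class = c("MethDiffTrack", "data.frame"))
  e2 <- extend_region(data.frame(chrom = "chr1", start = 200L, end = 401L,
                                 mean_diff = .6), t2)
  expect_equal(c(e2$start, e2$end), c(200L, 401L))
  e2b <- extend_region(data.frame(chrom = "chr1", start = e2$start,
                                  end = e2$end, mean_diff = .6), t2)
  expect_equal(e2b[c("start", "end")], e2[c("start", "end")])

  # opposite-sign neighbour is never included
  d3 <- c(-.5, .6, .6, .6)
  t3 <- structure(
    data.frame(chrom = "chr1", pos = seq_along(d3) * 100L, diff = d3),
    class = c("MethDiffTrack", "data.frame"))
  e3 <- extend_region(data.frame(chrom = "chr1", start = 200L, end = 401L,
                                 mean_diff = .6), t3)
  expect_equal(e3$start, 200L)
})

test_that("region means are unweighted means over covered CpGs", {
  m <- methyl_matrix(rep("chr1", 3), c(10L, 20L, 30L),
                     cbind(A = c(.1, .2, .3)), matrix(10L, 3, 1), "A")
  expect_equal(region_mean_methylation(m, "chr1", 0, 40, "A"), 0.2)
  m1 <- methyl_matrix(rep("chr1", 3), c(10L, 20L, 30L),
                      cbind(A = c(1, 1, 1)), matrix(10L, 3, 1), "A")
  expect_equal(region_mean_methylation(m1, "chr1", 0, 40, "A"), 1)
  # not-determined when no CpG is covered
  m2 <- methyl_matrix("chr1", 10L, cbind(A = NA_real_),
                      cbind(A = 0L), "A")
  expect_true(is.na(region_mean_methylation(m2, "chr1", 0, 40, "A")))

  set.seed(41)
  st <- small_study()
  mt <- st$matrix
  got <- region_mean_methylation(mt, "chr1", 1000, 50000, "ILC2")
  sel <- mt$pos >= 1000 & mt$pos < 50000
  expect_equal(got, mean(mt$levels[sel, "ILC2"], na.rm = TRUE))
})

test_that("marker ranking follows exclusivity, then size, then difference", {
  # two candidates distinguished purely by the ranking key
  mk <- data.frame(
    exclusivity = c(0.25, 0.45), n_cpgs = c(10L, 5L),
    max_abs_diff = c(0.6, 0.5))
  o <- order(-mk$exclusivity, -mk$n_cpgs, -mk$max_abs_diff)
  expect_equal(o[1], 2)   # 0.45 exclusivity outranks 0.25

  st <- small_study()
  tabs <- small_tables()
  m <- filter_by_coverage(st$matrix)
  sel <- select_markers(tabs, m, st$genome$genes, "ILC2")
  expect_true(all(diff(sel$exclusivity) <= 1e-9))
  means <- as.matrix(sel[, paste0("mean_", m$samples)])
  expect_true(all(means >= 0 & means <= 1, na.rm = TRUE))
  # recomputed exclusivity agrees with the stored per-population means
  others <- setdiff(st$config$populations, "ILC2")
  excl <- apply(means[, paste0("mean_", others), drop = FALSE] -
                  means[, "mean_ILC2"], 1, min)
  expect_equal(unname(excl), sel$exclusivity)
})

test_that("markers recover the planted marker genes of the population", {
  st <- small_study()
  tabs <- small_tables()
  m <- filter_by_coverage(st$matrix)
  planted <- st$truth$gene[st$truth$type == "marker" &
                             st$truth$populations == "ILC2"]
  sel <- select_markers(tabs, m, st$genome$genes, "ILC2",
                        top = length(planted))
  expect_gte(length(intersect(sel$gene, planted)),
             ceiling(0.9 * length(planted)))
  expect_error(select_markers(tabs, m, st$genome$genes, "nope"),
               "unknown population")
})

test_that("candidates below the 40% rule or without genes are excluded", {
  st <- small_study()
  m <- filter_by_coverage(st$matrix)
  genes <- st$genome$genes
  # construct one table with a weak DMR only
  weak <- data.frame(chrom = "chr1", start = m$pos[10], end = m$pos[12] + 1L,
                     n_cpgs = 3L, mean_diff = -0.30, p_value = 0.001,
                     comparison = "ILC2_vs_ILC1")
  tabs <- list(ILC2_vs_ILC1 = weak)
  sel <- select_markers(tabs, m, genes, "ILC2")
  expect_equal(nrow(sel), 0)   # fails the > 40% candidate rule

  # gene-free candidate dropped when require_gene
  far <- data.frame(chrom = "chr1", start = 1L, end = 2L)
  expect_true(is.na(methylmark:::associate_gene(far, genes[
    genes$start > 2e5, , drop = FALSE])))
})

test_that("marker matrix has population minima at the target column", {
  st <- small_study()
  tabs <- small_tables()
  m <- filter_by_coverage(st$matrix)
  sel <- select_markers(tabs, m, st$genome$genes, "ILC2", top = 6)
  mm <- marker_matrix(sel, m)
  expect_true(all(mm >= 0 & mm <= 1, na.rm = TRUE))
  ilc <- st$config$populations
  for (j in seq_len(ncol(mm)))
    expect_equal(unname(which.min(mm[ilc, j])), which(ilc == "ILC2"))
})

test_that("kernel smoothing preserves constants, isolates, and monotone steps", {
  # constant input stays constant
  m <- methyl_matrix(rep("chr1", 5), c(100L, 200L, 300L, 400L, 500L),
                     cbind(A = rep(.7, 5)), matrix(10L, 5, 1), "A")
  p <- smooth_profile(m, "chr1", 0, 1000, bandwidth = 200)
  expect_equal(p$A, rep(.7, 5), tolerance = 1e-12)

  # a single isolated CpG keeps its raw value
  m1 <- methyl_matrix(rep("chr1", 2), c(100L, 90000L),
                      cbind(A = c(.3, .9)), matrix(10L, 2, 1), "A")
  p1 <- smooth_profile(m1, "chr1", 0, 1e5, bandwidth = 200)
  expect_equal(p1$A, c(.3, .9))

  # step profile: smoothed values are monotone across the step
  pos <- as.integer(seq(100, by = 150, length.out = 40))
  lv <- c(rep(.1, 20), rep(.9, 20))
  m2 <- methyl_matrix(rep("chr1", 40), pos, cbind(A = lv),
                      matrix(10L, 40, 1), "A")
  p2 <- smooth_profile(m2, "chr1", 0, 1e4, bandwidth = 300)
  expect_true(all(diff(p2$A) >= -1e-9))
  expect_true(all(p2$A >= min(lv) - 1e-12 & p2$A <= max(lv) + 1e-12))

  expect_error(smooth_profile(m2, "chr1", 50000, 60000), "no CpG")
})
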