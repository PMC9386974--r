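diff_track <- function(d, pos = seq_along(d) * 100L, chrom = "chr1") {
  structure(data.frame(chrom = chrom, pos = pos, diff = d),
            class = c("MethDiffTrack", "data.frame"),
            comparison = c("a", "b"))
}

test_that("per-CpG difference is antisymmetric and respects missing data", {
  m <- toy_matrix()
  ab <- per_cpg_difference(m, "A", "B")
  ba <- per_cpg_difference(m, "B", "A")
  expect_equal(ab$diff[1], 0)
  expect_equal(ab$diff[4], -0.7)
  expect_true(is.na(ab$diff[9]) && is.na(ab$diff[10]))
  expect_equal(ab$diff, -ba$diff)
  expect_error(per_cpg_difference(m, "A", "nope"), "unknown sample")
})

test_that("segmentation reproduces the canonical toy cases", {
  d1 <- c(rep(.05, 4), rep(.6, 5), rep(.05, 4))
  r1 <- segment_dmrs(diff_track(d1))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_cpgs, 5L)
  expect_equal(r1$mean_diff, 0.6)
  expect_equal(c(r1$start, r1$end), c(500L, 901L))

  # only two individually differential CpGs: no region
  expect_equal(nrow(segment_dmrs(diff_track(c(0, .9, .9, 0)))), 0)
  # everywhere below the mean-difference threshold
  expect_equal(nrow(segment_dmrs(diff_track(rep(.1, 30)))), 0)
  expect_error(segment_dmrs(diff_track(rep(.5, 5)), min_cpgs = 1),
               "min_cpgs")
})

test_that("chromosome blocks split at large CpG gaps", {
  pos <- c(100L, 200L, 300L, 2000L, 2100L, 2200L)
  r <- segment_dmrs(diff_track(rep(0.5, 6), pos = pos))
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(100L, 2000L))
})

test_that("called DMRs equal the exhaustive-window oracle on random tracks", {
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(10:120, 1)
    base <- rnorm(n, 0, 0.12)
    # plant 0-2 blocks to give the oracle real structure
    for (b in seq_len(sample(0:2, 1))) {
      len <- sample(3:12, 1)
      at <- sample(n - len + 1, 1)
      base[at:(at + len - 1)] <- base[at:(at + len - 1)] +
        sample(c(-1, 1), 1) * runif(1, 0.3, 0.7)
    }
    d <- round(pmin(pmax(base, -1), 1), 3)
    got <- segment_dmrs(diff_track(d))
    want <- oracle_segment(d)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, function(s) s[1] * 100L,
                                     integer(1)))
      expect_equal(got$n_cpgs, vapply(want, function(s)
        s[2] - s[1] + 1L, integer(1)))
    }
  }
})

test_that("regions are sign-coherent and maximal under the extension rule", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 80
    d <- round(rnorm(n, 0, 0.25), 3)
    r <- segment_dmrs(diff_track(d))
    for (k in seq_len(nrow(r))) {
      i1 <- r$start[k] / 100; i2 <- (r$end[k] - 1) / 100
      seg <- d[i1:i2]
      expect_gte(abs(mean(seg)), 0.25 - 1e-9)
      expect_equal(sign(mean(seg)), sign(r$mean_diff[k]))
      s <- sign(mean(seg))
      if (i1 > 1)
        expect_false(sign(d[i1 - 1]) == s && abs(d[i1 - 1]) >= 0.25)
      if (i2 < n)
        expect_false(sign(d[i2 + 1]) == s && abs(d[i2 + 1]) >= 0.25)
    }
    # non-overlapping and sorted
    if (nrow(r) > 1) expect_true(all(diff(r$start) > 0) &&
                                   all(r$end[-nrow(r)] <= r$start[-1]))
  }
})

test_that("DMR p-values are symmetric, exact for clean separation", {
  expect_equal(score_dmr(rep(.5, 5), rep(.5, 5)), 1)
  a <- rep(.95, 10); b <- rep(.05, 10)
  expect_lt(score_dmr(a, b), 0.01)
  set.seed(3)
  x <- runif(8); y <- runif(8)
  expect_equal(score_dmr(x, y), score_dmr(y, x))
  expect_error(score_dmr(c(.1, .2), c(.3, .4)), "fewer than")
})

test_that("exact KS p matches full enumeration at small n", {
  enum_ks_p <- function(a, b) {
    pooled <- c(a, b)
    n <- length(a)
    d_of <- function(ia) {
      xa <- sort(pooled[ia]); xb <- sort(pooled[-ia])
      pts <- sort(unique(pooled))
      max(abs(vapply(pts, function(t)
        mean(xa <= t) - mean(xb <= t), numeric(1))))
    }
    d_obs <- d_of(seq_len(n))
    combos <- utils::combn(length(pooled), n)
    mean(apply(combos, 2, d_of) >= d_obs - 1e-12)
  }
  set.seed(21)
  for (rep in 1:5) {
    a <- runif(5); b <- runif(5) + runif(1, 0, .5)
    expect_equal(score_dmr(a, b), enum_ks_p(a, b), tolerance = 1e-10)
  }
})

test_that("pairwise tables cover every unordered pair", {
  st <- small_study()
  m <- filter_by_coverage(st$matrix)
  tabs <- small_tables()
  expect_equal(length(tabs), choose(5, 2))
  expect_setequal(
    names(tabs),
    apply(utils::combn(st$config$populations, 2), 2, paste,
          collapse = "_vs_"))
  two <- pairwise_dmr_tables(m, samples = c("ILC1", "ILC2"))
  expect_equal(names(two), "ILC1_vs_ILC2")
  for (tab in tabs)
    if (nrow(tab)) expect_true(all(tab$p_value > 0 & tab$p_value <= 0.05))
})

test_that("planted DMR blocks are recovered on the small study", {
  st <- small_study()
  tabs <- small_tables()
  jacc <- function(s1, e1, s2, e2) {
    i <- pmin(e1, e2) - pmax(s1, s2)
    ifelse(i > 0, i / (pmax(e1, e2) - pmin(s1, s2)), 0)
  }
  tp <- fp <- fn <- 0
  for (lab in names(tabs)) {
    ab <- strsplit(lab, "_vs_", fixed = TRUE)[[1]]
    tab <- tabs[[lab]]
    tr <- truth_for_pair(st$truth, ab[1], ab[2])
    hit <- rep(FALSE, nrow(tr))
    for (k in seq_len(nrow(tab))) {
      jj <- jacc(tab$start[k], tab$end[k], tr$start, tr$end) *
        (tr$chrom == tab$chrom[k])
      if (any(jj >= 0.5)) hit[which.max(jj)] <- TRUE else fp <- fp + 1
    }
    tp <- tp + sum(hit); fn <- fn + sum(!hit)
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_lte(fp / (tp + fp), 0.1)
})
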