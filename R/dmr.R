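#' Per-CpG methylation difference track between two samples
#'
#' @param matrix a [methyl_matrix()].
#' @param sample_a,sample_b sample names; differences are
#'   `level_a - level_b`, so the track is antisymmetric under swapping.
#' @return data.frame of class `MethDiffTrack` with columns `chrom`, `pos`,
#'   `diff` (`NA` where either sample lacks the CpG) and attribute
#'   `comparison = c(sample_a, sample_b)`.
#' @export
per_cpg_difference <- function(matrix, sample_a, sample_b) {
  stopifnot(inherits(matrix, "MethylMatrix"))
  for (s in c(sample_a, sample_b))
    if (!s %in% matrix$samples) stop_mm("unknown sample '%s'", s)
  d <- matrix$levels[, sample_a] - matrix$levels[, sample_b]
  out <- data.frame(chrom = matrix$chrom, pos = matrix$pos, diff = d,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- c(sample_a, sample_b)
  class(out) <- c("MethDiffTrack", "data.frame")
  out
}

# Numerical conventions for segmentation: per-CpG differences are rounded
# to 4 decimals (well below the resolution of count-ratio methylation
# levels) and window means are compared by cross-multiplied sums with a
# 1e-10 tie tolerance, so that independent implementations of the same rule
# agree bitwise on which window wins.
.SEG_ROUND <- 4L
.SEG_TOL <- 1e-10

#' Segment a difference track into DMRs
#'
#' A DMR must contain at least `min_cpgs` CpGs, have an absolute mean
#' methylation difference of at least `min_diff` (defaults: >= 3 CpGs and
#' >= 25%), and be delimited by CpGs that are individually differential
#' (|diff| >= `min_diff` with the sign of the region mean).  Within each
#' chromosome block (pre-split wherever adjacent covered CpGs lie more
#' than `max_cpg_gap` bp apart), the search repeatedly takes the
#' qualifying window maximizing |mean difference| (ties: longer window,
#' then leftmost), appends adjacent same-sign CpGs that individually
#' reach `min_diff`, recurses into the flanks, and finally merges
#' adjacent same-sign segments whose combined span still meets the mean
#' criterion.  Returned regions are therefore non-overlapping,
#' sign-coherent, and cannot be extended by an adjacent qualifying CpG.
#'
#' @param track a [per_cpg_difference()] track.
#' @param min_cpgs minimum CpGs per DMR (>= 2).
#' @param min_diff minimum absolute mean methylation difference (fraction).
#' @param max_cpg_gap maximum distance in bp between adjacent member CpGs.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open span from first to last member CpG), `n_cpgs`, `mean_diff`,
#'   `p_value` (`NA`; filled by [pairwise_dmr_tables()]), `comparison`.
#' @export
segment_dmrs <- function(track, min_cpgs = 3L, min_diff = 0.25,
                         max_cpg_gap = 500L) {
  if (min_cpgs < 2) stop_mm("min_cpgs must be >= 2")
  cmp <- attr(track, "comparison")
  label <- if (!is.null(cmp)) paste0(cmp[1], "_vs_", cmp[2]) else NA_character_
  keep <- !is.na(track$diff)
  chrom <- track$chrom[keep]; pos <- track$pos[keep]
  d <- round(track$diff[keep], .SEG_ROUND)
  n <- length(d)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_diff = numeric(), p_value = numeric(),
                      comparison = character(), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  new_block <- c(TRUE, chrom[-1] != chrom[-n] | diff(pos) > max_cpg_gap)
  block_id <- cumsum(new_block)
  res <- list()
  for (b in unique(block_id)) {
    idx <- which(block_id == b)
    if (length(idx) < min_cpgs) next
    segs <- segment_block(d[idx], min_cpgs, min_diff)
    segs <- merge_segments(segs, d[idx], min_diff)
    if (length(segs)) {
      for (s in segs) {
        i1 <- idx[s[1]]; i2 <- idx[s[2]]
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom[i1], start = pos[i1], end = pos[i2] + 1L,
          n_cpgs = i2 - i1 + 1L,
          mean_diff = mean(d[i1:i2]),
          p_value = NA_real_, comparison = label,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge adjacent same-sign segments of one block when the combined span
# (including the intervening CpGs) still meets the mean-difference
# criterion; repeated left-to-right until stable.  Keeps long regions that
# the best-window recursion split around local maxima in one piece.
merge_segments <- function(segs, d, min_diff) {
  if (length(segs) < 2) return(segs)
  segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
  repeat {
    merged <- FALSE
    k <- 1L
    while (k < length(segs)) {
      i1 <- segs[[k]][1]; i2 <- segs[[k + 1L]][2]
      m <- sum(d[i1:i2])
      s1 <- sign(sum(d[segs[[k]][1]:segs[[k]][2]]))
      s2 <- sign(sum(d[segs[[k + 1L]][1]:segs[[k + 1L]][2]]))
      if (s1 == s2 && abs(m) >= min_diff * (i2 - i1 + 1L) - .SEG_TOL) {
        segs[[k]] <- c(i1, i2)
        segs[[k + 1L]] <- NULL
        merged <- TRUE
      } else k <- k + 1L
    }
    if (!merged) break
  }
  segs
}

# Recursive best-window segmentation of one gap-free block of rounded
# diffs; returns list of c(start_index, end_index) pairs (1-based, local).
segment_block <- function(d, min_cpgs, min_diff) {
  n <- length(d)
  if (n < min_cpgs) return(list())
  if (n > 5000L) {
    # split-and-recurse heuristic for very long blocks: cut at the weakest
    # CpG in the central third so no strong window is likely to straddle it
    mid <- seq.int(floor(n / 3), ceiling(2 * n / 3))
    cut <- mid[which.min(abs(d[mid]))]
    return(c(segment_block(d[1:cut], min_cpgs, min_diff),
             lapply(segment_block(d[(cut + 1):n], min_cpgs, min_diff),
                    function(s) s + cut)))
  }
  S <- c(0, cumsum(d))
  qual <- abs(d) >= min_diff - .SEG_TOL     # individually differential CpGs
  sg <- sign(d)
  best_abs <- -1; best_L <- 0L; best_i <- 0L
  for (L in min_cpgs:n) {
    idx <- 1:(n - L + 1)
    sums <- S[idx + L] - S[idx]
    # a window qualifies when its boundary CpGs are themselves
    # differential with the sign of the window mean, and the mean passes
    valid <- qual[idx] & qual[idx + L - 1L] & sg[idx] == sg[idx + L - 1L] &
      sign(sums) == sg[idx] & abs(sums) >= min_diff * L - .SEG_TOL
    if (!any(valid)) next
    a <- abs(sums)
    a[!valid] <- -Inf
    i <- which.max(a)                     # leftmost maximum within length L
    # cross-multiplied comparison of |mean|s; ties go to the longer window
    if (best_L == 0L || a[i] * best_L >= best_abs * L - .SEG_TOL) {
      best_abs <- a[i]; best_L <- L; best_i <- i
    }
  }
  if (best_L == 0L) return(list())
  i1 <- best_i; i2 <- best_i + best_L - 1L
  sgn <- sign(S[i2 + 1] - S[i1])
  # maximality: absorb adjacent same-sign CpGs that qualify on their own
  while (i1 > 1L && sign(d[i1 - 1L]) == sgn &&
         abs(d[i1 - 1L]) >= min_diff - .SEG_TOL) i1 <- i1 - 1L
  while (i2 < n && sign(d[i2 + 1L]) == sgn &&
         abs(d[i2 + 1L]) >= min_diff - .SEG_TOL) i2 <- i2 + 1L
  out <- list(c(i1, i2))
  if (i1 - 1L >= min_cpgs)
    out <- c(segment_block(d[1:(i1 - 1L)], min_cpgs, min_diff), out)
  if (n - i2 >= min_cpgs)
    out <- c(out, lapply(segment_block(d[(i2 + 1L):n], min_cpgs, min_diff),
                         function(s) s + i2))
  out
}

#' Two-sided p-value for one DMR
#'
#' Compares the two samples' per-CpG methylation level vectors inside the
#' region with a two-sided (exact where possible) Kolmogorov-Smirnov test.
#' Symmetric under swapping the samples; identical vectors give p = 1.
#'
#' @param levels_a,levels_b per-CpG methylation levels of the region in
#'   each sample (paired positions; `NA` pairs are dropped).
#' @param min_cpgs minimum number of paired values required.
#' @return p-value in (0, 1].
#' @export
score_dmr <- function(levels_a, levels_b, min_cpgs = 3L) {
  ok <- !is.na(levels_a) & !is.na(levels_b)
  a <- levels_a[ok]; b <- levels_b[ok]
  if (length(a) < min_cpgs)
    stop_mm("score_dmr: fewer than %d paired CpG values", min_cpgs)
  if (all(a == b)) return(1)
  p <- suppressWarnings(
    stats::ks.test(a, b, alternative = "two.sided", exact = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Call DMRs for every pairwise sample comparison
#'
#' @param matrix a [methyl_matrix()].
#' @param min_cpgs,min_diff,max_cpg_gap see [segment_dmrs()].
#' @param max_p per-region significance screen: DMRs whose two-sample KS
#'   p-value exceeds this are dropped from the tables (the reference
#'   segmentation embeds the same statistic; `max_p = 1` disables the
#'   screen).  At 20x coverage this removes minimal three-CpG regions
#'   whose mean difference barely clears the threshold by sampling noise.
#' @param samples restrict to these samples (default: all).
#' @param out_dir if non-`NULL`, each table is also written as BED6+
#'   (`<a>_vs_<b>.dmr.bed`) via [write_dmr_bed()].
#' @return Named list (one element per unordered pair, `"A_vs_B"`) of DMR
#'   data.frames with p-values filled in.
#' @export
pairwise_dmr_tables <- function(matrix, min_cpgs = 3L, min_diff = 0.25,
                                max_cpg_gap = 500L, max_p = 0.05,
                                samples = NULL, out_dir = NULL) {
  stopifnot(inherits(matrix, "MethylMatrix"))
  if (is.null(samples)) samples <- matrix$samples
  stopifnot(all(samples %in% matrix$samples))
  ns <- length(samples)
  if (ns < 2) stop_mm("need at least two samples")
  tables <- list()
  for (i in seq_len(ns - 1)) {
    for (j in seq.int(i + 1, ns)) {
      a <- samples[i]; b <- samples[j]
      track <- per_cpg_difference(matrix, a, b)
      dmrs <- segment_dmrs(track, min_cpgs, min_diff, max_cpg_gap)
      dmrs <- score_dmr_table(dmrs, matrix, a, b, min_cpgs)
      dmrs <- dmrs[is.na(dmrs$p_value) | dmrs$p_value <= max_p, ,
                   drop = FALSE]
      rownames(dmrs) <- NULL
      lab <- paste0(a, "_vs_", b)
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        write_dmr_bed(dmrs, file.path(out_dir, paste0(lab, ".dmr.bed")))
      }
      tables[[lab]] <- dmrs
    }
  }
  tables
}

# fill the p_value column of a DMR table via score_dmr()
score_dmr_table <- function(dmrs, matrix, a, b, min_cpgs = 3L) {
  if (!nrow(dmrs)) return(dmrs)
  dmrs$p_value <- vapply(seq_len(nrow(dmrs)), function(k) {
    in_reg <- matrix$chrom == dmrs$chrom[k] &
      matrix$pos >= dmrs$start[k] & matrix$pos < dmrs$end[k]
    score_dmr(matrix$levels[in_reg, a], matrix$levels[in_reg, b],
              min_cpgs = min_cpgs)
  }, numeric(1))
  dmrs
}
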