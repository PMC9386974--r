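#' Extend a DMR with adjacent differentially methylated CpGs
#'
#' Starting from the DMR span, flanking CpGs are appended greedily in both
#' directions while each next CpG's |difference| is at least
#' `per_cpg_min_diff`, has the same sign as the DMR's mean difference, and
#' lies within `max_cpg_gap` bp of the current edge.  The result always
#' contains the input DMR, and re-extension is idempotent.
#'
#' @param dmr one-row DMR data.frame (from the same comparison as `track`).
#' @param track the comparison's [per_cpg_difference()] track.
#' @param per_cpg_min_diff per-CpG extension threshold (defaults to the
#'   DMR calling threshold, the only differential threshold stated).
#' @param max_cpg_gap maximum bp gap to the next appended CpG.
#' @return Named list `chrom`, `start`, `end`, `n_cpgs`, `mean_diff` for
#'   the extended span.
#' @export
extend_region <- function(dmr, track, per_cpg_min_diff = 0.25,
                          max_cpg_gap = 500L) {
  on_chr <- track$chrom == dmr$chrom & !is.na(track$diff)
  pos <- track$pos[on_chr]; d <- track$diff[on_chr]
  inside <- pos >= dmr$start & pos < dmr$end
  if (!any(inside)) stop_mm("DMR span contains no covered CpG of the track")
  i1 <- which(inside)[1]; i2 <- max(which(inside))
  sgn <- sign(mean(d[i1:i2]))
  while (i1 > 1L && sign(d[i1 - 1L]) == sgn &&
         abs(d[i1 - 1L]) >= per_cpg_min_diff &&
         pos[i1] - pos[i1 - 1L] <= max_cpg_gap) i1 <- i1 - 1L
  n <- length(pos)
  while (i2 < n && sign(d[i2 + 1L]) == sgn &&
         abs(d[i2 + 1L]) >= per_cpg_min_diff &&
         pos[i2 + 1L] - pos[i2] <= max_cpg_gap) i2 <- i2 + 1L
  list(chrom = dmr$chrom, start = pos[i1], end = pos[i2] + 1L,
       n_cpgs = i2 - i1 + 1L, mean_diff = mean(d[i1:i2]))
}

#' Region-mean methylation of one sample over a span
#'
#' Unweighted mean over the CpGs inside the span that have a defined level
#' in the sample; `NA` (not determined) when no member CpG is covered.
#'
#' @param matrix a [methyl_matrix()].
#' @param chrom,start,end region span (0-based half-open).
#' @param sample sample name.
#' @return Fraction in \[0, 1\], or `NA`.
#' @export
region_mean_methylation <- function(matrix, chrom, start, end, sample) {
  idx <- matrix$chrom == chrom & matrix$pos >= start & matrix$pos < end
  lv <- matrix$levels[idx, sample]
  lv <- lv[!is.na(lv)]
  if (!length(lv)) return(NA_real_)
  mean(lv)
}

# Region-mean methylation of every sample over a set of spans; optionally
# on Gaussian-kernel smoothed levels.  Returns regions x samples matrix.
region_mean_matrix <- function(matrix, regions, smooth_bandwidth = NULL) {
  lv <- matrix$levels
  if (!is.null(smooth_bandwidth))
    lv <- smooth_levels(matrix, smooth_bandwidth)
  out <- matrix(NA_real_, nrow(regions), length(matrix$samples),
                dimnames = list(NULL, matrix$samples))
  for (i in seq_len(nrow(regions))) {
    idx <- matrix$chrom == regions$chrom[i] &
      matrix$pos >= regions$start[i] & matrix$pos < regions$end[i]
    out[i, ] <- colMeans(lv[idx, , drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Select ranked epigenetic marker regions for one population
#'
#' Candidates are DMRs in which the target population is hypomethylated
#' with an absolute mean difference above `min_diff` (default > 40%) in at
#' least one pairwise comparison.  Each candidate is extended with
#' adjacent differentially methylated CpGs, associated with a gene (inside
#' the gene body, inside the promoter window, or within `assoc_window` bp
#' of a TSS; candidates without such a gene are dropped when
#' `require_gene`), deduplicated by overlapping span, and ranked by the
#' composite key (exclusivity = min over other populations of
#' `mean_other - mean_target`, then member CpG count, then maximal
#' pairwise |mean difference|), descending.
#'
#' @param dmr_tables list of pairwise DMR tables from
#'   [pairwise_dmr_tables()].
#' @param matrix the [methyl_matrix()] the tables came from.
#' @param genes gene models.
#' @param population target population (sample name).
#' @param min_diff candidate threshold on |mean_diff| (exclusive).
#' @param top number of markers to return (all, with a notice, if fewer).
#' @param require_gene drop candidates with no associated gene.
#' @param extension_min_diff per-CpG threshold for [extend_region()].
#' @param promoter_halfwidth,assoc_window gene-association windows (bp).
#' @return data.frame of marker regions: span, `gene`, `n_cpgs`,
#'   `exclusivity`, `max_abs_diff`, and one `mean_<sample>` column of
#'   region-mean methylation per population.
#' @export
select_markers <- function(dmr_tables, matrix, genes, population,
                           min_diff = 0.40, top = 12L, require_gene = TRUE,
                           extension_min_diff = 0.25,
                           promoter_halfwidth = 1000L,
                           assoc_window = 5000L) {
  stopifnot(inherits(matrix, "MethylMatrix"))
  if (!population %in% matrix$samples)
    stop_mm("unknown population '%s'", population)
  # exclusivity is judged against the populations the tables compare,
  # not against unrelated samples sharing the matrix
  table_pops <- unique(unlist(strsplit(names(dmr_tables), "_vs_",
                                       fixed = TRUE)))
  others <- intersect(setdiff(table_pops, population), matrix$samples)
  if (!length(others)) others <- setdiff(matrix$samples, population)
  cands <- list()
  for (lab in names(dmr_tables)) {
    ab <- strsplit(lab, "_vs_", fixed = TRUE)[[1]]
    if (!population %in% ab) next
    other <- setdiff(ab, population)
    tab <- dmr_tables[[lab]]
    if (!nrow(tab)) next
    # hypomethylated in the target: target level below the other sample
    sign_target <- if (ab[1] == population) -1 else 1
    keep <- sign(tab$mean_diff) == sign_target & abs(tab$mean_diff) > min_diff
    tab <- tab[keep, , drop = FALSE]
    if (!nrow(tab)) next
    track <- per_cpg_difference(matrix, population, other)
    for (k in seq_len(nrow(tab))) {
      ext <- extend_region(tab[k, ], track,
                           per_cpg_min_diff = extension_min_diff)
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = ext$chrom, start = ext$start, end = ext$end,
        n_cpgs = ext$n_cpgs, abs_diff = abs(tab$mean_diff[k]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cands)) return(empty_marker_frame(matrix$samples))
  cand <- do.call(rbind, cands)
  # merge duplicated/overlapping extended spans, keeping the widest
  cand <- cand[order(cand$chrom, cand$start, -cand$end,
                     method = "radix"), , drop = FALSE]
  merged <- list(); max_diff <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    m <- length(merged)
    if (m && merged[[m]]$chrom == cand$chrom[k] &&
        cand$start[k] < merged[[m]]$end) {
      merged[[m]]$end <- max(merged[[m]]$end, cand$end[k])
      merged[[m]]$n_cpgs <- max(merged[[m]]$n_cpgs, cand$n_cpgs[k])
      max_diff[m] <- max(max_diff[m], cand$abs_diff[k])
    } else {
      merged[[m + 1L]] <- as.list(cand[k, c("chrom", "start", "end", "n_cpgs")])
      max_diff[m + 1L] <- cand$abs_diff[k]
    }
  }
  reg <- do.call(rbind, lapply(merged, as.data.frame))
  reg$max_abs_diff <- max_diff
  gene <- associate_gene(reg, genes, promoter_halfwidth, assoc_window)
  reg$gene <- gene
  if (require_gene) reg <- reg[!is.na(reg$gene), , drop = FALSE]
  if (!nrow(reg)) return(empty_marker_frame(matrix$samples))
  means <- region_mean_matrix(matrix, reg)
  reg$exclusivity <- apply(
    means[, others, drop = FALSE] - means[, population], 1, min, na.rm = TRUE)
  for (s in matrix$samples) reg[[paste0("mean_", s)]] <- means[, s]
  reg <- reg[order(-reg$exclusivity, -reg$n_cpgs, -reg$max_abs_diff,
                   reg$chrom, reg$start, method = "radix"), , drop = FALSE]
  if (nrow(reg) < top)
    notice("only %d marker candidates available (top = %d requested)",
           nrow(reg), top)
  reg <- utils::head(reg, top)
  reg$population <- population
  rownames(reg) <- NULL
  reg
}

empty_marker_frame <- function(samples) {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   n_cpgs = integer(), max_abs_diff = numeric(),
                   gene = character(), exclusivity = numeric(),
                   stringsAsFactors = FALSE)
  for (s in samples) df[[paste0("mean_", s)]] <- numeric(0)
  df$population <- character(0)
  df
}

# Nearest gene "clearly associated" with a region: overlapping the gene
# body or promoter window, else a TSS within assoc_window bp; NA otherwise.
associate_gene <- function(regions, genes, promoter_halfwidth = 1000L,
                           assoc_window = 5000L) {
  td <- tss_distance(regions, genes)
  cls <- classify_dmr(regions, genes, promoter_halfwidth)
  gene <- ifelse(cls != "intergenic" | abs(td$tss_distance) <= assoc_window,
                 ifelse(is.na(td$nearest_gene_name) | td$nearest_gene_name == "",
                        td$nearest_gene_id, td$nearest_gene_name),
                 NA_character_)
  gene
}

#' Populations x markers matrix of region-mean methylation
#'
#' @param markers marker data.frame from [select_markers()] (or any table
#'   with `chrom`, `start`, `end`, and optionally `gene`).
#' @param matrix a [methyl_matrix()].
#' @return Numeric matrix samples x markers with values in \[0, 1\]
#'   (rendering maps 0 to yellow, 0.5 to white, 1 to blue).
#' @export
marker_matrix <- function(markers, matrix) {
  if (!nrow(markers)) stop_mm("no markers")
  mm <- t(region_mean_matrix(matrix, markers))
  colnames(mm) <- if (!is.null(markers$gene))
    make.unique(as.character(markers$gene)) else
      paste0(markers$chrom, ":", markers$start, "-", markers$end)
  mm
}

# Gaussian-kernel coverage-weighted smoothing of all levels (per sample,
# per chromosome).  Missing CpGs contribute nothing; values are convex
# combinations of raw levels, hence bounded by their range.
smooth_levels <- function(matrix, bandwidth = 500) {
  out <- matrix$levels
  for (ch in unique(matrix$chrom)) {
    rows <- which(matrix$chrom == ch)
    pos <- matrix$pos[rows]
    for (s in seq_along(matrix$samples)) {
      lv <- matrix$levels[rows, s]
      cv <- matrix$coverage[rows, s]
      ok <- !is.na(lv)
      if (!any(ok)) next
      out[rows, s] <- gauss_smooth(pos, lv, cv, ok, bandwidth)
    }
  }
  out
}

gauss_smooth <- function(pos, lv, cv, ok, bandwidth) {
  res <- rep(NA_real_, length(pos))
  pos_ok <- pos[ok]; lv_ok <- lv[ok]; w_ok <- pmax(cv[ok], 1)
  # positions are sorted: restrict each kernel to +/- 3 bandwidths
  lo <- findInterval(pos - 3 * bandwidth, pos_ok + 0.5) + 1L
  hi <- findInterval(pos + 3 * bandwidth, pos_ok - 0.5)
  for (i in seq_along(pos)) {
    if (hi[i] < lo[i]) { res[i] <- lv[i]; next }
    j <- lo[i]:hi[i]
    w <- w_ok[j] * exp(-((pos_ok[j] - pos[i]) / bandwidth)^2 / 2)
    res[i] <- sum(w * lv_ok[j]) / sum(w)
  }
  res
}

#' Smoothed methylation profile of a locus window
#'
#' Per-CpG smoothed value = coverage-weighted Gaussian-kernel average of
#' the raw levels within +/- 3 bandwidths.  Constant input stays constant;
#' an isolated CpG keeps its raw value.
#'
#' @param matrix a [methyl_matrix()].
#' @param chrom,start,end locus window (0-based half-open, >= 1 CpG).
#' @param bandwidth kernel bandwidth in bp.
#' @return data.frame of class `SmoothedProfile`: `chrom`, `pos`, then one
#'   smoothed-level column per sample; attribute `bandwidth`.
#' @export
smooth_profile <- function(matrix, chrom, start, end, bandwidth = 500) {
  keep <- matrix$chrom == chrom & matrix$pos >= start & matrix$pos < end
  if (!any(keep)) stop_mm("window contains no CpG")
  sm <- smooth_levels(subset_matrix(matrix, keep), bandwidth)
  out <- data.frame(chrom = chrom, pos = matrix$pos[keep],
                    stringsAsFactors = FALSE)
  for (s in matrix$samples) out[[s]] <- sm[, s]
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("SmoothedProfile", "data.frame")
  out
}
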