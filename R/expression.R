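#' Median-of-ratios count normalization
#'
#' Size factor of a sample = median over genes of the ratio of its count
#' to the gene's geometric mean across samples, using only genes with a
#' nonzero count in every sample.  Multiplying one sample's counts by c
#' multiplies its factor by c.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return List with `size_factors` (named numeric) and `normalized`
#'   (counts divided by their sample's factor).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop_mm(paste("no gene has nonzero counts in all samples;",
                  "consider adding a pseudocount"))
  sub <- counts[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  sf <- apply(sub, 2, function(x) stats::median(x / geo))
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Per-gene log2 fold-change between two groups
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))` on normalized
#' counts; antisymmetric under swapping the groups.
#'
#' @param normalized genes x samples matrix of normalized counts.
#' @param groups named character vector (or factor) mapping each sample
#'   (column) to its group.
#' @param group_a,group_b group labels.
#' @param pseudocount added to both means (bounds the fold-change on
#'   zero counts).
#' @return Named numeric vector of log2 fold-changes.
#' @export
log2_fold_change <- function(normalized, groups, group_a, group_b,
                             pseudocount = 1) {
  groups <- groups[colnames(normalized)]
  for (g in c(group_a, group_b))
    if (!any(groups == g)) stop_mm("group '%s' has no samples", g)
  ma <- rowMeans(normalized[, groups == group_a, drop = FALSE])
  mb <- rowMeans(normalized[, groups == group_b, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}

#' Reads per kilobase (maximum) transcript length per million mapped reads
#'
#' `RPKM = count / (length_kb * library_size_in_millions)`, computed from
#' raw counts and per-library totals.
#'
#' @param counts genes x samples raw count matrix.
#' @param lengths per-gene transcript lengths in bp (maximum transcript
#'   length convention).
#' @return genes x samples RPKM matrix.
#' @export
rpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop_mm("need one length per gene")
  if (any(lengths <= 0)) stop_mm("gene lengths must be positive")
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop_mm("zero library size")
  sweep(counts / (lengths / 1e3), 2, libsize / 1e6, "/")
}

#' Differential-expression table with internal p-values
#'
#' Normalizes counts, computes the group log2 fold-change, and derives
#' per-gene p-values from a Welch t-test on `log2(normalized + 1)` with
#' Benjamini-Hochberg adjustment.  Externally computed results can be
#' supplied downstream instead; this internal stage only feeds the
#' fold-change filter.
#'
#' @param counts genes x samples raw count matrix.
#' @param groups named vector mapping samples to groups.
#' @param group_a,group_b labels of the two groups.
#' @param lengths optional gene lengths for RPKM columns.
#' @return data.frame `gene`, `log2fc`, `mean_a`, `mean_b`, `p`, `padj`
#'   (+ `rpkm_a`, `rpkm_b` when lengths given).
#' @export
diff_expression <- function(counts, groups, group_a, group_b,
                            lengths = NULL) {
  nm <- normalize_counts(counts)
  lfc <- log2_fold_change(nm$normalized, groups, group_a, group_b)
  groups <- groups[colnames(counts)]
  la <- log2(nm$normalized[, groups == group_a, drop = FALSE] + 1)
  lb <- log2(nm$normalized[, groups == group_b, drop = FALSE] + 1)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0)
      return(if (mean(xa) == mean(xb)) 1 else 0)
    tryCatch(stats::t.test(xa, xb)$p.value, error = function(e) 1)
  }, numeric(1))
  out <- data.frame(gene = rownames(counts),
                    log2fc = lfc,
                    mean_a = rowMeans(nm$normalized[, groups == group_a,
                                                    drop = FALSE]),
                    mean_b = rowMeans(nm$normalized[, groups == group_b,
                                                    drop = FALSE]),
                    p = p, padj = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  if (!is.null(lengths)) {
    rk <- rpkm(counts, lengths)
    out$rpkm_a <- rowMeans(rk[, groups == group_a, drop = FALSE])
    out$rpkm_b <- rowMeans(rk[, groups == group_b, drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Apply the conservative differential-expression filter
#'
#' Keeps exactly the records with `|log2FC| >= min_abs_lfc` and adjusted
#' p-value `<= max_padj` (defaults: >= 2 and <= 0.05).
#'
#' @param records data.frame with `log2fc` and `padj` columns.
#' @param min_abs_lfc,max_padj thresholds.
#' @return The surviving rows.
#' @export
de_filter <- function(records, min_abs_lfc = 2, max_padj = 0.05) {
  records[abs(records$log2fc) >= min_abs_lfc &
            records$padj <= max_padj, , drop = FALSE]
}

#' Correlate marker methylation differences with expression changes
#'
#' Pairs each marker gene's region methylation difference with the gene's
#' expression log2 fold-change for the same comparison and reports the
#' Pearson correlation, its two-sided p-value, the fitted regression line
#' and the strength label of [classify_correlation()].
#'
#' @param meth_diff named numeric vector: per-gene methylation difference
#'   (comparison orientation A minus B).
#' @param lfc named numeric vector of per-gene log2 fold-changes (same
#'   orientation); paired by name with `meth_diff`.
#' @return List of class `CorrelationResult`: `pairs` (data.frame `gene`,
#'   `meth_diff`, `log2fc`), `R`, `R2`, `p`, `slope`, `intercept`, `label`.
#' @export
methylation_expression_correlation <- function(meth_diff, lfc) {
  genes <- intersect(names(meth_diff), names(lfc))
  genes <- genes[!is.na(meth_diff[genes]) & !is.na(lfc[genes])]
  if (length(genes) < 3) stop_mm("need at least 3 paired marker genes")
  x <- as.numeric(meth_diff[genes]); y <- as.numeric(lfc[genes])
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  fit <- stats::lm(y ~ x)
  structure(list(
    pairs = data.frame(gene = genes, meth_diff = x, log2fc = y,
                       stringsAsFactors = FALSE),
    R = unname(ct$estimate), R2 = unname(ct$estimate)^2,
    p = ct$p.value,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    label = classify_correlation(unname(ct$estimate))),
    class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Methylation-expression correlation: R = %.3f (%s), p = %.3g, n = %d\n",
              x$R, x$label, x$p, nrow(x$pairs)))
  invisible(x)
}

#' Strength label of a correlation coefficient
#'
#' Bins follow the half-open convention of the negative branch —
#' negligible (0 >= R >= -0.3), low (-0.3 > R >= -0.5), moderate
#' (-0.5 > R >= -0.7), high (-0.7 > R >= -0.9), very high
#' (-0.9 > R >= -1) — applied symmetrically to positive R, so R = -0.3 is
#' "negligible", R = -0.5 "low", R = -0.82 "high", R = -0.49 "low".
#'
#' @param R correlation coefficient in \[-1, 1\].
#' @return One of `"negligible"`, `"low"`, `"moderate"`, `"high"`,
#'   `"very high"`.
#' @export
classify_correlation <- function(R) {
  if (!is_scalar_number(R) || abs(R) > 1)
    stop_mm("R must be a number in [-1, 1]")
  a <- abs(R)
  if (a <= 0.3) "negligible"
  else if (a <= 0.5) "low"
  else if (a <= 0.7) "moderate"
  else if (a <= 0.9) "high"
  else "very high"
}
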