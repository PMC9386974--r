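#' Merge pairwise DMR tables into unique spans
#'
#' Overlapping DMR spans coming from different comparisons are merged into
#' one entry covering their union, keeping the maximum |mean_diff| (signed
#' as observed at that maximum) and the maximum CpG count.
#'
#' @param dmr_tables list of DMR data.frames.
#' @return data.frame `chrom`, `start`, `end`, `n_cpgs`, `mean_diff` of
#'   non-overlapping spans sorted by position.
#' @export
unique_dmrs <- function(dmr_tables) {
  if (!length(dmr_tables)) stop_mm("need at least one DMR table")
  all <- do.call(rbind, lapply(dmr_tables, function(t)
    t[, c("chrom", "start", "end", "n_cpgs", "mean_diff")]))
  if (is.null(all) || !nrow(all))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_diff = numeric()))
  all <- all[order(all$chrom, all$start, all$end, method = "radix"), ,
             drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(all))) {
    m <- length(out)
    if (m && out[[m]]$chrom == all$chrom[k] && all$start[k] < out[[m]]$end) {
      out[[m]]$end <- max(out[[m]]$end, all$end[k])
      out[[m]]$n_cpgs <- max(out[[m]]$n_cpgs, all$n_cpgs[k])
      if (abs(all$mean_diff[k]) > abs(out[[m]]$mean_diff))
        out[[m]]$mean_diff <- all$mean_diff[k]
    } else {
      out[[m + 1L]] <- as.list(all[k, ])
    }
  }
  res <- do.call(rbind, lapply(out, as.data.frame))
  rownames(res) <- NULL
  res
}

#' Filter DMRs for the between-group contrast ledger
#'
#' Keeps DMRs whose region-mean methylation difference has absolute value
#' >= `min_abs_diff` with a consistent sign in *every* cross-group sample
#' pair (recomputed from region means, not from the per-pair caller
#' output), whose nearest TSS lies within `tss_window` bp, and whose
#' nearest gene carries a canonical name (non-empty and not matching
#' `noncanonical_pattern`).
#'
#' @param dmrs data.frame of unique DMR spans.
#' @param matrix a [methyl_matrix()] containing all samples.
#' @param genes gene models.
#' @param group_a,group_b character vectors of sample names.
#' @param min_abs_diff threshold on |mean difference| in all comparisons.
#' @param tss_window maximal |TSS distance| in bp (distance of the DMR
#'   edge; `midpoint = TRUE` uses the DMR midpoint instead).
#' @param require_canonical_name drop genes with placeholder names.
#' @param noncanonical_pattern regex identifying placeholder gene names.
#' @param midpoint measure TSS proximity from the DMR midpoint.
#' @return The surviving rows with columns `mean_diff_groups` (mean over
#'   cross-pair differences, group A minus group B), `tss_distance`,
#'   `gene`, and per-sample `mean_<sample>` region means appended.
#' @export
filter_contrast <- function(dmrs, matrix, genes, group_a, group_b,
                            min_abs_diff = 0.5, tss_window = 5000L,
                            require_canonical_name = TRUE,
                            noncanonical_pattern = "^(Gm[0-9]+|.*Rik)$",
                            midpoint = FALSE) {
  stopifnot(all(c(group_a, group_b) %in% matrix$samples))
  if (!nrow(dmrs)) return(cbind(dmrs, mean_diff_groups = numeric(0)))
  means <- region_mean_matrix(matrix, dmrs)
  diffs <- matrix(NA_real_, nrow(dmrs), length(group_a) * length(group_b))
  k <- 0
  for (a in group_a) for (b in group_b) {
    k <- k + 1
    diffs[, k] <- means[, a] - means[, b]
  }
  min_abs <- apply(abs(diffs), 1, min)
  sign_ok <- apply(sign(diffs), 1, function(s) all(s == s[1]))
  pass_diff <- !is.na(min_abs) & min_abs >= min_abs_diff & sign_ok
  td_in <- dmrs
  if (midpoint) {
    mid <- floor((dmrs$start + dmrs$end) / 2)
    td_in$start <- mid; td_in$end <- mid + 1L
  }
  td <- tss_distance(td_in, genes)
  pass_tss <- abs(td$tss_distance) <= tss_window
  name <- td$nearest_gene_name
  canon <- !is.na(name) & name != "" & !grepl(noncanonical_pattern, name)
  pass_name <- if (require_canonical_name) canon else TRUE
  keep <- which(pass_diff & pass_tss & pass_name)
  out <- dmrs[keep, , drop = FALSE]
  out$mean_diff_groups <- rowMeans(diffs)[keep]
  out$tss_distance <- td$tss_distance[keep]
  out$gene <- name[keep]
  for (s in c(group_a, group_b)) out[[paste0("mean_", s)]] <- means[keep, s]
  rownames(out) <- NULL
  out
}

#' Top hyper- and hypomethylated contrast DMRs
#'
#' Splits a filtered contrast set by the sign of the group-A-minus-group-B
#' mean difference and returns the `n` entries of largest absolute
#' difference on each side (all of them, with a notice, if fewer exist),
#' sorted descending.  The accompanying plot table carries one row per
#' (DMR, sample): a gene with k DMRs contributes k x n_samples rows.
#'
#' @param filtered output of [filter_contrast()].
#' @param samples sample names to plot (default: all `mean_*` columns).
#' @param n ledger size per direction.
#' @return List with `hyper`, `hypo` (data.frames sorted by
#'   |mean_diff_groups| descending, ties by chrom/start) and `plot_table`
#'   (`gene`, `chrom`, `start`, `end`, `direction`, `sample`, `methylation`).
#' @export
top_hyper_hypo <- function(filtered, samples = NULL, n = 75L) {
  if (!nrow(filtered)) stop_mm("empty filtered contrast set")
  if (is.null(samples))
    samples <- sub("^mean_", "",
                   grep("^mean_", names(filtered), value = TRUE))
  o <- order(-abs(filtered$mean_diff_groups), filtered$chrom,
             filtered$start, method = "radix")
  filtered <- filtered[o, , drop = FALSE]
  hyper <- filtered[filtered$mean_diff_groups > 0, , drop = FALSE]
  hypo <- filtered[filtered$mean_diff_groups < 0, , drop = FALSE]
  for (nm in c("hyper", "hypo")) {
    x <- get(nm)
    if (nrow(x) < n)
      notice("only %d %smethylated DMRs available (top %d requested)",
             nrow(x), nm, n)
  }
  hyper <- utils::head(hyper, n); hypo <- utils::head(hypo, n)
  rownames(hyper) <- rownames(hypo) <- NULL
  plot_rows <- function(x, direction) {
    if (!nrow(x)) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(x)), function(i)
      data.frame(gene = x$gene[i], chrom = x$chrom[i], start = x$start[i],
                 end = x$end[i], direction = direction, sample = samples,
                 methylation = as.numeric(
                   x[i, paste0("mean_", samples)]),
                 stringsAsFactors = FALSE)))
  }
  plot_table <- rbind(plot_rows(hyper, "hyper"), plot_rows(hypo, "hypo"))
  list(hyper = hyper, hypo = hypo, plot_table = plot_table)
}
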