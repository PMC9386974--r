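#' Genes associated with significant DMRs of one comparison
#'
#' Keeps DMRs passing both thresholds (|mean methylation difference| >=
#' `min_abs_diff` and p-value <= `max_p`) and returns the unique nearest
#' annotated genes.
#'
#' @param dmrs annotated DMR data.frame (needs `mean_diff`, `p_value`,
#'   `nearest_gene_id`; run [annotate_dmrs()] first if absent — in that
#'   case pass `genes`).
#' @param genes gene models, only needed when `dmrs` lacks nearest-gene
#'   columns.
#' @param min_abs_diff,max_p thresholds (defaults: >= 0.25, <= 0.01).
#' @return Character vector of unique gene ids.
#' @export
dmr_gene_assignment <- function(dmrs, genes = NULL, min_abs_diff = 0.25,
                                max_p = 0.01) {
  if (is.null(dmrs$nearest_gene_id)) {
    if (is.null(genes)) stop_mm("dmrs lack nearest genes; supply `genes`")
    dmrs <- annotate_dmrs(dmrs, genes)
  }
  keep <- abs(dmrs$mean_diff) >= min_abs_diff & dmrs$p_value <= max_p
  unique(dmrs$nearest_gene_id[keep & !is.na(dmrs$nearest_gene_id)])
}

#' Hypergeometric gene-set overrepresentation test
#'
#' For each gene set: with universe size N, set size K (after intersection
#' with the universe), query size n and overlap k, the p-value is the
#' upper tail P(X >= k) of the hypergeometric distribution, and the odds
#' ratio comes from the 2x2 table `k, n-k, K-k, N-K-n+k` (Haldane 0.5
#' correction applied when any cell is zero).
#'
#' @param query character vector of query gene ids (subset of universe).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of background gene ids.
#' @return data.frame `set`, `N`, `K`, `n`, `k`, `p`, `padj_bh`,
#'   `odds_ratio`, sorted by p.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_mm("empty universe")
  query <- unique(intersect(query, universe))
  N <- length(universe); n <- length(query)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
    if (any(c(a, b, c, d) == 0)) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               odds_ratio = (a * d) / (b * c), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj_bh <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p, out$set, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "N", "K", "n", "k", "p", "padj_bh", "odds_ratio")]
}

#' Universe of genes with assayed CpGs
#'
#' Genes carrying at least one catalog CpG within the gene body or the
#' promoter window; avoids trivial enrichment of long genes.  Set
#' `all_genes = TRUE` for the plain all-annotated-genes universe.
#'
#' @param matrix a [methyl_matrix()].
#' @param genes gene models.
#' @param promoter_halfwidth promoter window half-width in bp.
#' @param all_genes return every annotated gene instead.
#' @return Character vector of gene ids.
#' @export
assayed_gene_universe <- function(matrix, genes,
                                  promoter_halfwidth = 1000L,
                                  all_genes = FALSE) {
  if (all_genes) return(genes$gene_id)
  cpg_r <- GenomicRanges::GRanges(
    matrix$chrom, IRanges::IRanges(matrix$pos + 1L, matrix$pos + 1L))
  gene_r <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(pmin(genes$start,
                               genes$tss - promoter_halfwidth), 0L) + 1L,
                     pmax(genes$end, genes$tss + promoter_halfwidth)))
  genes$gene_id[IRanges::overlapsAny(gene_r, cpg_r)]
}

#' Consensus pathway panel across comparisons
#'
#' Pathways significantly overrepresented (p <= `max_p`) in *every*
#' comparison, ranked by their minimum odds ratio across comparisons,
#' descending, truncated to `top_k`.
#'
#' @param results named list of [hypergeometric_enrichment()] tables, one
#'   per comparison.
#' @param max_p per-comparison significance threshold.
#' @param top_k panel size.
#' @return List with `panel` (data.frame `set`, `min_odds_ratio`) and
#'   `odds_matrix` (pathways x comparisons odds ratios).
#' @export
consensus_top_pathways <- function(results, max_p = 0.01, top_k = 40L) {
  if (!length(results)) stop_mm("need at least one comparison")
  sig_sets <- lapply(results, function(r) r$set[r$p <= max_p])
  consensus <- Reduce(intersect, sig_sets)
  if (!length(consensus))
    return(list(panel = data.frame(set = character(),
                                   min_odds_ratio = numeric()),
                odds_matrix = matrix(numeric(0), 0, length(results),
                                     dimnames = list(NULL, names(results)))))
  om <- vapply(results, function(r)
    r$odds_ratio[match(consensus, r$set)], numeric(length(consensus)))
  om <- matrix(om, nrow = length(consensus),
               dimnames = list(consensus, names(results)))
  min_or <- apply(om, 1, min)
  o <- order(-min_or, consensus, method = "radix")
  o <- utils::head(o, top_k)
  list(panel = data.frame(set = consensus[o], min_odds_ratio = min_or[o],
                          row.names = NULL, stringsAsFactors = FALSE),
       odds_matrix = om[o, , drop = FALSE])
}
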