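#' Most variable DMRs across samples
#'
#' Regions are ranked by the across-sample variance of their region-mean
#' methylation, descending; duplicate spans (identical regions emitted by
#' different comparisons) are merged first, keeping the maximum variance.
#'
#' @param region_means samples x regions numeric matrix (or regions given
#'   as rows via `regions` data.frame alongside a [methyl_matrix()] — see
#'   [unique_dmrs()] + [region_mean_matrix]).
#' @param regions data.frame describing the columns (`chrom`, `start`,
#'   `end`); used for duplicate-span merging and returned subset.
#' @param n number of regions to keep.
#' @return List with `regions` (the top rows, ranked) and `means` (the
#'   corresponding samples x regions matrix).
#' @export
top_variable_dmrs <- function(region_means, regions, n = 1000L) {
  if (n < 1) stop_mm("n must be >= 1")
  if (!ncol(region_means) || !nrow(regions)) stop_mm("empty region matrix")
  key <- paste(regions$chrom, regions$start, regions$end)
  v <- apply(region_means, 2, stats::var, na.rm = TRUE)
  o <- order(-v, key, method = "radix")
  o <- o[!duplicated(key[o])]           # duplicate spans: keep max variance
  if (length(o) < n) {
    notice("only %d unique regions available (top %d requested)",
           length(o), n)
    n <- length(o)
  }
  o <- o[seq_len(n)]
  list(regions = regions[o, , drop = FALSE],
       means = region_means[, o, drop = FALSE])
}

#' Euclidean distances between samples on region methylation
#'
#' Missing entries are imputed with the region's across-sample mean before
#' computing row-wise Euclidean norms.
#'
#' @param region_means samples x regions matrix.
#' @return Symmetric `dist`-convertible matrix of class `DistanceMatrix`
#'   with zero diagonal and sample names.
#' @export
euclidean_distances <- function(region_means) {
  if (nrow(region_means) < 2) stop_mm("need at least two samples")
  m <- region_means
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- mean(m[, j], na.rm = TRUE)
  }
  m[is.na(m)] <- 0          # regions undefined in every sample
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  class(d) <- c("DistanceMatrix", class(d))
  d
}

#' Hierarchical clustering of samples
#'
#' @param dist a symmetric distance matrix (e.g. from
#'   [euclidean_distances()]).
#' @param linkage agglomeration method for [stats::hclust()]
#'   (`"complete"`, `"single"`, `"average"`, `"ward.D2"`).
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(dist, linkage = "complete") {
  d <- unclass(as.matrix(dist))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop_mm("distance matrix is not symmetric")
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Sample-distance analysis of the most variable DMRs
#'
#' Convenience wrapper: merges all pairwise DMR tables into unique spans,
#' computes (optionally kernel-smoothed) region-mean methylation, keeps
#' the `top` most variable regions, and clusters samples on their
#' Euclidean distances.
#'
#' @param dmr_tables list from [pairwise_dmr_tables()].
#' @param matrix the [methyl_matrix()].
#' @param top number of most-variable regions.
#' @param linkage see [hierarchical_cluster()].
#' @param smooth_bandwidth bandwidth in bp for kernel smoothing of levels
#'   before region means; `NULL` for raw means.
#' @param samples restrict the analysis to these samples (default: all).
#' @return List with `regions`, `means`, `dist`, `hclust`.
#' @export
sample_distance_analysis <- function(dmr_tables, matrix, top = 1000L,
                                     linkage = "complete",
                                     smooth_bandwidth = 500,
                                     samples = NULL) {
  uni <- unique_dmrs(dmr_tables)
  if (!nrow(uni)) stop_mm("no DMRs to analyze")
  means <- t(region_mean_matrix(matrix, uni, smooth_bandwidth))
  if (!is.null(samples)) means <- means[samples, , drop = FALSE]
  tv <- top_variable_dmrs(means, uni, n = top)
  dm <- euclidean_distances(tv$means)
  list(regions = tv$regions, means = tv$means, dist = dm,
       hclust = hierarchical_cluster(dm, linkage))
}
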