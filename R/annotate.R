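#' Signed distance from DMRs to the nearest TSS
#'
#' Distances are measured in transcript orientation from the nearest TSS to
#' the nearest DMR edge: DMRs downstream of the TSS get positive distances,
#' DMRs upstream negative ones, and DMRs overlapping a TSS are counted as
#' zero.  Minus-strand genes mirror the sign.  The nearest gene is the one
#' whose TSS minimizes |distance|; ties are broken by the lexicographically
#' smaller `gene_id`.
#'
#' @param dmrs data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes gene models from [read_gene_annotation()].
#' @return data.frame with columns `tss_distance`, `nearest_gene_id`,
#'   `nearest_gene_name`, one row per DMR.
#' @export
tss_distance <- function(dmrs, genes) {
  if (!nrow(genes)) stop_mm("empty gene list")
  n <- nrow(dmrs)
  out <- data.frame(tss_distance = rep(NA_real_, n),
                    nearest_gene_id = NA_character_,
                    nearest_gene_name = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == dmrs$chrom[i], , drop = FALSE]
    if (!nrow(g)) g <- genes      # fall back to any gene, distance by |bp|
    d <- signed_tss_distance(dmrs$start[i], dmrs$end[i], g$tss, g$strand)
    d[g$chrom != dmrs$chrom[i]] <- Inf
    best <- order(abs(d), g$gene_id, method = "radix")[1]
    out$tss_distance[i] <- d[best]
    out$nearest_gene_id[i] <- g$gene_id[best]
    out$nearest_gene_name[i] <- g$gene_name[best]
  }
  out
}

# Vectorized over genes for one DMR [start, end); 0-based half-open.
signed_tss_distance <- function(start, end, tss, strand) {
  contains <- start <= tss & tss < end
  plus <- strand == "+"
  d <- numeric(length(tss))
  dn_p <- plus & !contains & start > tss          # downstream, + strand
  up_p <- plus & !contains & end <= tss           # upstream, + strand
  dn_m <- !plus & !contains & end <= tss          # downstream, - strand
  up_m <- !plus & !contains & start > tss         # upstream, - strand
  d[dn_p] <- start - tss[dn_p]
  d[up_p] <- end - tss[up_p]
  d[dn_m] <- tss[dn_m] - end + 1
  d[up_m] <- -(start - tss[up_m] - 1)
  d
}

#' Classify DMRs as promoter, intragenic or intergenic
#'
#' A DMR is a promoter DMR when it overlaps the window `TSS +/-
#' promoter_halfwidth` of any gene; otherwise intragenic when it overlaps
#' any gene body; otherwise intergenic (precedence promoter > intragenic >
#' intergenic).  The promoter region defaults to 1 kb around the TSS;
#' `promoter_halfwidth = 500` selects the alternative 1-kb-total reading.
#'
#' @param dmrs data.frame with `chrom`, `start`, `end`.
#' @param genes gene models.
#' @param promoter_halfwidth half-width in bp of the promoter window.
#' @return character vector in `{"promoter", "intragenic", "intergenic"}`.
#' @export
classify_dmr <- function(dmrs, genes, promoter_halfwidth = 1000L) {
  dmr_r <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  prom_r <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$tss - promoter_halfwidth, 0L) + 1L,
                     genes$tss + promoter_halfwidth))
  body_r <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
  cls <- rep("intergenic", nrow(dmrs))
  in_body <- IRanges::overlapsAny(dmr_r, body_r)
  cls[in_body] <- "intragenic"
  in_prom <- IRanges::overlapsAny(dmr_r, prom_r)
  cls[in_prom] <- "promoter"
  cls
}

#' Annotate DMRs with genomic class, TSS distance and nearest gene
#'
#' @inheritParams classify_dmr
#' @return The input data.frame with columns `genomic_class`,
#'   `tss_distance`, `nearest_gene_id`, `nearest_gene_name` appended.
#' @export
annotate_dmrs <- function(dmrs, genes, promoter_halfwidth = 1000L) {
  td <- tss_distance(dmrs, genes)
  dmrs$genomic_class <- classify_dmr(dmrs, genes, promoter_halfwidth)
  dmrs$tss_distance <- td$tss_distance
  dmrs$nearest_gene_id <- td$nearest_gene_id
  dmrs$nearest_gene_name <- td$nearest_gene_name
  dmrs
}

#' Genomic-class composition of an annotated DMR set
#'
#' @param annotated data.frame with a `genomic_class` column.
#' @return Named numeric vector of fractions `(promoter, intragenic,
#'   intergenic)` summing to 1.
#' @export
location_composition <- function(annotated) {
  if (!nrow(annotated)) stop_mm("empty DMR list")
  cls <- factor(annotated$genomic_class,
                levels = c("promoter", "intragenic", "intergenic"))
  tab <- table(cls)
  as.numeric(tab) / nrow(annotated) -> fr
  names(fr) <- names(tab)
  fr
}

#' Histogram of signed TSS distances
#'
#' @param annotated data.frame with `tss_distance`.
#' @param bin_width bin width in bp (> 0); bins are symmetric around 0
#'   (the central bin is `[-bin_width/2, bin_width/2)`).
#' @return data.frame with `bin_mid` and `count`; counts sum to the number
#'   of DMRs.
#' @export
tss_distance_histogram <- function(annotated, bin_width) {
  if (bin_width <= 0) stop_mm("bin_width must be > 0")
  d <- annotated$tss_distance
  bin <- floor((d + bin_width / 2) / bin_width)
  tab <- table(bin)
  data.frame(bin_mid = as.numeric(names(tab)) * bin_width,
             count = as.integer(tab))
}
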