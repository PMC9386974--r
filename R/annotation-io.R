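#' Read gene models from a GTF/GFF annotation
#'
#' Parses an Ensembl-dialect GTF (or GFF3) and collapses it to one gene
#' model per gene.  The representative transcript is the longest annotated
#' transcript (length = sum of exon widths, or the transcript span when no
#' exons are given); its 5' end in transcript orientation defines the gene
#' TSS, so a minus-strand transcript has its TSS at its maximum coordinate.
#' All coordinates are converted to 0-based half-open internally.
#'
#' @param path GTF or GFF3 file.
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open union span of the gene's
#'   transcripts), `tss` (0-based), `tx_length` (bp of the representative
#'   transcript).  The exon intervals of the representative transcripts are
#'   attached as attribute `"exons"` (data.frame `gene_id`, `start`, `end`).
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!nrow(df)) stop_mm("empty annotation: %s", path)
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  bad <- !df$strand %in% c("+", "-")
  if (any(bad & df$type %in% c("gene", "transcript", "mRNA", "exon"))) {
    warning(sprintf("%d feature(s) without usable strand skipped",
                    sum(bad)), call. = FALSE)
  }
  df <- df[!bad, , drop = FALSE]
  if (is.null(df$gene_id)) stop_mm("annotation lacks gene_id attributes")
  build_gene_models(df)
}

# df: 1-based closed coordinates as returned by rtracklayer::import().
build_gene_models <- function(df) {
  tx_types <- c("transcript", "mRNA")
  tx <- df[df$type %in% tx_types, , drop = FALSE]
  ex <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(tx)) {
    # gene-only annotation: treat each gene row as its own transcript
    tx <- df[df$type == "gene", , drop = FALSE]
    tx$transcript_id <- tx$gene_id
  }
  if (!nrow(tx)) stop_mm("annotation contains no gene or transcript features")
  if (is.null(tx$transcript_id)) tx$transcript_id <- tx$gene_id
  # transcript length: sum of exon widths where exons exist, else span
  tx$tx_length <- tx$end - tx$start + 1L
  if (nrow(ex) && !is.null(ex$transcript_id)) {
    exlen <- tapply(ex$end - ex$start + 1L, ex$transcript_id, sum)
    hit <- match(tx$transcript_id, names(exlen))
    tx$tx_length[!is.na(hit)] <- as.integer(exlen[hit[!is.na(hit)]])
  }
  # representative transcript = longest; ties broken by transcript_id
  o <- order(tx$gene_id, -tx$tx_length, tx$transcript_id, method = "radix")
  tx <- tx[o, , drop = FALSE]
  rep_tx <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  # union gene span over all transcripts
  span_start <- tapply(tx$start, tx$gene_id, min)
  span_end <- tapply(tx$end, tx$gene_id, max)
  gi <- rep_tx$gene_id
  gene_name <- rep_tx$gene_name
  if (is.null(gene_name)) gene_name <- rep(NA_character_, nrow(rep_tx))
  genes <- data.frame(
    gene_id = gi,
    gene_name = as.character(gene_name),
    chrom = as.character(rep_tx$seqnames),
    strand = rep_tx$strand,
    start = as.integer(span_start[gi]) - 1L,        # to 0-based half-open
    end = as.integer(span_end[gi]),
    tss = ifelse(rep_tx$strand == "+",
                 as.integer(rep_tx$start) - 1L,
                 as.integer(rep_tx$end) - 1L),
    tx_length = as.integer(rep_tx$tx_length),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id,
                       method = "radix"), , drop = FALSE]
  rownames(genes) <- NULL
  exons <- if (nrow(ex)) {
    keep <- if (!is.null(ex$transcript_id))
      ex$transcript_id %in% rep_tx$transcript_id else rep(TRUE, nrow(ex))
    data.frame(gene_id = ex$gene_id[keep],
               start = as.integer(ex$start[keep]) - 1L,
               end = as.integer(ex$end[keep]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), start = integer(), end = integer())
  }
  attr(genes, "exons") <- exons
  genes
}

#' Write DMRs as a BED6+ table
#'
#' Columns: chrom, start, end, name (`comparison#idx`), score
#' (`round(1000 * |mean_diff|)`), strand ".", then `n_cpgs`, `mean_diff`,
#' `p_value` and any further columns present (`genomic_class`,
#' `tss_distance`, `nearest_gene`, ...).
#'
#' @param dmrs DMR data.frame (see [segment_dmrs()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  cmp <- if (!is.null(dmrs$comparison)) dmrs$comparison else "dmr"
  extra_cols <- setdiff(names(dmrs),
                        c("chrom", "start", "end", "comparison"))
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                    name = paste0(cmp, "#", seq_len(nrow(dmrs))),
                    score = as.integer(round(1000 * abs(dmrs$mean_diff))),
                    strand = ".", stringsAsFactors = FALSE)
  for (cn in extra_cols) bed[[cn]] <- dmrs[[cn]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, genes...).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)
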