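#' Default pipeline configuration
#'
#' All thresholds surface here with the study defaults: coverage >= 5,
#' DMRs with >= 3 CpGs and >= 25% mean difference, promoter = TSS +/- 1
#' kb, marker selection > 40% with top 12 per population, top 1,000
#' most-variable DMRs for clustering, contrast ledger >= 0.5 in all
#' comparisons within 5 kb of a TSS (top 75 per direction), enrichment
#' p <= 0.01 with a top-40 consensus panel, motif discovery with 10-nt
#' flanks and an E < 0.05 cutoff.
#'
#' @param seed master seed.
#' @param ... overrides of any default (see source for the full list).
#' @return Named list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    simulation = list(),          # overrides for simulation_config()
    min_cov = 5L, min_samples = 1L,
    min_cpgs = 3L, min_diff = 0.25, max_cpg_gap = 500L, dmr_max_p = 0.05,
    promoter_halfwidth = 1000L, tss_bin_width = 1000L,
    marker_min_diff = 0.40, marker_top = 12L,
    correlation_target = "ILC2",
    top_dmrs = 1000L, linkage = "complete", smooth_bandwidth = 500,
    contrast_min_diff = 0.5, tss_window = 5000L, top_ledger = 75L,
    enrich_p = 0.01, top_pathways = 40L,
    motif_flank = 10L, n_motifs = 20L, motif_e = 0.05,
    motif_widths = c(6L, 8L, 10L), motif_shuffles = 99L,
    motif_max_seqs = 40L, motif_max_len = 250L,
    de_min_lfc = 2, de_max_padj = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_mm("unknown config key(s): %s",
                               paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Stage order: simulate -> coverage filter -> pairwise DMR calling ->
#' genomic annotation -> marker selection -> sample distances ->
#' expression integration -> group contrast -> pathway enrichment ->
#' motif discovery.  All stage outputs are written under `out_dir` (when
#' given) and summarized in the returned report, which is byte-stable
#' under a fixed seed (timings excluded).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; `NULL` keeps everything in memory.
#' @param sim optionally, a pre-built [simulate_ilc_study()] result (its
#'   config seed should match).
#' @return List of class `PipelineReport` (see `$report` for the
#'   serializable summary; heavyweight objects under `$data`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         sim = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ## simulate
  if (is.null(sim)) {
    sim_cfg <- do.call(simulation_config,
                       c(list(seed = config$seed), config$simulation))
    sim <- simulate_ilc_study(sim_cfg)
  }
  pops <- sim$config$populations
  th <- sim$config$th_populations
  tick("simulate")

  ## coverage filter
  mat <- filter_by_coverage(sim$matrix, config$min_cov, config$min_samples)
  tick("coverage_filter")

  ## pairwise DMRs among the primary populations
  dmr_dir <- if (!is.null(out_dir)) file.path(out_dir, "dmrs") else NULL
  tables <- pairwise_dmr_tables(mat, config$min_cpgs, config$min_diff,
                                config$max_cpg_gap, config$dmr_max_p,
                                samples = pops, out_dir = dmr_dir)
  dmr_counts <- vapply(tables, nrow, integer(1))
  tick("dmr_calling")

  ## annotation of the unique DMR set
  genes <- sim$genome$genes
  uni <- unique_dmrs(tables)
  annotated <- if (nrow(uni))
    annotate_dmrs(uni, genes, config$promoter_halfwidth) else uni
  composition <- if (nrow(uni)) as.list(location_composition(annotated))
  else list(promoter = NA, intragenic = NA, intergenic = NA)
  hist_tab <- if (nrow(uni))
    tss_distance_histogram(annotated, config$tss_bin_width) else NULL
  if (!is.null(out_dir) && nrow(uni)) {
    write_dmr_bed(annotated, file.path(out_dir, "dmrs_annotated.bed"))
    utils::write.table(hist_tab, file.path(out_dir, "tss_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("annotation")

  ## marker selection per population
  markers <- list()
  for (p in pops)
    markers[[p]] <- select_markers(
      tables, mat, genes, p, min_diff = config$marker_min_diff,
      top = config$marker_top,
      promoter_halfwidth = config$promoter_halfwidth,
      assoc_window = config$tss_window)
  if (!is.null(out_dir)) {
    all_mk <- do.call(rbind, markers)
    utils::write.table(all_mk, file.path(out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("markers")

  ## sample distances and clustering (all samples, most variable DMRs)
  distance <- if (nrow(uni) >= 2) {
    sd_res <- sample_distance_analysis(
      tables, mat, top = config$top_dmrs, linkage = config$linkage,
      smooth_bandwidth = config$smooth_bandwidth)
    if (!is.null(out_dir)) {
      utils::write.table(as.matrix(unclass(sd_res$dist)),
                         file.path(out_dir, "sample_distances.tsv"),
                         sep = "\t", quote = FALSE)
      write_newick(sd_res$hclust, file.path(out_dir, "dendrogram.nwk"))
    }
    sd_res
  } else NULL
  tick("distances")

  ## expression integration: correlation per comparison vs the target
  target <- config$correlation_target
  correlations <- list()
  expr <- sim$expression
  mk <- markers[[target]]
  if (!is.null(mk) && nrow(mk) >= 3 && target %in% pops) {
    nm <- normalize_counts(expr$counts)
    gene_of <- mk$gene
    gid <- genes$gene_id[match(gene_of, genes$gene_name)]
    for (o in setdiff(pops, target)) {
      lfc_all <- log2_fold_change(nm$normalized, expr$groups, o, target)
      md <- stats::setNames(mk[[paste0("mean_", o)]] -
                              mk[[paste0("mean_", target)]], gene_of)
      lf <- stats::setNames(lfc_all[gid], gene_of)
      res <- tryCatch(methylation_expression_correlation(md, lf),
                      error = function(e) NULL)
      if (!is.null(res))
        correlations[[paste0(o, "_vs_", target)]] <-
          list(R = res$R, R2 = res$R2, p = res$p, label = res$label,
               n = nrow(res$pairs))
    }
  }
  tick("expression")

  ## group contrast (needs the second super-group)
  contrast <- NULL
  if (length(th)) {
    cross <- list()
    for (a in pops) for (b in th) {
      track <- per_cpg_difference(mat, a, b)
      dm <- segment_dmrs(track, config$min_cpgs, config$min_diff,
                         config$max_cpg_gap)
      dm <- score_dmr_table(dm, mat, a, b, config$min_cpgs)
      cross[[paste0(a, "_vs_", b)]] <-
        dm[is.na(dm$p_value) | dm$p_value <= config$dmr_max_p, ,
           drop = FALSE]
    }
    cuni <- unique_dmrs(cross)
    filt <- filter_contrast(cuni, mat, genes, pops, th,
                            min_abs_diff = config$contrast_min_diff,
                            tss_window = config$tss_window)
    contrast <- if (nrow(filt))
      top_hyper_hypo(filt, samples = c(pops, th), n = config$top_ledger)
    else list(hyper = filt, hypo = filt, plot_table = NULL)
    if (!is.null(out_dir) && nrow(filt)) {
      utils::write.table(contrast$hyper,
                         file.path(out_dir, "contrast_hyper.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(contrast$hypo,
                         file.path(out_dir, "contrast_hypo.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  tick("contrast")

  ## pathway enrichment on per-comparison DMR genes
  gene_sets <- make_toy_gene_sets(genes, sim$truth, seed = sim$config$seed)
  universe <- assayed_gene_universe(mat, genes, config$promoter_halfwidth)
  enr <- list()
  for (lab in names(tables)) {
    tab <- tables[[lab]]
    if (!nrow(tab)) next
    ann <- annotate_dmrs(tab, genes, config$promoter_halfwidth)
    q <- dmr_gene_assignment(ann, min_abs_diff = config$min_diff,
                             max_p = config$enrich_p)
    if (length(q))
      enr[[lab]] <- hypergeometric_enrichment(q, gene_sets, universe)
  }
  consensus <- if (length(enr))
    consensus_top_pathways(enr, max_p = config$enrich_p,
                           top_k = config$top_pathways) else NULL
  tick("enrichment")

  ## motif discovery in target-comparison DMRs
  motifs <- NULL; motif_matches <- NULL
  target_tabs <- tables[grepl(paste0("(^", target, "_vs_|_vs_", target,
                                     "$)"), names(tables))]
  # motifs are sought in regions demethylated in the target population
  # (transcription-factor footprints)
  for (lab in names(target_tabs)) {
    ab <- strsplit(lab, "_vs_", fixed = TRUE)[[1]]
    want_sign <- if (ab[1] == target) -1 else 1
    tt <- target_tabs[[lab]]
    target_tabs[[lab]] <- tt[sign(tt$mean_diff) == want_sign, ,
                             drop = FALSE]
  }
  if (length(target_tabs)) {
    mu <- unique_dmrs(target_tabs)
    if (nrow(mu) >= 10) {
      mu <- mu[order(-abs(mu$mean_diff), mu$chrom, mu$start,
                     method = "radix"), , drop = FALSE]
      mu <- utils::head(mu, config$motif_max_seqs)
      # trim very long spans to their central window to bound compute
      wide <- mu$end - mu$start > config$motif_max_len
      mid <- floor((mu$start + mu$end) / 2)
      mu$start[wide] <- mid[wide] - config$motif_max_len %/% 2
      mu$end[wide] <- mu$start[wide] + config$motif_max_len
      seqs <- extract_dmr_sequences(mu, sim$genome$sequences,
                                    flank = config$motif_flank)
      disc <- discover_motifs(seqs, widths = config$motif_widths,
                              n_motifs = config$n_motifs,
                              seed = config$seed,
                              n_shuffles = config$motif_shuffles)
      motifs <- filter_low_complexity(disc, max_e = config$motif_e)
      if (length(motifs)) {
        db <- make_toy_pwm_database(sim$config$motif_consensus,
                                    seed = sim$config$seed)
        motif_matches <- match_pwm(motifs[[1]]$pwm, db, seed = config$seed)
        if (!is.null(out_dir)) {
          write_meme_motifs(motifs, file.path(out_dir, "motifs.meme.txt"))
          utils::write.table(motif_matches,
                             file.path(out_dir, "motif_matches.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }
  tick("motifs")

  report <- list(
    parameters = unclass(config)[setdiff(names(config), "simulation")],
    populations = pops, th_populations = th,
    n_cpgs_assayed = length(mat$pos),
    dmr_counts = as.list(dmr_counts),
    genomic_class_composition = composition,
    markers = lapply(markers, function(m)
      if (nrow(m)) m$gene else character(0)),
    correlations = correlations,
    contrast_sizes = if (!is.null(contrast))
      list(hyper = nrow(contrast$hyper), hypo = nrow(contrast$hypo))
    else NULL,
    enrichment_consensus = if (!is.null(consensus))
      as.list(stats::setNames(consensus$panel$min_odds_ratio,
                              consensus$panel$set)) else NULL,
    motifs = if (!is.null(motifs) && length(motifs))
      lapply(unclass(motifs), function(m)
        list(consensus = m$consensus, width = m$width,
             n_sites = m$n_sites, evalue = m$evalue)) else list(),
    top_motif_match = if (!is.null(motif_matches))
      motif_matches$target[1] else NULL,
    timing = timing)
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  structure(list(report = report,
                 data = list(sim = sim, matrix = mat, dmr_tables = tables,
                             annotated = annotated, markers = markers,
                             distance = distance, contrast = contrast,
                             enrichment = enr, consensus = consensus,
                             motifs = motifs,
                             motif_matches = motif_matches)),
            class = "PipelineReport")
}

#' @export
print.PipelineReport <- function(x, ...) {
  r <- x$report
  cat("methylmark pipeline report\n")
  cat(sprintf("  assayed CpGs: %d\n", r$n_cpgs_assayed))
  cat(sprintf("  DMR tables: %d (total %d DMRs)\n",
              length(r$dmr_counts), sum(unlist(r$dmr_counts))))
  cmp <- r$genomic_class_composition
  if (!is.null(cmp$promoter) && !is.na(cmp$promoter))
    cat(sprintf("  composition: %.0f%% intragenic / %.0f%% intergenic / %.0f%% promoter\n",
                100 * cmp$intragenic, 100 * cmp$intergenic,
                100 * cmp$promoter))
  for (nm in names(r$correlations))
    cat(sprintf("  correlation %s: R = %.2f (%s)\n", nm,
                r$correlations[[nm]]$R, r$correlations[[nm]]$label))
  if (length(r$motifs))
    cat(sprintf("  top motif: %s (E = %.3g)\n", r$motifs[[1]]$consensus,
                r$motifs[[1]]$evalue))
  invisible(x)
}
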