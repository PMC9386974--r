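## Seeded synthetic-data generator: genomes with placed CpGs, tiled gene
## models, multi-population methylomes with planted hypomethylated blocks,
## coupled expression counts, and planted motif occurrences — the ground
## truth every downstream stage is validated against.

#' Simulation configuration
#'
#' Defaults emulate the structure of a lymphocyte WGBS/RNA-seq study at
#' desk scale: 2 chromosomes x 2 Mb with ~20,000 CpGs, five innate
#' lymphoid populations (plus, optionally, three T-helper populations for
#' the group contrast), unicate methylomes at Poisson(20) coverage over a
#' bimodal Beta background, 25 population-exclusive hypomethylated blocks
#' per population (12 of them gene-associated marker blocks with coupled
#' expression, 13 intergenic), extra blocks shared by the ILC3/LTi sister
#' pair, and group-discriminating blocks between the ILC and Th
#' super-groups.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @param n_chromosomes,chrom_length,cpg_density genome shape.
#' @param populations methylome population names.
#' @param th_populations second super-group; `character(0)` disables the
#'   contrast layer.
#' @param gene_spacing,gene_length gene tiling in bp.
#' @param placeholder_name_every every k-th gene gets a non-canonical
#'   placeholder name (Gm-style).
#' @param background_alpha,background_beta Beta background of methylation
#'   levels (bimodal, mean ~0.75, emulating a mostly methylated genome).
#' @param jitter_sd per-(CpG, population) Gaussian jitter of levels.
#' @param coverage_mean Poisson mean read coverage.
#' @param exclusive_blocks_per_pop planted exclusive blocks per population
#'   (marker blocks included).
#' @param n_marker_genes gene-associated marker blocks per population.
#' @param block_len_range planted block length range in CpGs.
#' @param delta_range hypomethylation depth range for non-marker blocks.
#' @param marker_delta_range depth range for marker blocks.
#' @param block_base_range baseline methylation inside planted blocks.
#' @param max_block_gap maximal bp gap between consecutive CpGs of a
#'   planted block (blocks live in locally CpG-dense stretches).
#' @param sister_pair,shared_blocks populations sharing extra blocks.
#' @param group_blocks group-discriminating blocks per direction.
#' @param group_delta_range depth range for group blocks.
#' @param expression_replicates,expression_dispersion RNA-seq layer.
#' @param marker_slope,marker_noise_sd methylation-expression coupling:
#'   a marker gene with depth `delta` is upregulated in its population by
#'   `marker_slope * delta + Normal(0, marker_noise_sd)` log2 units.
#' @param motif_consensus,motif_fraction planted motif and the fraction of
#'   the marker population's blocks carrying it.
#' @param motif_population population whose blocks receive the motif.
#' @return List of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 2e6,
                              cpg_density = 0.005,
                              populations = c("ILC1", "ILC2", "ILC3",
                                              "LTi", "NK"),
                              th_populations = c("Th1", "Th2", "Th17"),
                              gene_spacing = 20000L,
                              gene_length = 6000L,
                              placeholder_name_every = 10L,
                              background_alpha = 0.6,
                              background_beta = 0.2,
                              jitter_sd = 0.03,
                              coverage_mean = 20,
                              exclusive_blocks_per_pop = 25L,
                              n_marker_genes = 12L,
                              block_len_range = c(5L, 20L),
                              delta_range = c(0.4, 0.8),
                              marker_delta_range = c(0.5, 0.85),
                              block_base_range = c(0.85, 0.98),
                              max_block_gap = 500L,
                              sister_pair = c("ILC3", "LTi"),
                              shared_blocks = 15L,
                              group_blocks = 30L,
                              group_delta_range = c(0.5, 0.8),
                              expression_replicates = 3L,
                              expression_dispersion = 0.05,
                              marker_slope = 4,
                              marker_noise_sd = 0.25,
                              motif_consensus = "TGACTCAG",
                              motif_fraction = 0.8,
                              motif_population = "ILC2") {
  cfg <- as.list(environment())
  stopifnot(cfg$cpg_density > 0, cfg$cpg_density < 0.5,
            all(cfg$delta_range > 0), all(cfg$delta_range <= 1),
            cfg$background_alpha > 0, cfg$background_beta > 0)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a genome: sequence with placed CpGs, plus tiled gene models
#'
#' CpG dinucleotides are placed at the configured density (incidental CG
#' occurrences are removed first, so the catalog equals the realized CG
#' positions); genes are tiled along each chromosome with promoters,
#' three exons and intergenic gaps, on alternating strands.
#'
#' @param config a [simulation_config()].
#' @return List with `sequences` (`DNAStringSet`), `cpgs` (data.frame
#'   `chrom`, `pos`, 0-based), `genes` (gene models as in
#'   [read_gene_annotation()], with exons attribute).
#' @export
simulate_genome <- function(config) {
  set.seed(derive_seed(config$seed, 1))
  L <- as.integer(config$chrom_length)
  n_cpg_per <- round(config$cpg_density * L)
  if (n_cpg_per > floor((L - 2) / 2))
    stop_mm("cpg_density incompatible with chromosome length")
  seqs <- character(config$n_chromosomes)
  cpg_list <- list()
  gene_rows <- list(); exon_rows <- list()
  gene_counter <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    cg <- which(s[-L] == "C" & s[-1] == "G")
    if (length(cg)) s[cg + 1L] <- "A"       # no incidental CpGs
    p <- sort(sample(seq.int(2L, L - 2L, by = 2L), n_cpg_per))
    s[p] <- "C"; s[p + 1L] <- "G"
    seqs[ci] <- paste(s, collapse = "")
    cpg_list[[ci]] <- data.frame(chrom = chrom, pos = p - 1L,
                                 stringsAsFactors = FALSE)
    starts <- seq.int(5000L, L - config$gene_length - 5000L,
                      by = config$gene_spacing)
    for (g in seq_along(starts)) {
      gene_counter <- gene_counter + 1L
      gid <- sprintf("GENE%05d", gene_counter)
      gname <- if (gene_counter %% config$placeholder_name_every == 0)
        sprintf("Gm%05d", gene_counter) else sprintf("Gene%05d", gene_counter)
      strand <- if (g %% 2 == 0) "-" else "+"
      st <- starts[g]; en <- st + config$gene_length   # 0-based half-open
      gene_rows[[gene_counter]] <- data.frame(
        gene_id = gid, gene_name = gname, chrom = chrom, strand = strand,
        start = st, end = en,
        tss = if (strand == "+") st else en - 1L,
        tx_length = 3000L, stringsAsFactors = FALSE)
      rel <- rbind(c(0L, 1000L), c(2500L, 3500L), c(5000L, 6000L))
      exon_rows[[gene_counter]] <- data.frame(
        gene_id = gid, start = st + rel[, 1], end = st + rel[, 2],
        stringsAsFactors = FALSE)
    }
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- paste0("chr", seq_len(config$n_chromosomes))
  genes <- do.call(rbind, gene_rows)
  attr(genes, "exons") <- do.call(rbind, exon_rows)
  list(sequences = sequences, cpgs = do.call(rbind, cpg_list),
       genes = genes)
}

#' Write simulated gene models as a GTF file
#' @param genes gene models with exons attribute (0-based half-open).
#' @param path output GTF path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(genes, path) {
  exons <- attr(genes, "exons")
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    at <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                  g$gene_id, g$gene_id, g$gene_name)
    lines <- c(lines,
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, g$start + 1L, g$end, g$strand, at),
               sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, g$start + 1L, g$end, g$strand, at))
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines,
                 sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                         g$chrom, ex$start[j] + 1L, ex$end[j], g$strand, at))
  }
  writeLines(lines, path)
  invisible(path)
}

# --- planted-block allocation --------------------------------------------

# valid start indices for a run of len CpGs whose internal gaps are all
# <= max_gap and which stays on one chromosome and untaken
valid_block_starts <- function(cpgs, len, max_gap, taken) {
  n <- nrow(cpgs)
  if (len > n) return(integer(0))
  gap_ok <- c(diff(cpgs$pos) <= max_gap &
                cpgs$chrom[-1] == cpgs$chrom[-n], FALSE)
  bad <- cumsum(!gap_ok)
  starts <- seq_len(n - len + 1L)
  ok <- if (len == 1L) rep(TRUE, length(starts)) else
    bad[starts + len - 2L] - c(0, bad[starts[-1] - 1L]) == 0
  tk <- cumsum(taken)
  free <- tk[starts + len - 1L] - c(0, tk[starts[-1] - 1L]) == 0 &
    !taken[starts]
  starts[ok & free]
}

allocate_block <- function(cpgs, len, max_gap, taken, within = NULL,
                           full = FALSE) {
  starts <- valid_block_starts(cpgs, len, max_gap, taken)
  if (!is.null(within)) {
    if (full) {
      # the whole run must lie inside the allowed index set
      allowed <- rep(FALSE, nrow(cpgs))
      allowed[within] <- TRUE
      na0 <- c(0, cumsum(!allowed))
      starts <- starts[na0[starts + len] - na0[starts] == 0]
    } else starts <- intersect(starts, within)
  }
  if (!length(starts)) return(NULL)
  s <- if (length(starts) == 1) starts else sample(starts, 1)
  s:(s + len - 1L)
}

#' Simulate multi-population methylomes with planted DMR blocks
#'
#' Per CpG, a background level drawn from Beta(alpha, beta) is shared
#' across populations; planted blocks sit on a high-methylation baseline
#' and are reduced by their depth `delta` in the affected populations.
#' Per-population Gaussian jitter is added, and the observed level is
#' `Binomial(coverage, level) / coverage` with Poisson coverage (missing
#' where coverage is 0).
#'
#' @param genome output of [simulate_genome()].
#' @param config the [simulation_config()].
#' @return List with `matrix` (a [methyl_matrix()] over all populations)
#'   and `truth` (data.frame of planted blocks: `chrom`, `start`, `end`,
#'   `cpg_from`, `cpg_to`, `delta`, `type`, `gene`, `populations`
#'   (comma-separated affected populations)).
#' @export
simulate_methylomes <- function(genome, config) {
  set.seed(derive_seed(config$seed, 2))
  cpgs <- genome$cpgs
  genes <- genome$genes
  n <- nrow(cpgs)
  pops <- c(config$populations, config$th_populations)
  ilc <- config$populations
  taken <- rep(FALSE, n)
  blocks <- list()
  add_block <- function(idx, delta, type, gene, affected) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      chrom = cpgs$chrom[idx[1]], start = cpgs$pos[idx[1]],
      end = cpgs$pos[idx[length(idx)]] + 1L,
      cpg_from = idx[1], cpg_to = idx[length(idx)],
      delta = delta, type = type, gene = gene,
      populations = paste(affected, collapse = ","),
      stringsAsFactors = FALSE)
    taken[idx] <<- TRUE
  }
  rlen <- function() sample(config$block_len_range[1]:config$block_len_range[2], 1)
  runif1 <- function(r) stats::runif(1, r[1], r[2])

  # CpG indices near each gene TSS (promoter +/- 1 kb) and intergenic ones
  tss_prox <- function(g, win = 1000L) {
    which(cpgs$chrom == g$chrom & cpgs$pos >= g$tss - win &
            cpgs$pos <= g$tss + win)
  }
  far_from_genes <- {
    far <- rep(TRUE, n)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      hit <- cpgs$chrom == g$chrom &
        cpgs$pos >= min(g$start, g$tss - 5000L) - 1000L &
        cpgs$pos <= max(g$end, g$tss + 5000L) + 1000L
      far[hit] <- FALSE
    }
    which(far)
  }
  canonical <- !grepl("^(Gm[0-9]+|.*Rik)$", genes$gene_name)
  gene_pool <- sample(which(canonical))   # draw genes without replacement
  take_gene <- function() {
    if (!length(gene_pool)) return(NULL)
    g <- gene_pool[1]; gene_pool <<- gene_pool[-1]; g
  }

  # marker blocks: gene-associated, exclusive to one population
  for (p in ilc) {
    for (k in seq_len(config$n_marker_genes)) {
      repeat {
        gi <- take_gene()
        if (is.null(gi)) break
        g <- genes[gi, ]
        prox <- tss_prox(g)
        len <- min(rlen(), length(prox))
        if (len < config$block_len_range[1]) next
        idx <- allocate_block(cpgs, len, config$max_block_gap, taken,
                              within = prox)
        if (is.null(idx)) next
        add_block(idx, runif1(config$marker_delta_range), "marker",
                  g$gene_name, p)
        break
      }
    }
  }
  # remaining exclusive blocks: intergenic, far from genes
  n_inter <- config$exclusive_blocks_per_pop - config$n_marker_genes
  for (p in ilc) {
    for (k in seq_len(max(n_inter, 0L))) {
      for (try in 1:50) {
        idx <- allocate_block(cpgs, rlen(), config$max_block_gap, taken,
                              within = far_from_genes, full = TRUE)
        if (!is.null(idx)) {
          add_block(idx, runif1(config$delta_range), "exclusive",
                    NA_character_, p)
          break
        }
      }
    }
  }
  # blocks shared by the sister pair
  if (length(config$sister_pair) == 2 && config$shared_blocks > 0) {
    for (k in seq_len(config$shared_blocks)) {
      idx <- allocate_block(cpgs, rlen(), config$max_block_gap, taken)
      if (!is.null(idx))
        add_block(idx, runif1(config$delta_range), "shared",
                  NA_character_, config$sister_pair)
    }
  }
  # group-discriminating blocks near gene TSSs (both directions)
  if (length(config$th_populations) && config$group_blocks > 0) {
    for (dir in c("ilc_hypo", "th_hypo")) {
      affected <- if (dir == "ilc_hypo") ilc else config$th_populations
      for (k in seq_len(config$group_blocks)) {
        repeat {
          gi <- take_gene()
          if (is.null(gi)) break
          g <- genes[gi, ]
          prox <- tss_prox(g, 2000L)
          len <- min(rlen(), length(prox))
          if (len < config$block_len_range[1]) next
          idx <- allocate_block(cpgs, len, config$max_block_gap, taken,
                                within = prox)
          if (is.null(idx)) next
          add_block(idx, runif1(config$group_delta_range), dir,
                    g$gene_name, affected)
          break
        }
      }
    }
  }
  truth <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               cpg_from = integer(), cpg_to = integer(), delta = numeric(),
               type = character(), gene = character(),
               populations = character(), stringsAsFactors = FALSE)

  # latent levels
  baseline <- stats::rbeta(n, config$background_alpha, config$background_beta)
  for (b in seq_len(nrow(truth))) {
    idx <- truth$cpg_from[b]:truth$cpg_to[b]
    baseline[idx] <- stats::runif(length(idx), config$block_base_range[1],
                                  config$block_base_range[2])
  }
  level <- matrix(baseline, n, length(pops))
  colnames(level) <- pops
  for (b in seq_len(nrow(truth))) {
    idx <- truth$cpg_from[b]:truth$cpg_to[b]
    aff <- strsplit(truth$populations[b], ",")[[1]]
    level[idx, aff] <- pmax(level[idx, aff] - truth$delta[b], 0.02)
  }
  level <- level + matrix(stats::rnorm(n * length(pops), 0, config$jitter_sd),
                          n, length(pops))
  level <- pmin(pmax(level, 0), 1)
  coverage <- matrix(stats::rpois(n * length(pops), config$coverage_mean),
                     n, length(pops))
  obs <- matrix(stats::rbinom(n * length(pops), coverage, level), n,
                length(pops)) / ifelse(coverage > 0, coverage, 1)
  obs[coverage == 0] <- NA_real_
  list(matrix = methyl_matrix(cpgs$chrom, cpgs$pos, obs, coverage, pops),
       truth = truth)
}

#' Planted truth for one pairwise comparison
#'
#' A planted block is a true DMR of the pair (a, b) exactly when it
#' affects one of the two populations but not the other.
#'
#' @param truth truth data.frame from [simulate_methylomes()].
#' @param a,b population names.
#' @return The subset of truth rows differential for this pair.
#' @export
truth_for_pair <- function(truth, a, b) {
  aff <- strsplit(truth$populations, ",")
  in_a <- vapply(aff, function(x) a %in% x, logical(1))
  in_b <- vapply(aff, function(x) b %in% x, logical(1))
  truth[xor(in_a, in_b), , drop = FALSE]
}

#' Simulate expression counts coupled to planted marker methylation
#'
#' Baseline counts are negative binomial around gene-specific lognormal
#' means, with `expression_replicates` replicates per population.  A
#' marker gene planted for population P is upregulated in P by
#' `2^(marker_slope * delta + Normal(0, marker_noise_sd))`.
#'
#' @param genome output of [simulate_genome()].
#' @param truth truth table from [simulate_methylomes()].
#' @param config the [simulation_config()].
#' @return List with `counts` (genes x samples), `groups` (named vector
#'   sample -> population), `lengths` (per-gene bp), `marker_effects`
#'   (data.frame `gene`, `population`, `delta`, `log2fc_planted`).
#' @export
simulate_expression <- function(genome, truth, config) {
  set.seed(derive_seed(config$seed, 3))
  genes <- genome$genes
  pops <- config$populations
  reps <- config$expression_replicates
  samples <- paste0(rep(pops, each = reps), "_r", seq_len(reps))
  groups <- stats::setNames(rep(pops, each = reps), samples)
  ng <- nrow(genes)
  base_mu <- exp(stats::rnorm(ng, log(100), 1))
  markers <- truth[truth$type == "marker" & !is.na(truth$gene), , drop = FALSE]
  mi <- match(markers$gene, genes$gene_name)
  base_mu[mi] <- exp(stats::rnorm(nrow(markers), log(400), 0.4))
  eff <- matrix(0, ng, length(pops), dimnames = list(genes$gene_id, pops))
  planted_lfc <- stats::rnorm(nrow(markers), config$marker_slope *
                                markers$delta, config$marker_noise_sd)
  for (k in seq_len(nrow(markers)))
    eff[mi[k], markers$populations[k]] <- planted_lfc[k]
  counts <- matrix(0L, ng, length(samples),
                   dimnames = list(genes$gene_id, samples))
  size <- 1 / config$expression_dispersion
  for (s in seq_along(samples)) {
    mu <- base_mu * 2^eff[, groups[samples[s]]]
    counts[, s] <- stats::rnbinom(ng, mu = mu, size = size)
  }
  list(counts = counts, groups = groups,
       lengths = stats::setNames(genes$tx_length, genes$gene_id),
       marker_effects = data.frame(
         gene = markers$gene, population = markers$populations,
         delta = markers$delta, log2fc_planted = planted_lfc,
         stringsAsFactors = FALSE))
}

#' Plant motif occurrences inside one population's DMR blocks
#'
#' Writes the consensus (or its reverse complement, 50/50) into the
#' configured fraction of the motif population's planted blocks at a
#' random offset; blocks shorter than the consensus are skipped with a
#' warning.
#'
#' @param genome output of [simulate_genome()] (modified copy returned).
#' @param truth truth table.
#' @param config the [simulation_config()].
#' @return List with `sequences` (modified `DNAStringSet`) and `sites`
#'   (data.frame `chrom`, `start` (0-based), `strand`, `seq`).
#' @export
plant_motifs <- function(genome, truth, config) {
  set.seed(derive_seed(config$seed, 4))
  seqs <- genome$sequences
  cons <- toupper(config$motif_consensus)
  w <- nchar(cons)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  aff <- strsplit(truth$populations, ",")
  own <- vapply(aff, function(x)
    identical(x, config$motif_population), logical(1))
  spans <- truth[own & truth$type %in% c("marker", "exclusive"), ,
                 drop = FALSE]
  sites <- list()
  skipped <- 0L
  for (b in seq_len(nrow(spans))) {
    if (stats::runif(1) > config$motif_fraction) next
    width <- spans$end[b] - spans$start[b]
    if (width < w) { skipped <- skipped + 1L; next }
    # binding sites sit in the core of their demethylation footprint:
    # place the occurrence within the central <= 400 bp of the block
    core <- min(width, 400L)
    core_start <- spans$start[b] + (width - core) %/% 2L
    off <- sample.int(core - w + 1L, 1) - 1L
    start0 <- core_start + off
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    ins <- if (strand == "+") cons else rc
    Biostrings::subseq(seqs[[spans$chrom[b]]],
                       start = start0 + 1L, width = w) <-
      Biostrings::DNAString(ins)
    sites[[length(sites) + 1L]] <- data.frame(
      chrom = spans$chrom[b], start = start0, strand = strand, seq = ins,
      stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(sprintf("%d block(s) shorter than the motif skipped", skipped),
            call. = FALSE)
  list(sequences = seqs,
       sites = if (length(sites)) do.call(rbind, sites) else
         data.frame(chrom = character(), start = integer(),
                    strand = character(), seq = character(),
                    stringsAsFactors = FALSE))
}

#' Run the full synthetic-study generator
#'
#' @param config a [simulation_config()] (or a seed, for defaults).
#' @return List of class `SyntheticStudy`: `config`, `genome` (with
#'   motif-modified sequences), `matrix`, `truth`, `expression`,
#'   `motif_sites`.
#' @export
simulate_ilc_study <- function(config = simulation_config()) {
  if (is.numeric(config)) config <- simulation_config(seed = config)
  genome <- simulate_genome(config)
  meth <- simulate_methylomes(genome, config)
  expr <- simulate_expression(genome, meth$truth, config)
  pm <- plant_motifs(genome, meth$truth, config)
  genome$sequences <- pm$sequences
  structure(list(config = config, genome = genome, matrix = meth$matrix,
                 truth = meth$truth, expression = expr,
                 motif_sites = pm$sites),
            class = "SyntheticStudy")
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf(
    "SyntheticStudy: %d chromosomes, %d CpGs, %d populations, %d planted blocks\n",
    length(x$genome$sequences), nrow(x$genome$cpgs),
    length(x$matrix$samples), nrow(x$truth)))
  invisible(x)
}

#' Toy gene sets for enrichment testing
#'
#' Builds one gene set per planted-block class (the genes carrying blocks,
#' padded with random genes) plus purely random sets.
#'
#' @param genes gene models.
#' @param truth truth table.
#' @param n_random number of random sets.
#' @param set_size size of random sets.
#' @param seed integer seed.
#' @return Named list of gene-id vectors.
#' @export
make_toy_gene_sets <- function(genes, truth, n_random = 20L,
                               set_size = 30L, seed = 1L) {
  rng <- get_rng_state(); on.exit(restore_rng_state(rng), add = TRUE)
  set.seed(derive_seed(seed, 5))
  sets <- list()
  for (ty in unique(truth$type)) {
    gn <- unique(truth$gene[truth$type == ty & !is.na(truth$gene)])
    gid <- genes$gene_id[match(gn, genes$gene_name)]
    gid <- gid[!is.na(gid)]
    if (length(gid) >= 3)
      sets[[paste0("PLANTED_", toupper(ty))]] <-
        unique(c(gid, sample(genes$gene_id, 10)))
  }
  for (k in seq_len(n_random))
    sets[[sprintf("RANDOM_%02d", k)]] <-
      sample(genes$gene_id, min(set_size, nrow(genes)))
  sets
}

#' Write a gene-set list as a GMT file
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Toy PWM database containing the planted motif
#'
#' One strong PWM matching `consensus` plus random PWMs, in JASPAR-style
#' count-matrix form (use [write_pwm_database()] to serialize).
#'
#' @param consensus the planted consensus.
#' @param n_random number of random PWMs.
#' @param seed integer seed.
#' @return Named list of 4 x w probability matrices.
#' @export
make_toy_pwm_database <- function(consensus = "TGACTCAG", n_random = 19L,
                                  seed = 1L) {
  rng <- get_rng_state(); on.exit(restore_rng_state(rng), add = TRUE)
  set.seed(derive_seed(seed, 6))
  from_consensus <- function(cons, strong = 0.85) {
    b <- match(strsplit(cons, "")[[1]], .BASES)
    m <- matrix((1 - strong) / 3, 4, length(b))
    m[cbind(b, seq_along(b))] <- strong
    rownames(m) <- .BASES
    m
  }
  db <- list(PLANTED_TF = from_consensus(toupper(consensus)))
  for (k in seq_len(n_random)) {
    w <- sample(6:12, 1)
    cons <- paste(sample(.BASES, w, replace = TRUE), collapse = "")
    db[[sprintf("RANDOM_TF_%02d", k)]] <- from_consensus(cons, 0.7)
  }
  db
}

#' Write a PWM list as JASPAR-style count matrices
#' @param db named list of 4 x w probability matrices.
#' @param path output path.
#' @param n_obs pseudo observation count used to scale probabilities to
#'   integer counts.
#' @return Invisibly, `path`.
#' @export
write_pwm_database <- function(db, path, n_obs = 100L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(db)) {
    writeLines(paste0(">", nm), con)
    m <- round(db[[nm]] * n_obs)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", .BASES[b],
                         paste(m[b, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Write all generator outputs to a directory
#'
#' Emits `genome.fa`, `genes.gtf`, per-sample methylation tables under
#' `methylomes/`, truth BEDs per pairwise ILC comparison under `truth/`,
#' `counts.tsv`, `groups.tsv`, `gene_sets.gmt`, `pwm_db.txt`,
#' `motif_sites.tsv`.
#'
#' @param sim a [simulate_ilc_study()] result.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome$sequences,
                              file.path(dir, "genome.fa"))
  write_gtf(sim$genome$genes, file.path(dir, "genes.gtf"))
  write_methyl_matrix(sim$matrix, file.path(dir, "methylomes"))
  tdir <- file.path(dir, "truth")
  if (!dir.exists(tdir)) dir.create(tdir)
  utils::write.table(sim$truth, file.path(tdir, "blocks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pops <- sim$config$populations
  for (i in seq_len(length(pops) - 1)) for (j in seq.int(i + 1, length(pops))) {
    tp <- truth_for_pair(sim$truth, pops[i], pops[j])
    utils::write.table(
      tp[, c("chrom", "start", "end", "delta")],
      file.path(tdir, sprintf("%s_vs_%s.truth.bed", pops[i], pops[j])),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(data.frame(gene = rownames(sim$expression$counts),
                                sim$expression$counts,
                                check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(sim$expression$groups),
                                group = sim$expression$groups),
                     file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(make_toy_gene_sets(sim$genome$genes, sim$truth,
                               seed = sim$config$seed),
            file.path(dir, "gene_sets.gmt"))
  write_pwm_database(make_toy_pwm_database(sim$config$motif_consensus,
                                           seed = sim$config$seed),
                     file.path(dir, "pwm_db.txt"))
  utils::write.table(sim$motif_sites, file.path(dir, "motif_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
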