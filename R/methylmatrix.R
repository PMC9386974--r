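#' Per-CpG methylation matrix across samples
#'
#' A `MethylMatrix` holds the shared CpG catalog of a set of bisulfite
#' methylomes together with per-sample methylation levels (fractions in
#' \[0, 1\], `NA` where a CpG was not covered in a sample) and read
#' coverages.  CpGs are strand-merged and keyed by the plus-strand C
#' position (0-based), so one row represents one CpG motif.
#'
#' @param chrom character vector of chromosome names, one per CpG.
#' @param pos integer vector of 0-based CpG positions.
#' @param levels numeric matrix, CpGs x samples, entries in \[0, 1\] or `NA`.
#' @param coverage integer matrix, CpGs x samples, non-negative.
#' @param samples character vector of sample names (column order).
#'
#' @return An object of class `MethylMatrix`: a list with elements
#'   `chrom`, `pos`, `levels`, `coverage`, `samples`.
#' @export
methyl_matrix <- function(chrom, pos, levels, coverage, samples) {
  n <- length(pos)
  levels <- as.matrix(levels)
  coverage <- as.matrix(coverage)
  if (length(chrom) != n || nrow(levels) != n || nrow(coverage) != n)
    stop_mm("chrom, pos, levels and coverage must agree on the CpG count")
  if (!identical(dim(levels), dim(coverage)))
    stop_mm("levels and coverage must have identical shape")
  if (ncol(levels) != length(samples))
    stop_mm("number of samples does not match matrix columns")
  o <- cpg_order(chrom, pos)
  if (is.unsorted(o)) {
    chrom <- chrom[o]; pos <- pos[o]
    levels <- levels[o, , drop = FALSE]
    coverage <- coverage[o, , drop = FALSE]
  }
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    stop_mm("duplicate CpG positions in catalog")
  bad <- !is.na(levels) & (levels < 0 | levels > 1)
  if (any(bad)) stop_mm("methylation levels must lie in [0, 1]")
  # a missing level implies zero usable coverage
  coverage[is.na(levels)] <- 0L
  dimnames(levels) <- dimnames(coverage) <- list(NULL, samples)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         levels = levels, coverage = coverage,
         samples = as.character(samples)),
    class = "MethylMatrix")
}

#' @export
print.MethylMatrix <- function(x, ...) {
  cat(sprintf("MethylMatrix: %d CpGs x %d samples (%s)\n",
              length(x$pos), length(x$samples),
              paste(x$samples, collapse = ", ")))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$chrom), collapse = ", ")))
  cov <- x$coverage[x$coverage > 0]
  if (length(cov))
    cat(sprintf("  median covered depth: %d\n", as.integer(stats::median(cov))))
  invisible(x)
}

#' @export
dim.MethylMatrix <- function(x) c(length(x$pos), length(x$samples))

#' Read one per-sample CpG methylation table
#'
#' Reads a tab-separated bedGraph-dialect table with columns
#' `chrom, start, end, meth_fraction[, meth_count, total_count]` where
#' `end = start + 1`.  Rows are returned sorted by (chrom, pos); unsorted
#' input is sorted with a notice.
#'
#' @param path file path.
#' @param sample_name name recorded for this sample.
#' @param percent_scale if `TRUE`, the fraction column is on a 0--100 scale
#'   and is divided by 100 on read.
#'
#' @return data.frame with columns `chrom`, `pos`, `meth_level`,
#'   `meth_count`, `total_count` (counts `NA` when the file has no count
#'   columns) and attribute `sample_name`.
#' @export
read_methylation_table <- function(path, sample_name, percent_scale = FALSE) {
  if (!file.exists(path)) stop_mm("no such file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(nf) == 0)
    return(structure(
      data.frame(chrom = character(), pos = integer(),
                 meth_level = numeric(), meth_count = integer(),
                 total_count = integer()),
      sample_name = sample_name))
  bad <- which(!nf %in% c(4L, 6L))
  if (length(bad))
    stop_mm("%s: malformed line %d (expected 4 or 6 tab-separated fields, got %d)",
            path, bad[1], nf[bad[1]])
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#",
                           colClasses = c("character", rep("numeric", nf[1] - 1)))
  if (any(tab[[3]] != tab[[2]] + 1))
    stop_mm("%s: line %d: end must equal start + 1 for per-CpG records",
            path, which(tab[[3]] != tab[[2]] + 1)[1])
  frac <- tab[[4]]
  if (percent_scale) frac <- frac / 100
  if (any(frac < 0 | frac > 1)) {
    i <- which(frac < 0 | frac > 1)[1]
    stop_mm("%s: line %d: methylation fraction %g outside [0, 1]%s",
            path, i, tab[[4]][i],
            if (!percent_scale && max(tab[[4]]) > 1)
              " (0-100 input? use percent_scale = TRUE)" else "")
  }
  if (nf[1] == 6L) {
    mc <- as.integer(tab[[5]]); tc <- as.integer(tab[[6]])
    if (any(mc > tc)) stop_mm("%s: meth_count exceeds total_count", path)
    chk <- tc > 0 & abs(frac - mc / tc) > 1e-6
    if (any(chk))
      stop_mm("%s: line %d: fraction inconsistent with counts",
              path, which(chk)[1])
  } else {
    # counts unknown; coverage is recorded as unknown-positive
    mc <- rep(NA_integer_, nrow(tab)); tc <- rep(NA_integer_, nrow(tab))
  }
  out <- data.frame(chrom = tab[[1]], pos = as.integer(tab[[2]]),
                    meth_level = frac, meth_count = mc, total_count = tc,
                    stringsAsFactors = FALSE)
  o <- cpg_order(out$chrom, out$pos)
  if (is.unsorted(o)) {
    notice("%s: input not sorted by (chrom, pos); sorted on load", path)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "sample_name") <- sample_name
  out
}

#' Assemble per-sample CpG tables into a MethylMatrix
#'
#' The CpG catalog is the sorted union of all per-sample positions; samples
#' missing a CpG carry coverage 0 and a missing level there.
#'
#' @param per_sample named list of data.frames as returned by
#'   [read_methylation_table()]; names (or `sample_name` attributes) give
#'   the sample names.
#' @param unknown_coverage coverage recorded when a table lacks count
#'   columns (it is known only to be positive); default 1.
#'
#' @return A [methyl_matrix()].
#' @export
build_matrix <- function(per_sample, unknown_coverage = 1L) {
  if (length(per_sample) < 1) stop_mm("need at least one sample")
  nms <- names(per_sample)
  if (is.null(nms))
    nms <- vapply(per_sample, function(d) attr(d, "sample_name") %||% NA_character_, "")
  if (anyNA(nms) || anyDuplicated(nms))
    stop_mm("samples must carry unique names")
  keys <- lapply(per_sample, function(d) paste(d$chrom, d$pos))
  for (i in seq_along(per_sample))
    if (anyDuplicated(keys[[i]]))
      stop_mm("duplicate CpG within sample '%s'", nms[i])
  all_chrom <- unlist(lapply(per_sample, `[[`, "chrom"), use.names = FALSE)
  all_pos <- unlist(lapply(per_sample, `[[`, "pos"), use.names = FALSE)
  cat_key <- unique(paste(all_chrom, all_pos))
  first <- !duplicated(paste(all_chrom, all_pos))
  chrom <- all_chrom[first]; pos <- all_pos[first]
  o <- cpg_order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  cat_key <- paste(chrom, pos)
  n <- length(cat_key)
  levels <- matrix(NA_real_, n, length(per_sample))
  coverage <- matrix(0L, n, length(per_sample))
  for (i in seq_along(per_sample)) {
    d <- per_sample[[i]]
    idx <- match(keys[[i]], cat_key)
    levels[idx, i] <- d$meth_level
    cv <- d$total_count
    cv[is.na(cv)] <- as.integer(unknown_coverage)
    coverage[idx, i] <- cv
  }
  methyl_matrix(chrom, pos, levels, coverage, nms)
}

#' Apply the CpG coverage filter
#'
#' Retains exactly the CpGs with read coverage of at least `min_cov` in at
#' least `min_samples` samples (default: coverage >= 5 in >= 1 sample).
#' Row order is preserved; the result may be empty.
#'
#' @param matrix a [methyl_matrix()].
#' @param min_cov minimum per-sample coverage, >= 1.
#' @param min_samples minimum number of samples meeting `min_cov`.
#' @return The filtered `MethylMatrix`.
#' @export
filter_by_coverage <- function(matrix, min_cov = 5L, min_samples = 1L) {
  stopifnot(inherits(matrix, "MethylMatrix"))
  if (min_cov < 1) stop_mm("min_cov must be >= 1")
  if (min_samples < 1 || min_samples > length(matrix$samples))
    stop_mm("min_samples must be between 1 and the number of samples")
  keep <- rowSums(matrix$coverage >= min_cov) >= min_samples
  subset_matrix(matrix, keep)
}

subset_matrix <- function(matrix, idx) {
  methyl_matrix(matrix$chrom[idx], matrix$pos[idx],
                matrix$levels[idx, , drop = FALSE],
                matrix$coverage[idx, , drop = FALSE],
                matrix$samples)
}

#' Write a MethylMatrix back to per-sample bedGraph-dialect tables
#'
#' One 6-column table per sample (chrom, start, end, fraction, meth_count,
#' total_count); CpGs missing in a sample are omitted from its file.
#' Fractions are printed with 6 decimals.  The methylated read count is
#' reconstructed as `round(level * coverage)`.
#'
#' @param matrix a [methyl_matrix()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_methyl_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "MethylMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in matrix$samples) {
    lv <- matrix$levels[, s]
    keep <- !is.na(lv)
    cv <- matrix$coverage[keep, s]
    df <- data.frame(matrix$chrom[keep], matrix$pos[keep],
                     matrix$pos[keep] + 1L, sprintf("%.6f", lv[keep]),
                     as.integer(round(lv[keep] * cv)), cv)
    p <- file.path(dir, paste0(s, ".meth.tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[s] <- p
  }
  invisible(paths)
}

#' Read per-sample tables from a directory written by [write_methyl_matrix()]
#' @param dir directory containing `<sample>.meth.tsv` files.
#' @param min_cov,min_samples optional coverage filter applied after
#'   assembly; `NULL` skips filtering.
#' @return A [methyl_matrix()].
#' @export
read_methyl_dir <- function(dir, min_cov = NULL, min_samples = 1L) {
  files <- list.files(dir, pattern = "\\.meth\\.tsv$", full.names = TRUE)
  if (!length(files)) stop_mm("no .meth.tsv files under %s", dir)
  samples <- sub("\\.meth\\.tsv$", "", basename(files))
  tabs <- mapply(read_methylation_table, files, samples, SIMPLIFY = FALSE)
  names(tabs) <- samples
  m <- build_matrix(tabs)
  if (!is.null(min_cov)) m <- filter_by_coverage(m, min_cov, min_samples)
  m
}
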