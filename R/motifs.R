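## De novo motif discovery inside DMR sequences: an expectation-maximization
## mixture finder in the "any number of repetitions" spirit (zero or more
## sites per sequence, site prior estimated by EM), run on both strands,
## with an empirical shuffle-based E-value.

#' Extract DMR sequences with flanks from a genome
#'
#' Each DMR span is extended by `flank` nucleotides on both ends (clipped
#' at chromosome edges with a warning) and extracted as an uppercase
#' sequence; Ns are preserved.
#'
#' @param dmrs data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genome a `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param flank extension in nt on each side.
#' @return `DNAStringSet` named `chrom:start-end`.
#' @export
extract_dmr_sequences <- function(dmrs, genome, flank = 10L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  miss <- setdiff(unique(dmrs$chrom), names(genome))
  if (length(miss)) stop_mm("chromosome(s) absent from FASTA: %s",
                            paste(miss, collapse = ", "))
  chrlen <- Biostrings::width(genome)[match(dmrs$chrom, names(genome))]
  s <- dmrs$start - flank
  e <- dmrs$end + flank
  clipped <- s < 0 | e > chrlen
  if (any(clipped))
    warning(sprintf("%d DMR(s) clipped at chromosome edges", sum(clipped)),
            call. = FALSE)
  s <- pmax(s, 0L); e <- pmin(e, chrlen)
  out <- Biostrings::DNAStringSet(toupper(as.character(
    Biostrings::subseq(genome[dmrs$chrom], start = s + 1L, end = e))))
  names(out) <- paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end)
  out
}

# --- sequence encoding ----------------------------------------------------

.BASE_CODE <- {
  v <- rep(NA_integer_, 127)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
  v
}
.BASES <- c("A", "C", "G", "T")

encode_seqs <- function(seqs) {
  ch <- toupper(as.character(seqs))
  lapply(ch, function(s) .BASE_CODE[utf8ToInt(s)])
}

# all strand-aware windows of width w: list(X = n x w code matrix,
# seq = seq index, start = 1-based forward-strand start, strand = +/-)
window_table <- function(codes, w, both_strands = TRUE) {
  Xs <- list(); seqi <- list(); starts <- list(); strands <- list()
  for (i in seq_along(codes)) {
    x <- codes[[i]]
    L <- length(x)
    if (L < w) next
    E <- embed(x, w)[, w:1, drop = FALSE]
    ok <- rowSums(is.na(E)) == 0L
    if (any(ok)) {
      Xs[[length(Xs) + 1L]] <- E[ok, , drop = FALSE]
      seqi[[length(Xs)]] <- rep(i, sum(ok))
      starts[[length(Xs)]] <- which(ok)
      strands[[length(Xs)]] <- rep("+", sum(ok))
    }
    if (both_strands) {
      rc <- rev(5L - x)
      E2 <- embed(rc, w)[, w:1, drop = FALSE]
      ok2 <- rowSums(is.na(E2)) == 0L
      if (any(ok2)) {
        Xs[[length(Xs) + 1L]] <- E2[ok2, , drop = FALSE]
        seqi[[length(Xs)]] <- rep(i, sum(ok2))
        # forward-strand start of the reverse-complement window
        starts[[length(Xs)]] <- L - w + 2L - which(ok2)
        strands[[length(Xs)]] <- rep("-", sum(ok2))
      }
    }
  }
  if (!length(Xs))
    return(list(X = matrix(integer(0), 0, w), seq = integer(0),
                start = integer(0), strand = character(0)))
  list(X = do.call(rbind, Xs), seq = unlist(seqi),
       start = unlist(starts), strand = unlist(strands))
}

# strand-symmetric 0th-order background from input composition
background_freqs <- function(codes) {
  tab <- tabulate(unlist(codes), nbins = 4)
  f <- (tab + rev(tab)) / (2 * max(sum(tab), 1))
  f[f == 0] <- 1e-6
  f / sum(f)
}

# most frequent w-mers as EM seeds (radix-encoded for speed)
seed_kmers <- function(wt, n_seeds = 3L) {
  if (!nrow(wt$X)) return(integer(0))
  key <- as.vector((wt$X - 1L) %*% 4^(seq_len(ncol(wt$X)) - 1L))
  tab <- sort(table(key), decreasing = TRUE)
  utils::head(match(as.numeric(names(tab)), key), n_seeds)
}

# one EM fit at fixed width; returns pwm, lambda, llr, z, ll trace.
# Inner loop avoids per-iteration matrix allocation: scores accumulate by
# column indexing into the flattened log-PWM, counts via rowsum().
em_fit <- function(wt, bg, seed_row, max_iter = 40L, tol = 1e-4,
                   pseudo = 0.1) {
  X <- wt$X
  n <- nrow(X); w <- ncol(X)
  pwm <- matrix(0.1 / 3, 4, w)
  pwm[cbind(X[seed_row, ], seq_len(w))] <- 0.9
  lambda <- min(0.3, length(unique(wt$seq)) / n)
  lbg <- rep(0, n)
  lb <- log(bg)
  colidx <- lapply(seq_len(w), function(j) X[, j] + 4L * (j - 1L))
  # per-column, per-base window index lists (X never changes)
  base_idx <- lapply(seq_len(w), function(j)
    lapply(1:4, function(b) which(X[, j] == b)))
  for (j in seq_len(w)) lbg <- lbg + lb[X[, j]]
  ll_trace <- numeric(0)
  z <- numeric(n)
  ps <- pseudo * bg * 4
  for (it in seq_len(max_iter)) {
    lp <- log(pwm)
    sc <- rep(0, n)
    for (j in seq_len(w)) sc <- sc + lp[colidx[[j]]]
    r <- exp(sc - lbg)
    denom <- lambda * r + (1 - lambda)
    z <- lambda * r / denom
    ll <- sum(log(denom))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_trace[it - 1] < tol) break
    for (j in seq_len(w)) {
      cnt <- ps + vapply(base_idx[[j]], function(ix) sum(z[ix]), numeric(1))
      pwm[, j] <- cnt / sum(cnt)
    }
    lambda <- min(max(mean(z), 1e-6), 0.5)
  }
  list(pwm = pwm, lambda = lambda, llr = ll_trace[length(ll_trace)],
       z = z, ll_trace = ll_trace)
}

# best EM fit at one width: tries k-mer seeds, keeps the highest LLR
fit_width <- function(wt, bg, max_iter = 40L, n_seeds = 2L) {
  seeds <- seed_kmers(wt, n_seeds)
  best <- NULL
  for (s in seeds) {
    f <- em_fit(wt, bg, s, max_iter = max_iter)
    if (is.null(best) || f$llr > best$llr) best <- f
  }
  best
}

#' Consensus string of a PWM
#' @param pwm 4 x w probability matrix (rows A, C, G, T).
#' @return Character consensus (per-column argmax).
#' @export
pwm_consensus <- function(pwm) paste(.BASES[apply(pwm, 2, which.max)],
                                     collapse = "")

#' Reverse complement of a PWM
#' @param pwm 4 x w probability matrix.
#' @return The reverse-complemented matrix.
#' @export
pwm_reverse_complement <- function(pwm) pwm[4:1, rev(seq_len(ncol(pwm))),
                                            drop = FALSE]

#' Discover overrepresented motifs by expectation maximization
#'
#' Fits a two-component mixture (motif sites vs 0th-order background) over
#' all windows of each candidate width on both strands, any number of
#' sites per sequence.  For each reported motif the width with the highest
#' z-score against a shuffle null is kept, its sites are masked, and the
#' search repeats.  Significance is an empirical E-value: the fitted
#' log-likelihood ratio is ranked against a null distribution obtained by
#' refitting on `n_shuffles` within-sequence letter shuffles at every
#' width (null statistic = the maximum z-score across widths, which
#' accounts for the width search), then multiplied by the number of widths
#' tested.  Fixed seeds give bitwise-reproducible output.
#'
#' @param seqs `DNAStringSet` or character vector (>= 10 sequences).
#' @param widths integer vector of candidate motif widths.
#' @param n_motifs maximum number of motifs to report.
#' @param both_strands search the reverse complement too.
#' @param seed integer seed for the shuffle null.
#' @param n_shuffles shuffles per width for the empirical null.
#' @param max_iter EM iteration cap.
#' @param stop_at_e stop searching once a motif's E-value reaches this
#'   (that motif is still reported); `NULL` searches all `n_motifs`.
#' @return List of class `MotifResultList`; each element has `pwm`,
#'   `width`, `consensus`, `n_sites`, `llr`, `z`, `evalue`, `lambda`,
#'   `sites` (data.frame `seq`, `start`, `strand`), `ll_trace`.
#' @export
discover_motifs <- function(seqs, widths = 6:12, n_motifs = 20L,
                            both_strands = TRUE, seed = 1L,
                            n_shuffles = 99L, max_iter = 40L,
                            stop_at_e = 0.05) {
  codes <- encode_seqs(seqs)
  if (length(codes) < 10) stop_mm("need at least 10 sequences")
  if (all(vapply(codes, function(x) all(is.na(x)), logical(1))))
    stop_mm("all-N input")
  if (max(lengths(codes)) < max(widths))
    stop_mm("sequences shorter than the largest motif width")
  widths <- widths[widths <= max(lengths(codes))]
  bg <- background_freqs(codes)

  # null LLR distribution per width from within-sequence letter shuffles
  rng <- get_rng_state()
  on.exit(restore_rng_state(rng), add = TRUE)
  set.seed(derive_seed(seed, 7))
  null_llr <- matrix(NA_real_, n_shuffles, length(widths))
  for (m in seq_len(n_shuffles)) {
    shuf <- lapply(codes, function(x) sample(x))
    for (wi in seq_along(widths)) {
      swt <- window_table(shuf, widths[wi], both_strands)
      if (!nrow(swt$X)) next
      null_llr[m, wi] <- fit_width(swt, bg, max_iter = max_iter)$llr
    }
  }
  null_mean <- colMeans(null_llr, na.rm = TRUE)
  null_sd <- pmax(apply(null_llr, 2, stats::sd, na.rm = TRUE), 1e-9)
  null_z <- sweep(sweep(null_llr, 2, null_mean), 2, null_sd, "/")
  null_max_z <- apply(null_z, 1, max, na.rm = TRUE)

  masked <- lapply(codes, function(x) rep(FALSE, length(x)))
  results <- list()
  for (k in seq_len(n_motifs)) {
    cur <- mapply(function(x, m) { x[m] <- NA_integer_; x },
                  codes, masked, SIMPLIFY = FALSE)
    fits <- vector("list", length(widths))
    zs <- rep(-Inf, length(widths))
    for (wi in seq_along(widths)) {
      wt <- window_table(cur, widths[wi], both_strands)
      if (nrow(wt$X) < 10 * widths[wi]) next
      f <- fit_width(wt, bg, max_iter = max_iter)
      f$wt <- wt
      fits[[wi]] <- f
      zs[wi] <- (f$llr - null_mean[wi]) / null_sd[wi]
    }
    if (all(!is.finite(zs))) break
    wi <- which.max(zs)
    f <- fits[[wi]]
    p_emp <- (1 + sum(null_max_z >= zs[wi])) / (n_shuffles + 1)
    evalue <- p_emp * length(widths)
    site_sel <- f$z > 0.5
    sites <- data.frame(seq = f$wt$seq[site_sel],
                        start = f$wt$start[site_sel],
                        strand = f$wt$strand[site_sel],
                        stringsAsFactors = FALSE)
    results[[k]] <- list(pwm = f$pwm, width = widths[wi],
                         consensus = pwm_consensus(f$pwm),
                         n_sites = nrow(sites), llr = f$llr, z = zs[wi],
                         evalue = evalue, lambda = f$lambda,
                         sites = sites, ll_trace = f$ll_trace)
    if (!is.null(stop_at_e) && evalue >= stop_at_e) break
    if (!nrow(sites)) break
    for (i in seq_len(nrow(sites))) {
      s <- sites$start[i]
      span <- s:(s + widths[wi] - 1L)
      span <- span[span >= 1 & span <= length(masked[[sites$seq[i]]])]
      masked[[sites$seq[i]]][span] <- TRUE
    }
  }
  structure(results, class = "MotifResultList")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' @export
print.MotifResultList <- function(x, ...) {
  cat(sprintf("%d discovered motif(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  %2d. %-14s w=%-2d sites=%-4d E=%.3g\n", i,
                x[[i]]$consensus, x[[i]]$width, x[[i]]$n_sites,
                x[[i]]$evalue))
  invisible(x)
}

#' Drop low-complexity and non-significant motifs
#'
#' Removes motifs whose consensus is dominated by one base (> 70% of
#' columns, the poly(A/T) class) or by a dinucleotide repeat (period-2
#' pattern over > 80% of columns), then drops motifs with E-value >=
#' `max_e`.
#'
#' @param results `MotifResultList` from [discover_motifs()].
#' @param max_e E-value cutoff (exclusive).
#' @return Filtered `MotifResultList`.
#' @export
filter_low_complexity <- function(results, max_e = 0.05) {
  keep <- vapply(results, function(r) {
    cons <- strsplit(r$consensus, "")[[1]]
    w <- length(cons)
    mono <- max(table(cons)) / w
    if (mono > 0.7) return(FALSE)
    if (w > 2) {
      per2 <- mean(cons[-(1:2)] == cons[seq_len(w - 2)])
      if (per2 > 0.8) return(FALSE)
    }
    r$evalue < max_e
  }, logical(1))
  structure(results[keep], class = "MotifResultList")
}

#' Match a discovered PWM against a database of known motifs
#'
#' Every database PWM is compared at all ungapped offsets (overlap of at
#' least `min_overlap` columns) in both orientations; an alignment is
#' scored by the sum of Pearson correlations of aligned probability
#' columns, so longer consistent alignments outrank short coincidental
#' ones (a self-match scores its own width).
#' An empirical p-value ranks the best score against scores obtained from
#' column-order shuffles of the query (seeded).
#'
#' @param query 4 x w probability matrix.
#' @param database named list of PWMs (see [read_pwm_database()]).
#' @param min_overlap minimum aligned columns.
#' @param n_shuffles query-column shuffles for the null.
#' @param seed integer seed.
#' @return data.frame `target`, `score`, `orientation`, `offset`, `p`,
#'   ranked by score descending.
#' @export
match_pwm <- function(query, database, min_overlap = 4L,
                      n_shuffles = 100L, seed = 1L) {
  if (!length(database)) stop_mm("empty PWM database")
  best <- lapply(database, best_alignment, query = query,
                 min_overlap = min_overlap)
  rng <- get_rng_state()
  on.exit(restore_rng_state(rng), add = TRUE)
  set.seed(derive_seed(seed, 13))
  null_scores <- matrix(NA_real_, n_shuffles, length(database))
  for (m in seq_len(n_shuffles)) {
    q <- query[, sample(ncol(query)), drop = FALSE]
    null_scores[m, ] <- vapply(database, function(t)
      best_alignment(t, q, min_overlap)$score, numeric(1))
  }
  out <- data.frame(
    target = names(database),
    score = vapply(best, `[[`, numeric(1), "score"),
    orientation = vapply(best, `[[`, character(1), "orientation"),
    offset = vapply(best, `[[`, numeric(1), "offset"),
    p = vapply(seq_along(best), function(i)
      (1 + sum(null_scores[, i] >= best[[i]]$score)) / (n_shuffles + 1),
      numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$target, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

best_alignment <- function(target, query, min_overlap = 4L) {
  score_or <- function(tg, orient) {
    wq <- ncol(query); wt <- ncol(tg)
    best <- -Inf; best_off <- 0L
    for (off in seq.int(-(wq - min_overlap), wt - min_overlap)) {
      qcols <- max(1, 1 - off):min(wq, wt - off)
      tcols <- qcols + off
      sc <- sum(vapply(seq_along(qcols), function(j) {
        r <- suppressWarnings(stats::cor(query[, qcols[j]], tg[, tcols[j]]))
        if (is.na(r)) 0 else r
      }, numeric(1)))
      if (sc > best) { best <- sc; best_off <- off }
    }
    list(score = best, offset = best_off, orientation = orient)
  }
  f <- score_or(target, "+")
  r <- score_or(pwm_reverse_complement(target), "-")
  if (r$score > f$score) r else f
}

#' Read a JASPAR/HOCOMOCO-style text PWM database
#'
#' Records start with `>id [name]` followed by four rows (A, C, G, T),
#' either labelled (`A [ 1 2 3 ]`) or bare numbers.  Count matrices are
#' converted to probabilities with a 0.25 pseudocount per cell.
#'
#' @param path text file.
#' @return Named list of 4 x w probability matrices.
#' @export
read_pwm_database <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  starts <- grep("^>", lines)
  if (!length(starts)) stop_mm("no PWM records in %s", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(body[seq_len(min(4, length(body)))], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      as.numeric(strsplit(gsub("[][]", " ", l), "\\s+")[[1]] |>
                   (\(v) v[v != ""])())
    })
    if (length(rows) < 4 || length(unique(lengths(rows))) != 1)
      stop_mm("malformed PWM record '%s'", id)
    m <- do.call(rbind, rows)
    m <- m + 0.25
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- .BASES
    out[[id]] <- m
  }
  out
}

#' Write discovered motifs in MEME minimal text format
#'
#' @param results `MotifResultList`.
#' @param path output file.
#' @param bg background frequencies (A, C, G, T).
#' @return Invisibly, `path`.
#' @export
write_meme_motifs <- function(results, path, bg = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (i in seq_along(results)) {
    r <- results[[i]]
    writeLines(sprintf("MOTIF m%d %s", i, r$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
      r$width, r$n_sites, r$evalue), con)
    for (j in seq_len(r$width))
      writeLines(paste(sprintf("%.6f", r$pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
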