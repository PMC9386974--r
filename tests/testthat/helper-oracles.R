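# Independent naive implementation of the segmentation definition, used as
# the oracle: exhaustive window scan with per-window sums computed by
# sum(), the same boundary/mean/tie rules, per-CpG extension, recursion
# into the flanks, and the same-sign merge pass.
oracle_segment <- function(d, min_cpgs = 3L, min_diff = 0.25) {
  d <- round(d, 4)
  tol <- 1e-10
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < min_cpgs) return(list())
    best <- NULL
    for (L in min_cpgs:n) {
      for (i in lo:(hi - L + 1L)) {
        j <- i + L - 1L
        s <- sum(d[i:j])
        if (abs(d[i]) < min_diff - tol || abs(d[j]) < min_diff - tol) next
        if (sign(d[i]) != sign(d[j]) || sign(s) != sign(d[i])) next
        if (abs(s) < min_diff * L - tol) next
        if (is.null(best) || abs(s) * best$L > best$abs * L + tol ||
            (abs(abs(s) * best$L - best$abs * L) <= tol && L > best$L)) {
          best <- list(abs = abs(s), L = L, i = i)
        }
      }
    }
    if (is.null(best)) return(list())
    i1 <- best$i; i2 <- best$i + best$L - 1L
    sgn <- sign(sum(d[i1:i2]))
    while (i1 > lo && sign(d[i1 - 1]) == sgn &&
           abs(d[i1 - 1]) >= min_diff - tol) i1 <- i1 - 1L
    while (i2 < hi && sign(d[i2 + 1]) == sgn &&
           abs(d[i2 + 1]) >= min_diff - tol) i2 <- i2 + 1L
    c(recurse(lo, i1 - 1L), list(c(i1, i2)), recurse(i2 + 1L, hi))
  }
  segs <- recurse(1L, length(d))
  if (length(segs) < 2) return(segs)
  segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
  repeat {
    done <- TRUE
    k <- 1L
    while (k < length(segs)) {
      i1 <- segs[[k]][1]; i2 <- segs[[k + 1]][2]
      s <- sum(d[i1:i2])
      if (sign(sum(d[segs[[k]][1]:segs[[k]][2]])) ==
          sign(sum(d[segs[[k + 1]][1]:segs[[k + 1]][2]])) &&
          abs(s) >= min_diff * (i2 - i1 + 1L) - tol) {
        segs[[k]] <- c(i1, i2); segs[[k + 1]] <- NULL; done <- FALSE
      } else k <- k + 1L
    }
    if (done) break
  }
  segs
}


# minimal Hamming distance between the consensus and the planted word (or
# its reverse complement) over all full-overlap ungapped alignments, so a
# consensus one column wider/narrower than the plant is compared fairly
aligned_hamming <- function(consensus, word) {
  best <- Inf
  for (target in unique(c(word, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(word)))))) {
    a <- strsplit(consensus, "")[[1]]; b <- strsplit(target, "")[[1]]
    if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
    for (off in 0:(length(a) - length(b)))
      best <- min(best, sum(a[off + seq_along(b)] != b))
  }
  best
}
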