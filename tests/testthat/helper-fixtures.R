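# Shared fixtures built in code.  The default synthetic study is expensive
# (~5 s), so it is generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small shared study for stages that need realistic structure but not the
# full default scale
small_study <- function() cached("small_study", function() {
  simulate_ilc_study(simulation_config(
    seed = 42, n_chromosomes = 1L, chrom_length = 2e6,
    exclusive_blocks_per_pop = 8L, n_marker_genes = 5L,
    shared_blocks = 5L, group_blocks = 8L))
})

small_tables <- function() cached("small_tables", function() {
  st <- small_study()
  m <- filter_by_coverage(st$matrix)
  pairwise_dmr_tables(m, samples = st$config$populations)
})

# a tiny deterministic matrix with two samples and hand-set levels
toy_matrix <- function() {
  pos <- as.integer(seq(100, by = 100, length.out = 10))
  lv <- cbind(A = c(.9, .9, .8, .2, .1, .2, .9, .8, NA, .5),
              B = c(.9, .8, .8, .9, .9, .8, .9, .8, .7, NA))
  cv <- matrix(10L, 10, 2)
  cv[9, 1] <- 0L; cv[10, 2] <- 0L
  methyl_matrix(rep("chr1", 10), pos, lv, cv, c("A", "B"))
}

# toy gene models: two genes on chr1 (one per strand) in internal 0-based
# half-open coordinates
toy_genes <- function() {
  g <- data.frame(
    gene_id = c("G1", "G2"),
    gene_name = c("Alpha", "Beta"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(1000L, 10000L),
    end = c(5000L, 14000L),
    tss = c(1000L, 13999L),
    tx_length = c(3000L, 3000L),
    stringsAsFactors = FALSE)
  attr(g, "exons") <- data.frame(gene_id = c("G1", "G2"),
                                 start = c(1000L, 10000L),
                                 end = c(5000L, 14000L))
  g
}

# random gene models on one chromosome for oracle comparisons
random_genes <- function(n, chrom_len = 1e6) {
  start <- sort(sample.int(chrom_len - 20000L, n))
  len <- sample(1000:10000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  g <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n)),
    gene_name = sprintf("Gene%03d", seq_len(n)),
    chrom = "chr1", strand = strand,
    start = start, end = start + len,
    tss = ifelse(strand == "+", start, start + len - 1L),
    tx_length = len, stringsAsFactors = FALSE)
  g
}

write_meth_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
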