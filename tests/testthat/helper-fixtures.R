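# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# Small two-chromosome genome with mixed strands; written to a temp dir.
shared_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "spliceworks-fixture")
    .fixture_cache$fx <- generate_genome(
      fixture_spec(seed = 101, n_chromosomes = 2, n_genes = 8,
                   exon_count = c(2, 4), exon_len = c(120, 300),
                   intron_len = c(90, 200), minus_fraction = 0.5),
      dir = dir)
  }
  .fixture_cache$fx
}

shared_mock <- function() {
  if (is.null(.fixture_cache$mock)) {
    .fixture_cache$mock <- make_mock_scorer()
  }
  .fixture_cache$mock
}

# A minimal GFF with one protein-coding and one lncRNA gene.
write_two_biotype_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t700\t.\t+\t.\tID=gA;gene_biotype=protein_coding",
    "chr1\ttest\tmRNA\t101\t700\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\ttest\texon\t101\t300\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "chr1\ttest\texon\t501\t700\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
    "chr1\ttest\tgene\t1001\t1400\t.\t+\t.\tID=gB;gene_biotype=lncRNA",
    "chr1\ttest\tmRNA\t1001\t1400\t.\t+\t.\tID=gB.t1;Parent=gB",
    "chr1\ttest\texon\t1001\t1400\t.\t+\t.\tID=gB.e1;Parent=gB.t1"),
    path)
  path
}

# Random one-hot sequence matrix of length n (no Ns).
random_onehot <- function(n, seed = 1) {
  with_seed_local(seed, {
    m <- matrix(0, n, 4)
    m[cbind(seq_len(n), sample.int(4, n, replace = TRUE))] <- 1
    m
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

random_dna_str <- function(n, seed = 1) {
  with_seed_local(seed, paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = ""))
}
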