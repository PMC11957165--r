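test_that("annotation parsing honours the biotype filter", {
  gff <- write_two_biotype_gff(withr::local_tempfile(fileext = ".gff3"))
  pc <- parse_annotation(gff, biotype_filter = "protein-coding")
  expect_length(pc, 1)
  expect_equal(pc[[1]]$id, "gA")
  expect_equal(pc[[1]]$start, 101)
  expect_equal(pc[[1]]$end, 700)

  all_loci <- parse_annotation(gff, biotype_filter = "all")
  expect_length(all_loci, 2)

  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_length(parse_annotation(empty, "all"), 0)
})

test_that("orphan exons are dropped with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
    "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e1;Parent=g1.t1",
    "chr1\tt\texon\t10\t50\t.\t+\t.\tID=e2;Parent=missing.tx"), gff)
  expect_warning(loci <- parse_annotation(gff, "all"), "without a resolvable")
  expect_length(loci[[1]]$transcripts[[1]]$exons[, 1], 1)
})

test_that("pseudogene loci are removed by biotype or feature type", {
  mk <- function(id, biotype, ft = "gene") {
    spliceworks:::new_gene_locus(id, "chr1", "+", 1, 100, biotype, ft)
  }
  loci <- list(mk("a", "processed_pseudogene"),
               mk("b", "protein_coding"),
               mk("c", "protein_coding", ft = "pseudogene"),
               mk("d", NA_character_),
               mk("e", "transcribed_pseudogene"),
               mk("f", "pseudogene"))
  kept <- filter_pseudogenes(loci)
  expect_equal(vapply(kept, `[[`, character(1), "id"), c("b", "d"))
})

test_that("canonical transcript is the longest, ties broken by id", {
  mk_tx <- function(id, start, end) list(id = id, exons = cbind(start = start,
                                                                end = end))
  locus <- spliceworks:::new_gene_locus(
    "g", "chr1", "+", 1, 5000, "protein_coding",
    transcripts = list(mk_tx("T1", 1, 1000), mk_tx("T2", 1, 2500)))
  expect_equal(select_canonical(locus)$id, "T2")

  tie <- spliceworks:::new_gene_locus(
    "g", "chr1", "+", 1, 5000, "protein_coding",
    transcripts = list(mk_tx("T2", 1, 1000), mk_tx("T1", 101, 1100)))
  expect_equal(select_canonical(tie)$id, "T1")

  single <- spliceworks:::new_gene_locus(
    "g", "chr1", "+", 1, 5000, "protein_coding",
    transcripts = list(mk_tx("only", 1, 1000)))
  expect_equal(select_canonical(single)$id, "only")

  none <- spliceworks:::new_gene_locus("g", "chr1", "+", 1, 100,
                                       "protein_coding")
  expect_warning(res <- select_canonical(none), "no transcripts")
  expect_null(res)
})

test_that("one-hot encoding maps bases to unit vectors and others to zero", {
  expect_equal(unname(encode_sequence("A")), matrix(c(1, 0, 0, 0), 1))
  expect_equal(unname(encode_sequence("N")), matrix(c(0, 0, 0, 0), 1))
  m <- encode_sequence("ACGTN")
  expect_equal(unname(m), rbind(diag(4), 0))
  # U treated as T; lowercase uppercased
  expect_equal(unname(encode_sequence("u")), matrix(c(0, 0, 0, 1), 1))
  expect_equal(encode_sequence("acgt"), encode_sequence("ACGT"))
})

test_that("splice-site labels land on exon boundary bases", {
  # exon1 1-10, intron GT..AG 11-20, exon2 21-30
  seq <- paste0("AAAAAAAAAA", "GTCCCCCCAG", "GAAAAAAAAA")
  exons <- cbind(start = c(1L, 21L), end = c(10L, 30L))
  lab <- label_splice_sites(exons, seq)
  expect_equal(which(lab == 2L), 10L) # donor at last exonic base
  expect_equal(which(lab == 1L), 21L) # acceptor at first exonic base
  expect_equal(sum(lab != 0), 2)

  # single exon: all none
  expect_equal(label_splice_sites(cbind(start = 1L, end = 30L), seq),
               integer(30))

  # canonical_only: CT..AC motif skipped, GC..AG labeled
  seq_ct <- paste0("AAAAAAAAAA", "CTCCCCCCAC", "GAAAAAAAAA")
  expect_equal(sum(label_splice_sites(exons, seq_ct,
                                      canonical_only = TRUE)), 0)
  seq_gc <- paste0("AAAAAAAAAA", "GCCCCCCCAG", "GAAAAAAAAA")
  expect_equal(sum(label_splice_sites(exons, seq_gc,
                                      canonical_only = TRUE) != 0), 2)
  # same motifs labeled when canonical_only is off
  expect_equal(sum(label_splice_sites(exons, seq_ct) != 0), 2)

  expect_error(label_splice_sites(cbind(start = 1L, end = 40L), seq),
               "bounds")
})

test_that("segmentation follows the ceil(L/5000) law with padded tails", {
  L <- 22000L
  ex <- segment_gene(random_onehot(L), integer(L))
  expect_equal(dim(ex$X), c(5, 15000, 4))
  expect_equal(dim(ex$Y), c(5, 5000, 3))
  # final segment holds 2000 real nt in its core
  expect_equal(sum(rowSums(ex$Y[5, , ])), 2000)
  expect_equal(sum(ex$Y[5, 2001:5000, ]), 0)

  expect_equal(dim(segment_gene(random_onehot(5000), integer(5000))$X)[1], 1)
  ex2 <- segment_gene(random_onehot(5001), integer(5001))
  expect_equal(dim(ex2$X)[1], 2)
  expect_equal(sum(rowSums(ex2$Y[2, , ])), 1)

  expect_error(segment_gene(matrix(0, 0, 4), integer(0)), "zero-length")
})

test_that("segment cores concatenate back to the full label track", {
  for (L in c(1L, 4999L, 5000L, 5001L, 12345L)) {
    lab <- integer(L)
    set.seed(L)
    lab[sample(L, min(L, 7L))] <- sample(1:2, min(L, 7L), replace = TRUE)
    ex <- segment_gene(random_onehot(L, seed = L), lab)
    expect_equal(dim(ex$X)[1], ceiling(L / 5000))
    flat <- do.call(rbind, lapply(seq_len(dim(ex$Y)[1]),
                                  function(s) ex$Y[s, , ]))
    expect_equal(sum(rowSums(flat)), L) # non-pad core positions == L
    rec <- spliceworks:::onehot_to_labels(flat[seq_len(L), , drop = FALSE])
    expect_equal(rec, lab)
  }
})

test_that("chromosome splitting follows the fixed human and random rules", {
  mk <- function(id, chrom) spliceworks:::new_gene_locus(
    id, chrom, "+", 1, 10, "protein_coding")
  loci <- list(mk("a", "chr1"), mk("b", "chr2"))
  sp <- split_dataset(loci, split_spec("human"))
  expect_equal(vapply(sp$test, `[[`, character(1), "id"), "a")
  expect_equal(vapply(sp$train, `[[`, character(1), "id"), "b")

  # one chromosome: everything trains
  one <- split_dataset(list(mk("a", "c1")), split_spec("random", 0.8, 1),
                       chrom_lengths = c(c1 = 100))
  expect_length(one$train, 1)
  expect_length(one$test, 0)

  # 10 equal chromosomes at ratio 0.8: greedy accumulation gives 8/2
  chroms <- paste0("c", 1:10)
  loci10 <- lapply(chroms, function(ch) mk(ch, ch))
  lens <- stats::setNames(rep(100, 10), chroms)
  sp10 <- split_dataset(loci10, split_spec("random", 0.8, 7),
                        chrom_lengths = lens)
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)

  # determinism
  sp10b <- split_dataset(loci10, split_spec("random", 0.8, 7),
                         chrom_lengths = lens)
  expect_identical(sp10$assignment, sp10b$assignment)

  expect_warning(split_dataset(list(mk("a", "chrUn")), split_spec("human")),
                 "excluded")
})

test_that("paralog removal applies strict identity and coverage thresholds", {
  train <- c(t1 = random_dna_str(800, seed = 5))
  identical_seq <- train[["t1"]]
  unrelated <- random_dna_str(1000, seed = 6)
  mk <- function(id) spliceworks:::new_gene_locus(
    id, "chr1", "+", 1, 10, "protein_coding")

  res <- remove_paralogs(list(mk("same"), mk("diff")),
                         c(identical_seq, unrelated), train)
  expect_equal(res$removed, "same")
  expect_length(res$loci, 1)
  expect_equal(res$loci[[1]]$id, "diff")

  # a hit failing one threshold keeps the sequence
  fake_aligner <- function(query, targets) {
    data.frame(target = "t", identity = 0.9, coverage = 0.5)
  }
  res2 <- remove_paralogs(list(mk("x")), "ACGT", train,
                          aligner = fake_aligner)
  expect_length(res2$loci, 1)

  # idempotence
  res3 <- remove_paralogs(res$loci, res$seqs, train)
  expect_equal(vapply(res3$loci, `[[`, character(1), "id"),
               vapply(res$loci, `[[`, character(1), "id"))
})

test_that("archives batch 100 genes per group and round-trip losslessly", {
  mk_ex <- function(i) segment_gene(random_onehot(1200, seed = i),
                                    integer(1200), gene_id = paste0("g", i))
  examples <- lapply(1:250, mk_ex)
  arch <- write_archive(examples)
  expect_length(arch$groups, 3)
  expect_equal(vapply(arch$groups, function(g) length(g$gene_ids),
                      integer(1)), c(100L, 100L, 50L))

  path <- withr::local_tempfile(fileext = ".rds")
  write_archive_file(arch, path)
  back <- read_archive(path)
  expect_identical(back$groups[[2]]$X, arch$groups[[2]]$X)
  expect_identical(back$groups[[3]]$Y, arch$groups[[3]]$Y)

  # unpack restores the per-gene tensors
  ex_back <- archive_examples(arch)
  expect_equal(ex_back[[137]]$X, examples[[137]]$X)
  expect_equal(ex_back[[137]]$gene_id, "g137")

  expect_length(write_archive(examples[1])$groups, 1)
  expect_error(write_archive(list()), "zero examples")

  corrupt <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(not = "an archive"), corrupt)
  expect_error(read_archive(corrupt), "corrupt")
})

test_that("create-data recovers the fixture's planted ground truth exactly", {
  fx <- shared_fixture()
  loci <- parse_annotation(fx$gff)
  genome <- Biostrings::readDNAStringSet(fx$fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  sites <- extract_labeled_sites(loci, genome)
  truth <- fx$truth[order(fx$truth$chrom, fx$truth$pos, fx$truth$type), ]
  got <- sites[order(sites$chrom, sites$pos, sites$type), ]
  expect_equal(got$pos, truth$pos)
  expect_equal(got$type, truth$type)
  expect_equal(got$chrom, truth$chrom)
})

test_that("minus-strand labeling equals the reverse-complemented construction", {
  fx <- shared_fixture()
  minus <- Filter(function(g) g$strand == "-", fx$genes)[[1]]
  genome <- Biostrings::readDNAStringSet(fx$fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  loci <- parse_annotation(fx$gff)
  locus <- Filter(function(l) l$id == minus$id, loci)[[1]]
  tx <- select_canonical(locus)
  gseq <- spliceworks:::gene_sequence(locus, genome)
  # the sense-strand sequence equals the generator's sense construction
  expect_equal(gseq, minus$seq)
  lab <- label_splice_sites(spliceworks:::exons_local(locus, tx), gseq)
  expect_equal(sort(which(lab == 2L)), sort(minus$donors))
  expect_equal(sort(which(lab == 1L)), sort(minus$acceptors))
})
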