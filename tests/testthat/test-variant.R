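vcf_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- shared_fixture()
      vcf_path <- file.path(tempdir(), "fixture_variants.vcf")
      vv <- generate_vcf(fx, path = vcf_path, distance = 50, seed = 7)
      cache <<- list(fx = fx, vcf = vv)
    }
    cache
  }
})

test_that("variant validation applies the exclusion rules with reasons", {
  fx <- shared_fixture()
  genome <- fx$genome
  gene_ranges <- tibble::tibble(
    chrom = vapply(fx$genes, `[[`, character(1), "chrom"),
    start = vapply(fx$genes, `[[`, numeric(1), "start"),
    end = vapply(fx$genes, `[[`, numeric(1), "end"),
    gene = vapply(fx$genes, `[[`, character(1), "id"))
  g <- Filter(function(x) x$strand == "+", fx$genes)[[1]]
  mid <- g$start + 50L
  ref <- substr(genome[[g$chrom]], mid, mid)

  ok <- validate_variant(g$chrom, mid, ref, "A", gene_ranges, genome,
                         flank = 20, distance = 50)
  expect_true(ok$accept)
  expect_equal(ok$gene, g$id)

  inter <- validate_variant(g$chrom, 10L, "A", "C", gene_ranges, genome,
                            flank = 2, distance = 50)
  expect_false(inter$accept)
  expect_equal(inter$reason, "outside_gene")

  long_del <- validate_variant(g$chrom, mid, strrep("A", 151), "A",
                               gene_ranges, genome, flank = 20,
                               distance = 50)
  expect_false(long_del$accept)
  expect_equal(long_del$reason, "deletion_too_long")

  near_end <- validate_variant(g$chrom, 3L, "A", "C",
                               tibble::tibble(chrom = g$chrom, start = 1,
                                              end = 1e6, gene = "g"),
                               genome, flank = 100, distance = 50)
  expect_false(near_end$accept)
  expect_equal(near_end$reason, "too_close_to_chrom_end")

  wrong_ref <- validate_variant(g$chrom, mid,
                                if (ref == "A") "C" else "A", "G",
                                gene_ranges, genome, flank = 20,
                                distance = 50)
  expect_false(wrong_ref$accept)
  expect_equal(wrong_ref$reason, "ref_mismatch")
})

test_that("ref/alt construction spans the window and aligns indels", {
  genome <- c(chr = random_dna_str(2000, seed = 41))
  # SNP: same length, one base differs, identity map
  ba <- build_ref_alt("chr", 1000L, substr(genome[["chr"]], 1000, 1000),
                      "T", genome, distance = 50, flank = 20)
  expect_equal(nchar(ba$ref_seq), 2 * (50 + 10) + 1)
  expect_equal(nchar(ba$alt_seq), nchar(ba$ref_seq))
  diff_at <- which(seq_chars(ba$ref_seq) != seq_chars(ba$alt_seq))
  expect_lte(length(diff_at), 1)
  scores <- seq_len(101)
  expect_equal(ba$align_alt(scores), scores)

  # 2-nt deletion: alt shorter by 2; ref offsets +1, +2 masked
  ref3 <- substr(genome[["chr"]], 1000, 1002)
  ba_del <- build_ref_alt("chr", 1000L, ref3, substr(ref3, 1, 1), genome,
                          distance = 50, flank = 20)
  expect_equal(nchar(ba_del$alt_seq), nchar(ba_del$ref_seq) - 2)
  aligned <- ba_del$align_alt(seq_len(99))
  expect_true(all(is.na(aligned[c(52, 53)]))) # offsets +1 and +2
  expect_equal(sum(is.na(aligned)), 2)
  expect_equal(aligned[1:51], 1:51)   # identity up to the variant
  expect_equal(aligned[54], 52)       # right flank shifted by the deletion

  # 3-nt insertion: four alt slots collapse onto the variant offset by max
  ref1 <- substr(genome[["chr"]], 1000, 1000)
  ba_ins <- build_ref_alt("chr", 1000L, ref1, paste0(ref1, "ACG"), genome,
                          distance = 50, flank = 20)
  expect_equal(nchar(ba_ins$alt_seq), nchar(ba_ins$ref_seq) + 3)
  aligned_ins <- ba_ins$align_alt(seq_len(104))
  expect_equal(aligned_ins[51], 54)   # max over alt slots 51..54
  expect_equal(aligned_ins[52], 55)   # downstream shifted by +3
  expect_false(anyNA(aligned_ins))
})

test_that("delta scores match their defining maxima with deterministic ties", {
  n <- 101
  a <- runif(n)
  d <- runif(n)
  ann0 <- delta_scores(a, a, d, d)
  expect_equal(c(ann0$DS_AG, ann0$DS_AL, ann0$DS_DG, ann0$DS_DL),
               rep(0, 4))

  # planted acceptor gain of 0.7 at offset +3
  a_ref <- rep(0.1, n); a_alt <- a_ref
  a_alt[51 + 3] <- 0.8
  ann <- delta_scores(a_ref, a_alt, rep(0, n), rep(0, n))
  expect_equal(ann$DS_AG, 0.7)
  expect_equal(ann$DP_AG, 3L)

  # tie at offsets -2 and +2 resolves upstream
  a_tie <- rep(0, n); a_tie[c(49, 53)] <- 0.5
  ann_tie <- delta_scores(rep(0, n), a_tie, rep(0, n), rep(0, n))
  expect_equal(ann_tie$DP_AG, -2L)

  expect_error(delta_scores(numeric(0), numeric(0), numeric(0),
                            numeric(0)), "empty")
})

test_that("swapping ref and alt swaps gains and losses exactly", {
  set.seed(17)
  for (i in 1:50) {
    n <- 101
    a1 <- runif(n); a2 <- runif(n); d1 <- runif(n); d2 <- runif(n)
    fwd <- delta_scores(a1, a2, d1, d2)
    rev <- delta_scores(a2, a1, d2, d1)
    expect_equal(fwd$DS_AG, rev$DS_AL)
    expect_equal(fwd$DS_AL, rev$DS_AG)
    expect_equal(fwd$DS_DG, rev$DS_DL)
    expect_equal(fwd$DS_DL, rev$DS_DG)
    expect_true(all(c(fwd$DS_AG, fwd$DS_AL, fwd$DS_DG, fwd$DS_DL) >= 0))
    expect_true(all(c(fwd$DS_AG, fwd$DS_AL, fwd$DS_DG, fwd$DS_DL) <= 1))
    expect_true(all(abs(c(fwd$DP_AG, fwd$DP_AL, fwd$DP_DG,
                          fwd$DP_DL)) <= 50))
  }
})

test_that("VCF annotation scores valid variants and passes the rest through", {
  vf <- vcf_fixture()
  fx <- vf$fx
  out_vcf <- withr::local_tempfile(fileext = ".vcf")
  res <- annotate_vcf(vf$vcf$vcf, fx$fasta, fx$gff, shared_mock(),
                      distance = 50, vcf_out = out_vcf)
  expect_equal(nrow(res), nrow(vf$vcf$records))

  by_id <- split(res, res$id)
  expect_false(by_id$intergenic$accepted)
  expect_equal(by_id$intergenic$reason, "outside_gene")
  expect_false(by_id$long_deletion$accepted)
  expect_equal(by_id$long_deletion$reason, "deletion_too_long")
  expect_true(by_id$benign$accepted)
  expect_true(by_id$donor_loss$accepted)

  # destroying a planted donor GT: large donor loss, tiny donor gain
  expect_gt(by_id$donor_loss$DS_DL, 0.9)
  expect_lt(by_id$donor_loss$DS_DG, 0.1)
  # restoring a planted near-consensus donor: gain dominates loss
  expect_gt(by_id$donor_gain$DS_DG, 0.9)
  expect_gt(by_id$donor_gain$DS_DG, by_id$donor_gain$DS_DL)
  # benign exonic SNP moves nothing much
  expect_lt(max(by_id$benign$DS_AG, by_id$benign$DS_AL,
                by_id$benign$DS_DG, by_id$benign$DS_DL), 0.1)

  # output VCF: header declares the INFO key; skipped lines unchanged
  lines <- readLines(out_vcf)
  expect_true(any(grepl("##INFO=<ID=SpliceDelta", lines)))
  in_lines <- readLines(vf$vcf$vcf)
  skipped_in <- grep("\tintergenic\t", in_lines, value = TRUE)
  expect_true(skipped_in %in% lines)
  annotated <- grep("\tdonor_loss\t", lines, value = TRUE)
  expect_true(grepl("SpliceDelta=", annotated))
})

test_that("an empty VCF body yields a header-only annotated VCF", {
  fx <- shared_fixture()
  vcf_in <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), vcf_in)
  vcf_out <- withr::local_tempfile(fileext = ".vcf")
  res <- annotate_vcf(vcf_in, fx$fasta, fx$gff, shared_mock(),
                      vcf_out = vcf_out)
  expect_equal(nrow(res), 0)
  lines <- readLines(vcf_out)
  expect_true(all(startsWith(lines, "#")))
  expect_true(any(grepl("##INFO=<ID=SpliceDelta", lines)))
})
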