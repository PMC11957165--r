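# Deterministic synthetic genomes, annotations, variants and a mock
# scorer, so every stage of the pipeline is testable end-to-end without
# downloads. The generator plants strong splice-site consensus motifs
# (donor CAG|GTAAGT, acceptor polypyrimidine + TTTTTCAG|G) so that both
# the motif-matching mock scorer and small trained models have real
# signal to find.

DONOR_CONS <- "CAGGTAAGT"    # label at the 3rd base (last exonic)
DONOR_OFFSET <- 2L           # 0-based offset of the labeled base
ACCEPTOR_CONS <- "TTTTTCAGG" # label at the 9th base (first exonic)
ACCEPTOR_OFFSET <- 8L

#' Specify a synthetic-genome fixture
#'
#' @param seed Master seed; identical seeds give byte-identical outputs.
#' @param n_chromosomes,n_genes Genome shape.
#' @param exon_count Range of exons per gene.
#' @param exon_len,intron_len Length ranges (nt).
#' @param minus_fraction Fraction of genes on the minus strand.
#' @param pseudogene_fraction Fraction (of `n_genes`) of added pseudogene
#'   decoys.
#' @param paralog_fraction Fraction of genes duplicated as paralogs with
#'   `paralog_mutation_rate` per-base substitutions (consensus windows are
#'   never mutated, so planted labels stay truthful).
#' @param paralog_mutation_rate Per-base substitution rate in paralogs.
#' @param motif_mix Named probabilities over intron boundary motifs
#'   `gtag`, `gcag`, `atac`, `noncanonical`.
#' @param intergenic Intergenic spacer length between genes (nt).
#' @param polypyrimidine Enrich C/T upstream of acceptors.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chromosomes = 2L, n_genes = 8L,
                         exon_count = c(2L, 4L), exon_len = c(120L, 300L),
                         intron_len = c(90L, 200L), minus_fraction = 0.5,
                         pseudogene_fraction = 0, paralog_fraction = 0,
                         paralog_mutation_rate = 0.05,
                         motif_mix = c(gtag = 1, gcag = 0, atac = 0,
                                       noncanonical = 0),
                         intergenic = 400L, polypyrimidine = TRUE) {
  stopifnot(all(exon_len > 0), all(intron_len >= 20),
            pseudogene_fraction >= 0, pseudogene_fraction <= 1,
            paralog_fraction >= 0, paralog_fraction <= 1,
            abs(sum(motif_mix) - 1) < 1e-9)
  structure(as.list(environment()), class = "fixture_spec")
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

MOTIF_ENDS <- list(gtag = c("GT", "AG"), gcag = c("GC", "AG"),
                   atac = c("AT", "AC"), noncanonical = c("CT", "AT"))

# Build one gene in sense orientation. Returns sequence, local exon
# intervals, local donor/acceptor positions and motif classes.
build_gene <- function(spec) {
  k <- sample(spec$exon_count[1]:spec$exon_count[2], 1)
  exon_lens <- sample(spec$exon_len[1]:spec$exon_len[2], k, replace = TRUE)
  intron_lens <- if (k > 1) {
    sample(spec$intron_len[1]:spec$intron_len[2], k - 1, replace = TRUE)
  } else integer(0)
  motifs <- if (k > 1) {
    sample(names(spec$motif_mix), k - 1, replace = TRUE,
           prob = spec$motif_mix)
  } else character(0)

  pieces <- character(0)
  exons <- matrix(0L, nrow = k, ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  donors <- integer(0); acceptors <- integer(0)
  pos <- 0L
  broken_donor <- NA_integer_ # intronic near-consensus for gain variants
  for (j in seq_len(k)) {
    ex <- seq_chars(random_dna(exon_lens[j]))
    if (j > 1) ex[1] <- "G"                       # acceptor exonic G
    if (j < k) ex[(length(ex) - 2):length(ex)] <- c("C", "A", "G")
    exons[j, ] <- c(pos + 1L, pos + length(ex))
    pieces <- c(pieces, paste(ex, collapse = ""))
    pos <- pos + length(ex)
    if (j < k) {
      il <- intron_lens[j]
      intr <- seq_chars(random_dna(il))
      ends <- MOTIF_ENDS[[motifs[j]]]
      intr[1:6] <- c(seq_chars(ends[1]), "A", "A", "G", "T")
      if (spec$polypyrimidine) {
        ppt <- max(9L, il - 25L):(il - 8L)
        intr[ppt] <- sample(c("C", "T"), length(ppt), replace = TRUE,
                            prob = c(0.4, 0.6))
      }
      intr[(il - 7):(il - 2)] <- c("T", "T", "T", "T", "T", "C")
      intr[(il - 1):il] <- seq_chars(ends[2])
      # plant a single-mismatch donor consensus mid-intron for
      # gain-variant fixtures (CAGGT_C_AGT; fixing C->A restores it)
      if (is.na(broken_donor) && il >= 60) {
        at <- 20L
        intr[at:(at + 8)] <- seq_chars("CAGGTCAGT")
        broken_donor <- pos + at + 5L # local position of the broken base
      }
      donors <- c(donors, pos)          # last exonic base
      acceptors <- c(acceptors, pos + il + 1L)
      pieces <- c(pieces, paste(intr, collapse = ""))
      pos <- pos + il
    }
  }
  list(seq = paste(pieces, collapse = ""), exons = exons,
       donors = donors, acceptors = acceptors, motifs = motifs,
       broken_donor = broken_donor)
}

# Positions (local) covered by planted consensus windows; paralog
# mutation avoids them.
consensus_mask <- function(gene) {
  idx <- integer(0)
  for (d in gene$donors) idx <- c(idx, (d - 2L):(d + 6L))
  for (a in gene$acceptors) idx <- c(idx, (a - 8L):a)
  if (!is.na(gene$broken_donor)) {
    idx <- c(idx, (gene$broken_donor - 5L):(gene$broken_donor + 3L))
  }
  idx
}

#' Generate a synthetic genome, annotation and ground-truth site table
#'
#' Lays multi-exon genes (both strands) with planted boundary motifs along
#' uniform-random chromosomes, optionally adding pseudogene decoys and
#' mutated paralog copies. Identical seeds give byte-identical FASTA/GFF
#' output.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, `genome.fa` and
#'   `annotation.gff3` are written and their paths returned.
#' @return A `splice_fixture`: list with `genome` (named character),
#'   `truth` (tibble gene/chrom/strand/type/pos), `genes` (per-gene
#'   details incl. local structure), and `fasta`/`gff` paths when written.
#' @export
generate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    genes <- lapply(seq_len(spec$n_genes), function(i) {
      g <- build_gene(spec)
      g$id <- sprintf("gene%02d", i)
      g$strand <- if (stats::runif(1) < spec$minus_fraction) "-" else "+"
      g$biotype <- "protein_coding"
      g$feature_type <- "gene"
      g
    })
    n_pseudo <- round(spec$pseudogene_fraction * spec$n_genes)
    if (n_pseudo > 0) {
      for (i in seq_len(n_pseudo)) {
        src <- genes[[sample(spec$n_genes, 1)]]
        g <- src
        g$id <- sprintf("pseudo%02d", i)
        g$strand <- "+"
        g$biotype <- "processed_pseudogene"
        g$feature_type <- "pseudogene"
        g$donors <- integer(0); g$acceptors <- integer(0)
        g$broken_donor <- NA_integer_
        genes[[length(genes) + 1L]] <- g
      }
    }
    n_par <- round(spec$paralog_fraction * spec$n_genes)
    if (n_par > 0) {
      for (i in seq_len(n_par)) {
        src <- genes[[i]]
        g <- src
        g$id <- sprintf("%s_par", src$id)
        ch <- seq_chars(g$seq)
        mask <- consensus_mask(g)
        mutable <- setdiff(seq_along(ch), mask)
        n_mut <- round(spec$paralog_mutation_rate * length(mutable))
        at <- sample(mutable, n_mut)
        ch[at] <- vapply(ch[at], function(b) sample(setdiff(BASES, b), 1),
                         character(1))
        g$seq <- paste(ch, collapse = "")
        g$paralog_of <- src$id
        genes[[length(genes) + 1L]] <- g
      }
    }

    # round-robin placement across chromosomes
    chrom_of <- rep(seq_len(spec$n_chromosomes), length.out = length(genes))
    chroms <- stats::setNames(vector("list", spec$n_chromosomes),
                              sprintf("chr%d", seq_len(spec$n_chromosomes)))
    placed <- list()
    offsets <- integer(spec$n_chromosomes)
    parts <- lapply(seq_len(spec$n_chromosomes),
                    function(i) random_dna(spec$intergenic))
    offsets <- vapply(parts, nchar, integer(1))
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      ci <- chrom_of[gi]
      glen <- nchar(g$seq)
      gstart <- offsets[ci] + 1L
      body <- if (g$strand == "-") revcomp(g$seq) else g$seq
      parts[[ci]] <- paste0(parts[[ci]], body, random_dna(spec$intergenic))
      offsets[ci] <- offsets[ci] + glen + spec$intergenic
      g$chrom <- names(chroms)[ci]
      g$start <- gstart
      g$end <- gstart + glen - 1L
      placed[[gi]] <- g
    }
    genome <- stats::setNames(unlist(parts), names(chroms))

    to_genomic <- function(g, local) {
      if (g$strand == "-") g$end - local + 1L else g$start + local - 1L
    }
    truth_rows <- list()
    for (g in placed) {
      if (!length(g$donors) && !length(g$acceptors)) next
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        gene = g$id, chrom = g$chrom, strand = g$strand,
        type = c(rep("donor", length(g$donors)),
                 rep("acceptor", length(g$acceptors))),
        pos = c(vapply(g$donors, to_genomic, integer(1), g = g),
                vapply(g$acceptors, to_genomic, integer(1), g = g)))
    }
    truth <- if (length(truth_rows)) {
      tr <- do.call(rbind, truth_rows)
      tr[order(tr$chrom, tr$pos), ]
    } else tibble::tibble()

    fx <- structure(list(spec = spec, genome = genome, genes = placed,
                         truth = truth), class = "splice_fixture")
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fx$fasta <- file.path(dir, "genome.fa")
      fx$gff <- file.path(dir, "annotation.gff3")
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fx$fasta)
      writeLines(fixture_gff_lines(fx), fx$gff)
    }
    fx
  })
}

# GFF3 serialization of fixture genes (gene -> mRNA -> exon).
fixture_gff_lines <- function(fx) {
  lines <- "##gff-version 3"
  for (g in fx$genes) {
    attr_gene <- sprintf("ID=%s;gene_biotype=%s", g$id, g$biotype)
    lines <- c(lines, paste(g$chrom, "fixture", g$feature_type, g$start,
                            g$end, ".", g$strand, ".", attr_gene,
                            sep = "\t"))
    tid <- paste0(g$id, ".t1")
    lines <- c(lines, paste(g$chrom, "fixture", "mRNA", g$start, g$end, ".",
                            g$strand, ".",
                            sprintf("ID=%s;Parent=%s", tid, g$id),
                            sep = "\t"))
    glen <- g$end - g$start + 1L
    for (j in seq_len(nrow(g$exons))) {
      if (g$strand == "-") {
        es <- g$end - g$exons[j, "end"] + 1L
        ee <- g$end - g$exons[j, "start"] + 1L
      } else {
        es <- g$start + g$exons[j, "start"] - 1L
        ee <- g$start + g$exons[j, "end"] - 1L
      }
      lines <- c(lines, paste(g$chrom, "fixture", "exon", es, ee, ".",
                              g$strand, ".",
                              sprintf("ID=%s.e%d;Parent=%s", tid, j, tid),
                              sep = "\t"))
    }
  }
  lines
}

#' @export
print.splice_fixture <- function(x, ...) {
  cat(sprintf("<splice_fixture> %d chromosome(s), %d gene(s), %d truth site(s)\n",
              length(x$genome), length(x$genes), nrow(x$truth)))
  invisible(x)
}

#' Consensus-motif mock scorer
#'
#' A deterministic stand-in for a trained scorer: donor/acceptor logits
#' are proportional to the match count between the local sequence window
#' and the planted consensus motifs (donor CAG|GTAAGT, acceptor
#' TTTTTCAG|G), passed through a softmax. A full consensus match scores
#' above 0.9; one or more mismatches score below 0.1. Satisfies the same
#' forward contract as a trained scorer (simplex rows, output length
#' `n - CL`).
#'
#' @param sharpness Logit scale per matched base (default 10).
#' @param cl Declared cropping length (even; default 20).
#' @return A `mock_scorer`.
#' @export
make_mock_scorer <- function(sharpness = 10, cl = 20L) {
  stopifnot(cl %% 2 == 0, cl >= 18)
  structure(list(sharpness = sharpness, cl = as.integer(cl),
                 donor_consensus = DONOR_CONS, donor_offset = DONOR_OFFSET,
                 acceptor_consensus = ACCEPTOR_CONS,
                 acceptor_offset = ACCEPTOR_OFFSET),
            class = "mock_scorer")
}

#' @export
scorer_cl.mock_scorer <- function(scorer) scorer$cl

match_count <- function(ch, consensus, offset) {
  cons <- seq_chars(consensus)
  n <- length(ch)
  m <- integer(n)
  for (k in seq_along(cons)) {
    src <- seq_len(n) - offset + k - 1L
    ok <- src >= 1L & src <= n
    hits <- logical(n)
    hits[ok] <- ch[src[ok]] == cons[k]
    m <- m + hits
  }
  m
}

#' @rdname forward
#' @export
forward.mock_scorer <- function(scorer, x, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  single <- is.matrix(x)
  xb <- if (single) array(x, c(1L, nrow(x), ncol(x))) else x
  n <- dim(xb)[2]
  cl <- scorer$cl
  if (n <= cl) stop("input length ", n, " must exceed the cropping length ",
                    cl, " (minimum valid length ", cl + 1L, ")")
  half <- cl %/% 2L
  keep <- (half + 1L):(n - half)
  out <- array(0, dim = c(dim(xb)[1], length(keep), 3))
  for (i in seq_len(dim(xb)[1])) {
    ch <- seq_chars(decode_onehot(matrix(xb[i, , ], ncol = 4)))
    md <- match_count(ch, scorer$donor_consensus, scorer$donor_offset)
    ma <- match_count(ch, scorer$acceptor_consensus, scorer$acceptor_offset)
    z <- cbind(none = 0,
               acceptor = scorer$sharpness * (ma - 8.5),
               donor = scorer$sharpness * (md - 8.5))[keep, , drop = FALSE]
    out[i, , ] <- if (type == "prob") softmax_rows(z) else z
  }
  if (single) out[1, , , drop = TRUE] else out
}

#' Generate a variant fixture VCF with known expected effects
#'
#' Builds a small VCF against a fixture genome containing: a SNP
#' destroying a planted donor GT (expected donor-loss), a SNP restoring a
#' planted one-mismatch intronic donor consensus (expected donor-gain), a
#' benign exonic SNP, an intergenic SNP (expected skip), and a deletion
#' longer than `2 * distance` (expected skip). Each record's ID carries
#' its effect tag, also returned in a side table.
#'
#' @param fixture A `splice_fixture` from [generate_genome()].
#' @param path Optional output VCF path.
#' @param distance Delta-score window radius the fixture targets.
#' @param seed Seed for variant placement.
#' @return List with `records` tibble (`chrom`, `pos`, `id`, `ref`,
#'   `alt`, `expect`) and `vcf` path when written.
#' @export
generate_vcf <- function(fixture, path = NULL, distance = 50L, seed = 1L) {
  genome <- fixture$genome
  plus_genes <- Filter(function(g) g$strand == "+" && length(g$donors) > 0,
                       fixture$genes)
  if (!length(plus_genes)) stop("fixture has no plus-strand genes with introns")
  base_at <- function(chrom, pos) substr(genome[[chrom]], pos, pos)

  with_seed(seed, {
    recs <- list()
    g <- plus_genes[[1]]
    # donor loss: mutate the intronic G of the GT dinucleotide
    dpos <- g$start + g$donors[1] - 1L + 1L
    recs$donor_loss <- tibble::tibble(
      chrom = g$chrom, pos = dpos, id = "donor_loss",
      ref = base_at(g$chrom, dpos), alt = "A", expect = "donor_loss")
    # donor gain: fix the planted one-mismatch donor consensus
    gain_gene <- Filter(function(x) x$strand == "+" && !is.na(x$broken_donor),
                        fixture$genes)
    if (length(gain_gene)) {
      gg <- gain_gene[[1]]
      bpos <- gg$start + gg$broken_donor - 1L
      recs$donor_gain <- tibble::tibble(
        chrom = gg$chrom, pos = bpos, id = "donor_gain",
        ref = base_at(gg$chrom, bpos), alt = "A", expect = "donor_gain")
    }
    # benign exonic SNP, away from any consensus window
    mid_ex <- g$exons[1, "start"] + (g$exons[1, "end"] -
                                       g$exons[1, "start"]) %/% 2L
    bpos <- g$start + mid_ex - 1L
    ref <- base_at(g$chrom, bpos)
    recs$benign <- tibble::tibble(
      chrom = g$chrom, pos = bpos, id = "benign", ref = ref,
      alt = sample(setdiff(BASES, ref), 1), expect = "benign")
    # intergenic SNP (within the leading spacer)
    ipos <- 50L
    ref <- base_at(names(genome)[1], ipos)
    recs$intergenic <- tibble::tibble(
      chrom = names(genome)[1], pos = ipos, id = "intergenic", ref = ref,
      alt = sample(setdiff(BASES, ref), 1), expect = "skip_outside_gene")
    # over-long deletion inside the gene
    dstart <- g$start + 5L
    dlen <- 2L * distance + 2L
    recs$longdel <- tibble::tibble(
      chrom = g$chrom, pos = dstart, id = "long_deletion",
      ref = substr(genome[[g$chrom]], dstart, dstart + dlen),
      alt = base_at(g$chrom, dstart), expect = "skip_deletion_too_long")
    records <- do.call(rbind, recs)
    records <- records[order(records$chrom, records$pos), ]

    out <- list(records = records)
    if (!is.null(path)) {
      lines <- c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s,length=%d>", names(genome),
                         nchar(genome)),
                 paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                     "QUAL", "FILTER", "INFO"),
                                   collapse = "\t")),
                 sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                         records$chrom, records$pos, records$id,
                         records$ref, records$alt))
      writeLines(lines, path)
      out$vcf <- path
    }
    out
  })
}
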