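# Data preparation: FASTA + GFF3/GTF -> labeled, segmented one-hot tensors.
#
# Coordinate conventions: annotation intervals are 1-based inclusive
# (GFF/GTF); gene-local label tracks are 1-based over the sense-strand gene
# sequence; BED output elsewhere is 0-based half-open.

CORE_LEN <- 5000L   # central labeled region per segment
CTX_LEN <- 5000L    # context carried on each side of the core
SEG_LEN <- CORE_LEN + 2L * CTX_LEN

PSEUDOGENE_BIOTYPES <- c("pseudogene", "transcribed_pseudogene",
                         "processed_pseudogene")

CANONICAL_MOTIFS <- list(c("GT", "AG"), c("GC", "AG"), c("AT", "AC"))

new_gene_locus <- function(id, chrom, strand, start, end, biotype,
                           feature_type = "gene", transcripts = list()) {
  stopifnot(start <= end)
  structure(
    list(id = id, chrom = chrom, strand = strand, start = start, end = end,
         biotype = biotype, feature_type = feature_type,
         transcripts = transcripts),
    class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s %s:%d-%d(%s) biotype=%s transcripts=%d\n",
              x$id, x$chrom, x$start, x$end, x$strand,
              x$biotype %||% "NA", length(x$transcripts)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

first_or_na <- function(x) {
  if (is.null(x) || length(x) == 0) NA_character_ else as.character(x[[1]])
}

#' Parse a GFF3/GTF annotation into gene loci
#'
#' Reads a gene/transcript/exon hierarchy and returns one locus per gene
#' feature (pseudogene-typed features are retained so that
#' [filter_pseudogenes()] can act on them). With
#' `biotype_filter = "protein-coding"` only genes whose
#' `gene_biotype`/`biotype` attribute is `protein_coding` are kept;
#' `"all"` keeps every biotype. Exons whose `Parent` does not resolve to a
#' known transcript are dropped with a warning.
#'
#' @param gff Path to a GFF3 or GTF file.
#' @param biotype_filter `"protein-coding"` (default) or `"all"`.
#' @return A list of `gene_locus` objects.
#' @export
parse_annotation <- function(gff, biotype_filter = c("protein-coding", "all")) {
  biotype_filter <- match.arg(biotype_filter)
  gr <- tryCatch(rtracklayer::import(gff),
                 error = function(e) stop("unreadable annotation file: ",
                                          conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  biotype_col <- if ("gene_biotype" %in% names(mc)) "gene_biotype"
                 else if ("biotype" %in% names(mc)) "biotype" else NULL

  is_gtf <- "transcript_id" %in% names(mc) && !("Parent" %in% names(mc))
  gene_rows <- which(type %in% c("gene", "pseudogene"))
  loci <- list()

  if (is_gtf) {
    exon_rows <- which(type == "exon")
    ex_tx <- as.character(mc$transcript_id[exon_rows])
    ex_gene <- as.character(mc$gene_id[exon_rows])
    for (gi in gene_rows) {
      gid <- as.character(mc$gene_id[gi])
      bt <- if (is.null(biotype_col)) NA_character_
            else as.character(mc[[biotype_col]][gi])
      sel <- exon_rows[ex_gene == gid]
      txs <- split(sel, as.character(mc$transcript_id[sel]))
      transcripts <- lapply(names(txs), function(tid) {
        rows <- txs[[tid]]
        ex <- cbind(start = GenomicRanges::start(gr)[rows],
                    end = GenomicRanges::end(gr)[rows])
        ex <- ex[order(ex[, 1]), , drop = FALSE]
        list(id = tid, exons = ex)
      })
      loci[[length(loci) + 1L]] <- new_gene_locus(
        id = gid, chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
        strand = as.character(GenomicRanges::strand(gr)[gi]),
        start = GenomicRanges::start(gr)[gi],
        end = GenomicRanges::end(gr)[gi],
        biotype = bt, feature_type = type[gi], transcripts = transcripts)
    }
  } else {
    ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else
      rep(NA_character_, length(gr))
    parents <- if ("Parent" %in% names(mc)) {
      vapply(as.list(mc$Parent), first_or_na, character(1))
    } else rep(NA_character_, length(gr))

    tx_rows <- which(!(type %in% c("gene", "pseudogene", "exon", "CDS",
                                   "five_prime_UTR", "three_prime_UTR",
                                   "start_codon", "stop_codon")) &
                       !is.na(parents))
    tx_parent <- parents[tx_rows]
    names(tx_rows) <- ids[tx_rows]

    exon_rows <- which(type == "exon")
    ex_parent <- parents[exon_rows]
    orphan <- !(ex_parent %in% ids[tx_rows])
    if (any(orphan)) {
      warning(sum(orphan), " exon record(s) without a resolvable transcript",
              " parent were dropped")
      exon_rows <- exon_rows[!orphan]
      ex_parent <- ex_parent[!orphan]
    }
    exons_by_tx <- split(exon_rows, ex_parent)

    for (gi in gene_rows) {
      gid <- ids[gi] %||% paste0("gene", gi)
      bt <- if (is.null(biotype_col)) NA_character_
            else as.character(mc[[biotype_col]][gi])
      child_tx <- tx_rows[tx_parent == gid]
      transcripts <- lapply(names(child_tx), function(tid) {
        rows <- exons_by_tx[[tid]]
        if (is.null(rows)) return(NULL)
        ex <- cbind(start = GenomicRanges::start(gr)[rows],
                    end = GenomicRanges::end(gr)[rows])
        ex <- ex[order(ex[, 1]), , drop = FALSE]
        list(id = tid, exons = ex)
      })
      transcripts <- Filter(Negate(is.null), transcripts)
      loci[[length(loci) + 1L]] <- new_gene_locus(
        id = gid, chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
        strand = as.character(GenomicRanges::strand(gr)[gi]),
        start = GenomicRanges::start(gr)[gi],
        end = GenomicRanges::end(gr)[gi],
        biotype = bt, feature_type = type[gi], transcripts = transcripts)
    }
  }

  if (biotype_filter == "protein-coding") {
    keep <- vapply(loci, function(l) {
      !is.na(l$biotype) && l$biotype %in% c("protein_coding", "protein-coding")
    }, logical(1))
    loci <- loci[keep]
  }
  loci
}

#' Remove pseudogene loci
#'
#' Drops loci whose GFF feature type (third column) is `pseudogene` or whose
#' `gene_biotype`/`biotype` is one of `pseudogene`, `transcribed_pseudogene`,
#' `processed_pseudogene`. Loci with missing attributes are kept.
#'
#' @param loci List of `gene_locus` objects.
#' @return The filtered list.
#' @export
filter_pseudogenes <- function(loci) {
  keep <- vapply(loci, function(l) {
    ft_pseudo <- !is.na(l$feature_type) && l$feature_type == "pseudogene"
    bt_pseudo <- !is.na(l$biotype) && l$biotype %in% PSEUDOGENE_BIOTYPES
    !(ft_pseudo || bt_pseudo)
  }, logical(1))
  loci[keep]
}

#' Select the canonical transcript of a locus
#'
#' The canonical transcript is the one with the longest genomic span; ties
#' are broken by the lexicographically smallest transcript id so the choice
#' is deterministic across runs.
#'
#' @param locus A `gene_locus`.
#' @return The chosen transcript (list with `id` and genomic `exons`
#'   matrix), or `NULL` with a warning when the locus has no transcripts.
#' @export
select_canonical <- function(locus) {
  txs <- locus$transcripts
  if (length(txs) == 0) {
    warning("locus ", locus$id, " has no transcripts; skipped")
    return(NULL)
  }
  lens <- vapply(txs, function(t) {
    max(t$exons[, "end"]) - min(t$exons[, "start"]) + 1L
  }, numeric(1))
  ids <- vapply(txs, `[[`, character(1), "id")
  best <- which(lens == max(lens))
  txs[[best[order(ids[best])[1]]]]
}

# Convert genomic exon intervals of a transcript to 1-based sense-strand
# gene-local intervals, sorted 5'->3'.
exons_local <- function(locus, transcript) {
  ex <- transcript$exons
  if (locus$strand == "-") {
    loc <- cbind(start = locus$end - ex[, "end"] + 1L,
                 end = locus$end - ex[, "start"] + 1L)
  } else {
    loc <- cbind(start = ex[, "start"] - locus$start + 1L,
                 end = ex[, "end"] - locus$start + 1L)
  }
  loc[order(loc[, 1]), , drop = FALSE]
}

#' Label donor and acceptor splice sites on a gene sequence
#'
#' For every intron of the transcript, the donor is labeled at the last
#' exonic base of the upstream exon and the acceptor at the first exonic
#' base of the downstream exon, both in sense-strand gene-local coordinates
#' (minus-strand genes must already be reverse-complemented). With
#' `canonical_only = TRUE`, introns whose terminal dinucleotides fall
#' outside the GT-AG / GC-AG / AT-AC motif set contribute no labels.
#'
#' @param exons Integer matrix of sense-local exon intervals (columns
#'   `start`, `end`), or a transcript list carrying such a matrix in
#'   `$exons`.
#' @param gene_seq Sense-strand gene sequence (character).
#' @param canonical_only Restrict labels to canonical intron motifs.
#' @return Integer vector over the gene sequence: 0 none, 1 acceptor,
#'   2 donor.
#' @export
label_splice_sites <- function(exons, gene_seq, canonical_only = FALSE) {
  if (is.list(exons)) exons <- exons$exons
  n <- nchar(gene_seq)
  if (any(exons < 1L) || any(exons > n)) {
    stop("exon interval outside gene sequence bounds")
  }
  labels <- integer(n)
  k <- nrow(exons)
  if (k < 2L) return(labels)
  seq_up <- toupper(gene_seq)
  for (j in seq_len(k - 1L)) {
    istart <- exons[j, "end"] + 1L
    iend <- exons[j + 1L, "start"] - 1L
    if (iend - istart + 1L < 2L) next
    d5 <- substr(seq_up, istart, istart + 1L)
    d3 <- substr(seq_up, iend - 1L, iend)
    if (canonical_only) {
      ok <- any(vapply(CANONICAL_MOTIFS,
                       function(m) m[1] == d5 && m[2] == d3, logical(1)))
      if (!ok) next
    }
    labels[exons[j, "end"]] <- LBL_DONOR
    labels[exons[j + 1L, "start"]] <- LBL_ACCEPTOR
  }
  labels
}

#' Segment a gene into fixed-size training windows
#'
#' Tiles the gene into `ceil(L/5000)` disjoint 5,000-nt label cores, each
#' carried inside a 15,000-nt feature window (5,000 nt of context per
#' side). Feature deficits are padded with zero rows (the N encoding) and
#' label deficits with the all-zero pad vector, so concatenating the cores
#' and trimming trailing pad reconstructs the full label track.
#'
#' @param onehot `L x 4` one-hot feature matrix for the gene.
#' @param labels Integer label track of length `L` (see
#'   [label_splice_sites()]) or an `L x 3` one-hot label matrix.
#' @param gene_id Optional identifier stored with the example.
#' @return A `segmented_example`: list with `X` (`n_seg x 15000 x 4`),
#'   `Y` (`n_seg x 5000 x 3`) and `gene_id`.
#' @export
segment_gene <- function(onehot, labels, gene_id = NA_character_) {
  L <- nrow(onehot)
  if (is.null(L) || L < 1L) stop("zero-length gene cannot be segmented")
  if (is.matrix(labels)) {
    stopifnot(nrow(labels) == L, ncol(labels) == 3)
    y_full <- labels
  } else {
    stopifnot(length(labels) == L)
    y_full <- labels_to_onehot(labels)
  }
  n_seg <- as.integer(ceiling(L / CORE_LEN))
  padded_len <- n_seg * CORE_LEN

  xp <- matrix(0, nrow = padded_len + 2L * CTX_LEN, ncol = 4)
  xp[CTX_LEN + seq_len(L), ] <- onehot
  yp <- matrix(0, nrow = padded_len, ncol = 3)
  yp[seq_len(L), ] <- y_full

  X <- array(0, dim = c(n_seg, SEG_LEN, 4))
  Y <- array(0, dim = c(n_seg, CORE_LEN, 3))
  for (s in seq_len(n_seg)) {
    off <- (s - 1L) * CORE_LEN
    X[s, , ] <- xp[off + seq_len(SEG_LEN), ]
    Y[s, , ] <- yp[off + seq_len(CORE_LEN), ]
  }
  structure(list(gene_id = gene_id, X = X, Y = Y, length = L),
            class = "segmented_example")
}

#' Specify a train/test chromosome split
#'
#' `method = "human"` uses the fixed human assignment (chromosomes 1, 3, 5,
#' 7, 9 held out for testing; 2, 4, 6, 8, 10-22, X, Y for training).
#' `method = "random"` shuffles chromosomes with the given seed and
#' accumulates them by length into the training set until at least `ratio`
#' of the total length is covered; the remainder is the test set.
#'
#' @param method `"human"` or `"random"`.
#' @param ratio Training fraction for the random method (default 0.8).
#' @param seed Seed for the random method (default 10).
#' @return A `split_spec` list.
#' @export
split_spec <- function(method = c("random", "human"), ratio = 0.8, seed = 10) {
  method <- match.arg(method)
  structure(list(method = method, ratio = ratio, seed = as.integer(seed)),
            class = "split_spec")
}

HUMAN_TRAIN_CHROMS <- c(as.character(c(2, 4, 6, 8, 10:22)), "X", "Y")
HUMAN_TEST_CHROMS <- as.character(c(1, 3, 5, 7, 9))

normalize_chrom <- function(x) toupper(sub("^chr", "", x, ignore.case = TRUE))

#' Split gene loci into training and test sets by chromosome
#'
#' @param loci List of `gene_locus` objects.
#' @param spec A [split_spec()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (required
#'   for the random method; typically the FASTA sequence widths).
#' @return List with `train`, `test` (lists of loci) and `assignment`
#'   (tibble of chromosome -> set).
#' @export
split_dataset <- function(loci, spec, chrom_lengths = NULL) {
  stopifnot(inherits(spec, "split_spec"))
  chroms <- unique(vapply(loci, `[[`, character(1), "chrom"))
  if (spec$method == "human") {
    norm <- normalize_chrom(chroms)
    set <- ifelse(norm %in% HUMAN_TRAIN_CHROMS, "train",
                  ifelse(norm %in% HUMAN_TEST_CHROMS, "test", NA))
    if (anyNA(set)) {
      warning("chromosome(s) outside the human split lists excluded: ",
              paste(chroms[is.na(set)], collapse = ", "))
    }
  } else {
    if (is.null(chrom_lengths)) {
      stop("chrom_lengths is required for the random split method")
    }
    lens <- chrom_lengths[chroms]
    if (anyNA(lens)) stop("missing lengths for chromosome(s): ",
                          paste(chroms[is.na(lens)], collapse = ", "))
    ord <- with_seed(spec$seed, sample.int(length(chroms)))
    total <- sum(lens)
    acc <- 0
    set <- rep("test", length(chroms))
    for (i in ord) {
      if (acc / total >= spec$ratio) break
      set[i] <- "train"
      acc <- acc + lens[i]
    }
  }
  names(set) <- chroms
  by_locus <- set[vapply(loci, `[[`, character(1), "chrom")]
  list(train = loci[!is.na(by_locus) & by_locus == "train"],
       test = loci[!is.na(by_locus) & by_locus == "test"],
       assignment = tibble::tibble(chrom = chroms, set = unname(set)))
}

#' Local-alignment backend built on Biostrings
#'
#' Returns a function implementing the paralog-aligner contract
#' `align(query, targets) -> data.frame(target, identity, coverage)`, where
#' identity is matching bases over the alignment block length and coverage
#' the aligned query span over the query length. Suitable for the gene-scale
#' sequences of fixtures and small genomes; any backend honouring the same
#' contract (e.g. a minimizer-based long-read aligner) can be substituted.
#'
#' @param match,mismatch,gap_opening,gap_extension Local-alignment scoring.
#' @return A backend function.
#' @export
pairwise_aligner <- function(match = 2, mismatch = -3,
                             gap_opening = 5, gap_extension = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  function(query, targets) {
    q <- Biostrings::DNAString(query)
    res <- lapply(seq_along(targets), function(i) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = q, subject = Biostrings::DNAString(targets[[i]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_opening, gapExtension = gap_extension)
      aln_len <- Biostrings::nchar(pa)
      data.frame(
        target = names(targets)[i] %||% as.character(i),
        identity = if (aln_len > 0) Biostrings::nmatch(pa) / aln_len else 0,
        coverage = IRanges::width(Biostrings::pattern(pa)@range) /
          nchar(query))
    })
    do.call(rbind, res)
  }
}

#' Remove test loci paralogous to training sequences
#'
#' A test locus is excluded when its gene-span DNA aligns to any training
#' sequence with identity above `min_identity` and query coverage above
#' `min_coverage` (both strict), the standard leakage guard between
#' training and held-out splice sites.
#'
#' @param test_loci List of test `gene_locus` objects.
#' @param test_seqs Character vector of test gene sequences, parallel to
#'   `test_loci`.
#' @param train_seqs Named character vector of training gene sequences.
#' @param min_identity,min_coverage Exclusion thresholds (default 0.8).
#' @param aligner Backend from [pairwise_aligner()] or a compatible
#'   function.
#' @return List with `loci` (kept loci), `seqs` (their sequences) and
#'   `removed` (ids of excluded loci).
#' @export
remove_paralogs <- function(test_loci, test_seqs, train_seqs,
                            min_identity = 0.8, min_coverage = 0.8,
                            aligner = pairwise_aligner()) {
  stopifnot(length(test_loci) == length(test_seqs))
  if (length(train_seqs) == 0 || length(test_loci) == 0) {
    return(list(loci = test_loci, seqs = test_seqs, removed = character(0)))
  }
  drop <- vapply(seq_along(test_loci), function(i) {
    hits <- aligner(test_seqs[[i]], train_seqs)
    any(hits$identity > min_identity & hits$coverage > min_coverage)
  }, logical(1))
  if (any(drop)) {
    message(sum(drop), " paralogous test sequence(s) removed")
  }
  list(loci = test_loci[!drop], seqs = test_seqs[!drop],
       removed = vapply(test_loci[drop], `[[`, character(1), "id"))
}

#' Extract labeled splice sites in genomic coordinates
#'
#' Runs canonical-transcript selection and splice-site labeling for each
#' locus and reports every labeled site with its 1-based genomic
#' coordinate, for auditing label tracks against external ground truth.
#'
#' @param loci List of `gene_locus` objects.
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param canonical_only Passed to [label_splice_sites()].
#' @return Tibble with columns `gene`, `chrom`, `strand`, `type`
#'   (`donor`/`acceptor`) and `pos`.
#' @export
extract_labeled_sites <- function(loci, genome, canonical_only = FALSE) {
  rows <- list()
  for (locus in loci) {
    tx <- select_canonical(locus)
    if (is.null(tx)) next
    gseq <- gene_sequence(locus, genome)
    lab <- label_splice_sites(exons_local(locus, tx), gseq,
                              canonical_only = canonical_only)
    sites <- which(lab != LBL_NONE)
    if (!length(sites)) next
    gpos <- if (locus$strand == "-") locus$end - sites + 1L
            else locus$start + sites - 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = locus$id, chrom = locus$chrom, strand = locus$strand,
      type = ifelse(lab[sites] == LBL_DONOR, "donor", "acceptor"),
      pos = gpos)
  }
  if (!length(rows)) {
    return(tibble::tibble(gene = character(0), chrom = character(0),
                          strand = character(0), type = character(0),
                          pos = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), ]
}

# Sense-strand, uppercased gene sequence for a locus.
gene_sequence <- function(locus, genome) {
  if (inherits(genome, "DNAStringSet")) {
    s <- as.character(Biostrings::subseq(genome[[locus$chrom]],
                                         locus$start, locus$end))
  } else {
    s <- substr(genome[[locus$chrom]], locus$start, locus$end)
  }
  s <- toupper(s)
  if (locus$strand == "-") revcomp(s) else s
}

#' Build train/test datasets from a genome and annotation
#'
#' The full preprocessing pipeline: parse and biotype-filter the
#' annotation, drop pseudogenes, split chromosomes into train/test, select
#' canonical transcripts, extract sense-strand gene sequences, label splice
#' sites, segment into training tensors, optionally remove paralogous test
#' genes, and package both sets as archives.
#'
#' @param genome_fasta Path to the genome FASTA.
#' @param annotation_gff Path to the GFF3/GTF annotation.
#' @param output_dir Optional directory; when given, archives
#'   (`dataset_train.rds`, `dataset_test.rds`), a gene summary TSV and
#'   (optionally) a FASTA of extracted gene sequences are written there.
#' @param biotype Biotype filter, `"protein-coding"` or `"all"`.
#' @param split Split specification from [split_spec()].
#' @param remove_paralogs Exclude test genes similar to training genes.
#' @param min_identity,min_coverage Paralog-exclusion thresholds.
#' @param canonical_only Restrict labels to canonical intron motifs.
#' @param write_fasta Also dump extracted gene sequences as FASTA.
#' @param aligner Paralog aligner backend (see [pairwise_aligner()]).
#' @return List with `train` and `test` archives and a `summary` tibble.
#' @export
create_dataset <- function(genome_fasta, annotation_gff, output_dir = NULL,
                           biotype = "protein-coding",
                           split = split_spec("random"),
                           remove_paralogs = FALSE,
                           min_identity = 0.8, min_coverage = 0.8,
                           canonical_only = FALSE, write_fasta = FALSE,
                           aligner = pairwise_aligner()) {
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`, character(1), 1)

  loci <- parse_annotation(annotation_gff, biotype_filter = biotype)
  loci <- filter_pseudogenes(loci)
  if (!length(loci)) stop("no loci retained after filtering")

  sp <- split_dataset(loci, split, chrom_lengths = stats::setNames(
    as.numeric(Biostrings::width(genome)), names(genome)))

  build_side <- function(side_loci) {
    seqs <- vapply(side_loci, gene_sequence, character(1), genome = genome)
    names(seqs) <- vapply(side_loci, `[[`, character(1), "id")
    list(loci = side_loci, seqs = seqs)
  }
  train <- build_side(sp$train)
  test <- build_side(sp$test)

  if (remove_paralogs && length(test$loci)) {
    filt <- remove_paralogs(test$loci, test$seqs, train$seqs,
                            min_identity = min_identity,
                            min_coverage = min_coverage, aligner = aligner)
    test <- list(loci = filt$loci, seqs = filt$seqs)
  }

  make_examples <- function(side) {
    examples <- list()
    for (i in seq_along(side$loci)) {
      locus <- side$loci[[i]]
      tx <- select_canonical(locus)
      if (is.null(tx)) next
      gseq <- side$seqs[[i]]
      lab <- label_splice_sites(exons_local(locus, tx), gseq,
                                canonical_only = canonical_only)
      examples[[length(examples) + 1L]] <-
        segment_gene(encode_sequence(gseq), lab, gene_id = locus$id)
    }
    examples
  }

  meta <- list(flank = 2L * CTX_LEN, core = CORE_LEN,
               encoding_version = 1L, canonical_only = canonical_only,
               label_convention = paste("donor at last exonic base of the",
                                        "upstream exon; acceptor at first",
                                        "exonic base of the downstream exon"),
               split_method = split$method, split_ratio = split$ratio,
               split_seed = split$seed)

  train_ex <- make_examples(train)
  test_ex <- make_examples(test)
  train_arch <- if (length(train_ex)) {
    write_archive(train_ex, meta = c(meta, list(set = "train")))
  } else NULL
  test_arch <- if (length(test_ex)) {
    write_archive(test_ex, meta = c(meta, list(set = "test")))
  } else NULL

  summarize <- function(side, set) {
    if (!length(side$loci)) return(NULL)
    tibble::tibble(
      gene = vapply(side$loci, `[[`, character(1), "id"),
      chrom = vapply(side$loci, `[[`, character(1), "chrom"),
      strand = vapply(side$loci, `[[`, character(1), "strand"),
      length = nchar(unname(side$seqs)), set = set)
  }
  summary <- rbind(summarize(train, "train"), summarize(test, "test"))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(train_arch)) {
      write_archive_file(train_arch, file.path(output_dir, "dataset_train.rds"))
    }
    if (!is.null(test_arch)) {
      write_archive_file(test_arch, file.path(output_dir, "dataset_test.rds"))
    }
    utils::write.table(summary, file.path(output_dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_fasta) {
      all_seqs <- c(train$seqs, test$seqs)
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(all_seqs),
        file.path(output_dir, "gene_sequences.fa"))
    }
  }

  list(train = train_arch, test = test_arch, summary = summary)
}
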