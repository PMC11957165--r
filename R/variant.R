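# VCF variant annotation with splice gain/loss delta scores: the maximum
# change, within a window around the variant, in predicted acceptor/donor
# probability between the reference and alternate alleles.

#' Validate a variant for delta-score annotation
#'
#' Applies the exclusion rules: variants outside annotated gene intervals,
#' variants closer than `flank` to a chromosome end, deletions longer than
#' `2 * distance`, and records whose REF allele does not match the genome.
#' Skips are reported with machine-readable reason codes, never fatally.
#'
#' @param chrom,pos,ref,alt The variant (1-based position).
#' @param gene_ranges Tibble/data.frame of gene intervals with columns
#'   `chrom`, `start`, `end` (and optionally `gene`, `strand`).
#' @param genome Named `DNAStringSet` or character vector of chromosomes.
#' @param flank Model flanking size.
#' @param distance Delta-score window radius (default 50).
#' @return List with `accept` (logical), `reason` (`NA` when accepted) and
#'   `gene` (overlapping gene id, if any).
#' @export
validate_variant <- function(chrom, pos, ref, alt, gene_ranges, genome,
                             flank, distance = 50L) {
  skip <- function(reason, gene = NA_character_) {
    list(accept = FALSE, reason = reason, gene = gene)
  }
  if (!chrom %in% names(genome)) return(skip("chrom_not_in_genome"))
  chrom_len <- if (inherits(genome, "DNAStringSet")) {
    Biostrings::width(genome[chrom])
  } else nchar(genome[[chrom]])

  hit <- gene_ranges$chrom == chrom & gene_ranges$start <= pos &
    gene_ranges$end >= pos
  if (!any(hit)) return(skip("outside_gene"))
  gene <- if ("gene" %in% names(gene_ranges)) {
    gene_ranges$gene[which(hit)[1]]
  } else NA_character_

  if (pos < flank || pos > chrom_len - flank) {
    return(skip("too_close_to_chrom_end", gene))
  }
  del_len <- nchar(ref) - nchar(alt)
  if (del_len > 2L * distance) return(skip("deletion_too_long", gene))

  genome_ref <- if (inherits(genome, "DNAStringSet")) {
    as.character(Biostrings::subseq(genome[[chrom]], pos,
                                    pos + nchar(ref) - 1L))
  } else substr(genome[[chrom]], pos, pos + nchar(ref) - 1L)
  if (toupper(genome_ref) != toupper(ref)) return(skip("ref_mismatch", gene))

  list(accept = TRUE, reason = NA_character_, gene = gene)
}

#' Build aligned reference and alternate sequences around a variant
#'
#' Both sequences span `variant position +/- (distance + flank/2)` so that
#' a scorer with `CL = flank` returns scores for exactly the
#' `2 * distance + 1` comparison positions. For indels, an alignment map
#' relates alternate-track positions to reference offsets: reference
#' positions inside a deletion are masked, and scores over inserted bases
#' are collapsed onto the variant slot by maximum.
#'
#' @param chrom,pos,ref,alt The (validated) variant.
#' @param genome Named `DNAStringSet` or character vector.
#' @param distance Window radius (default 50).
#' @param flank Model flanking size.
#' @return List with `ref_seq`, `alt_seq`, `offsets` (reference offsets
#'   `-distance ... +distance`), and `align_alt(scores)` mapping an
#'   alternate score track onto reference offsets (`NA` where masked).
#' @export
build_ref_alt <- function(chrom, pos, ref, alt, genome, distance = 50L,
                          flank) {
  half <- flank %/% 2L
  radius <- distance + half
  lo <- pos - radius
  hi <- pos + radius + nchar(ref) - 1L
  get_seq <- function(a, b) {
    if (inherits(genome, "DNAStringSet")) {
      as.character(Biostrings::subseq(genome[[chrom]], a, b))
    } else substr(genome[[chrom]], a, b)
  }
  chrom_len <- if (inherits(genome, "DNAStringSet")) {
    Biostrings::width(genome[chrom])
  } else nchar(genome[[chrom]])
  if (lo < 1L || hi > chrom_len) {
    stop("variant window exceeds chromosome bounds")
  }
  left <- get_seq(lo, pos - 1L)
  right <- get_seq(pos + nchar(ref), hi)
  ref_seq <- toupper(paste0(left, get_seq(pos, pos + nchar(ref) - 1L), right))
  alt_seq <- toupper(paste0(left, alt, right))

  n_ref <- nchar(ref)
  n_alt <- nchar(alt)
  # Score tracks start at genomic position lo + half = pos - distance.
  # Reference track index for offset o (-distance..distance before the
  # allele, allele-aware beyond it) is distance + 1 + o.
  offsets <- -distance:distance

  align_alt <- function(alt_scores) {
    # alt_scores: vector over the alt track (length 2*distance+1+n_alt-n_ref)
    out <- rep(NA_real_, 2L * distance + 1L)
    for (j in seq_along(offsets)) {
      o <- offsets[j]
      if (o < 0) {
        out[j] <- alt_scores[distance + 1L + o]
      } else if (o == 0) {
        # variant slot: max over the alt allele span (collapses insertions)
        span <- distance + 1L + seq_len(max(1L, n_alt)) - 1L
        span <- span[span <= length(alt_scores)]
        out[j] <- if (length(span)) max(alt_scores[span]) else NA_real_
      } else {
        if (o < n_ref) {
          # inside the reference allele beyond its first base: for
          # deletions these reference positions have no alternate
          # counterpart and stay masked
          out[j] <- if (n_alt > o) alt_scores[distance + 1L + o] else NA_real_
        } else {
          # right of both alleles: shift by the length difference
          idx <- distance + 1L + o + (n_alt - n_ref)
          out[j] <- if (idx >= 1L && idx <= length(alt_scores)) {
            alt_scores[idx]
          } else NA_real_
        }
      }
    }
    out
  }

  list(ref_seq = ref_seq, alt_seq = alt_seq, offsets = offsets,
       align_alt = align_alt)
}

#' Delta scores and delta positions from aligned score arrays
#'
#' `DS_AG = max(a_alt - a_ref)`, `DS_AL = max(a_ref - a_alt)`,
#' `DS_DG = max(d_alt - d_ref)`, `DS_DL = max(d_ref - d_alt)`, each over
#' the `2*distance + 1` comparison window, reported clipped to `[0, 1]`
#' (signed values kept in `raw`). The delta positions are the offsets of
#' the maxima; ties resolve to the smallest absolute offset, then
#' upstream (negative).
#'
#' @param a_ref,a_alt,d_ref,d_alt Aligned acceptor/donor score arrays over
#'   the window (`NA` = masked by an indel).
#' @param offsets Reference offsets, default `-distance..distance` from
#'   the array length.
#' @return A `delta_annotation` list with `DS_AG`, `DS_AL`, `DS_DG`,
#'   `DS_DL`, `DP_AG`, `DP_AL`, `DP_DG`, `DP_DL` and `raw`.
#' @export
delta_scores <- function(a_ref, a_alt, d_ref, d_alt, offsets = NULL) {
  n <- length(a_ref)
  if (n == 0) stop("empty comparison window")
  stopifnot(length(a_alt) == n, length(d_ref) == n, length(d_alt) == n)
  if (is.null(offsets)) offsets <- seq_len(n) - ((n + 1L) %/% 2L)

  peak <- function(diff) {
    ok <- which(!is.na(diff))
    if (!length(ok)) return(list(ds = 0, dp = 0L, raw = 0))
    m <- max(diff[ok])
    at <- ok[diff[ok] == m]
    # ties: smallest absolute offset, then upstream
    at <- at[order(abs(offsets[at]), offsets[at])]
    list(ds = max(0, min(1, m)), dp = as.integer(offsets[at[1]]), raw = m)
  }
  ag <- peak(a_alt - a_ref)
  al <- peak(a_ref - a_alt)
  dg <- peak(d_alt - d_ref)
  dl <- peak(d_ref - d_alt)
  structure(list(
    DS_AG = ag$ds, DS_AL = al$ds, DS_DG = dg$ds, DS_DL = dl$ds,
    DP_AG = ag$dp, DP_AL = al$dp, DP_DG = dg$dp, DP_DL = dl$dp,
    raw = c(AG = ag$raw, AL = al$raw, DG = dg$raw, DL = dl$raw)),
    class = "delta_annotation")
}

#' @export
print.delta_annotation <- function(x, ...) {
  cat(sprintf(
    "<delta_annotation> AG %.3f@%+d  AL %.3f@%+d  DG %.3f@%+d  DL %.3f@%+d\n",
    x$DS_AG, x$DP_AG, x$DS_AL, x$DP_AL, x$DS_DG, x$DP_DG, x$DS_DL, x$DP_DL))
  invisible(x)
}

# Minimal VCF text reader preserving original lines for passthrough.
read_vcf_lines <- function(path) {
  lines <- tryCatch(readLines(path),
                    error = function(e) stop("unreadable VCF: ",
                                             conditionMessage(e)))
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  recs <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    tibble::tibble(
      chrom = vapply(parts, `[`, character(1), 1),
      pos = as.integer(vapply(parts, `[`, character(1), 2)),
      id = vapply(parts, `[`, character(1), 3),
      ref = vapply(parts, `[`, character(1), 4),
      alt = vapply(parts, `[`, character(1), 5),
      line = body)
  } else {
    tibble::tibble(chrom = character(0), pos = integer(0), id = character(0),
                   ref = character(0), alt = character(0), line = character(0))
  }
  list(header = header, records = recs)
}

SPLICE_INFO_KEY <- "SpliceDelta"
SPLICE_INFO_HEADER <- paste0(
  '##INFO=<ID=', SPLICE_INFO_KEY, ',Number=.,Type=String,Description=',
  '"Splice delta annotation: gene|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|',
  'DP_DG|DP_DL">')

#' Annotate a VCF with splice delta scores
#'
#' For every valid variant, scores the reference and alternate sequences
#' with the scorer ensemble, computes the four delta scores and positions
#' over the `+/- distance` window, and appends them to the INFO field as
#' `gene|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`. Variants
#' failing validation are passed through unannotated; the header gains the
#' INFO declaration.
#'
#' @param vcf_in Path to the input VCF.
#' @param genome_fasta Path to the reference genome FASTA.
#' @param gff Path to the gene annotation (GFF3/GTF).
#' @param scorers Scorer or list of scorers.
#' @param distance Window radius (default 50).
#' @param vcf_out Optional output path.
#' @param biotype Biotype filter for gene intervals.
#' @return Tibble of per-record results (`chrom`, `pos`, `ref`, `alt`,
#'   `accepted`, `reason`, `gene`, the eight delta fields); the annotated
#'   VCF is written when `vcf_out` is given.
#' @export
annotate_vcf <- function(vcf_in, genome_fasta, gff, scorers, distance = 50L,
                         vcf_out = NULL, biotype = "protein-coding") {
  if (!is.list(scorers) || inherits(scorers, c("splice_scorer", "mock_scorer"))) {
    scorers <- list(scorers)
  }
  flank <- scorer_cl(scorers[[1]])
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`,
                          character(1), 1)
  loci <- filter_pseudogenes(parse_annotation(gff, biotype_filter = biotype))
  gene_ranges <- tibble::tibble(
    chrom = vapply(loci, `[[`, character(1), "chrom"),
    start = vapply(loci, `[[`, numeric(1), "start"),
    end = vapply(loci, `[[`, numeric(1), "end"),
    gene = vapply(loci, `[[`, character(1), "id"),
    strand = vapply(loci, `[[`, character(1), "strand"))

  vcf <- read_vcf_lines(vcf_in)
  out_lines <- character(0)
  rows <- list()

  score_seq <- function(seq) {
    # mean ensemble probabilities over a short sequence
    x <- encode_sequence(seq)
    acc <- NULL
    for (sc in scorers) {
      p <- forward(sc, x)
      acc <- if (is.null(acc)) p else acc + p
    }
    acc / length(scorers)
  }

  for (i in seq_len(nrow(vcf$records))) {
    r <- vcf$records[i, ]
    v <- validate_variant(r$chrom, r$pos, r$ref, r$alt, gene_ranges, genome,
                          flank = flank, distance = distance)
    ann <- NULL
    if (v$accept) {
      ba <- build_ref_alt(r$chrom, r$pos, r$ref, r$alt, genome,
                          distance = distance, flank = flank)
      # the gene's strand decides which physical strand the scorer reads;
      # minus-strand tracks are flipped back to plus orientation
      gstrand <- gene_ranges$strand[gene_ranges$gene %in% v$gene][1]
      if (!is.na(gstrand) && gstrand == "-") {
        p_ref <- score_seq(revcomp(ba$ref_seq))
        p_alt <- score_seq(revcomp(ba$alt_seq))
        p_ref <- p_ref[rev(seq_len(nrow(p_ref))), , drop = FALSE]
        p_alt <- p_alt[rev(seq_len(nrow(p_alt))), , drop = FALSE]
      } else {
        p_ref <- score_seq(ba$ref_seq)
        p_alt <- score_seq(ba$alt_seq)
      }
      n_ref_track <- 2L * distance + 1L
      a_ref <- p_ref[seq_len(n_ref_track), 2]
      d_ref <- p_ref[seq_len(n_ref_track), 3]
      a_alt <- ba$align_alt(p_alt[, 2])
      d_alt <- ba$align_alt(p_alt[, 3])
      ann <- delta_scores(a_ref, a_alt, d_ref, d_alt, offsets = ba$offsets)
    }

    rows[[i]] <- tibble::tibble(
      chrom = r$chrom, pos = r$pos, id = r$id, ref = r$ref, alt = r$alt,
      accepted = v$accept, reason = v$reason, gene = v$gene,
      DS_AG = if (is.null(ann)) NA_real_ else ann$DS_AG,
      DS_AL = if (is.null(ann)) NA_real_ else ann$DS_AL,
      DS_DG = if (is.null(ann)) NA_real_ else ann$DS_DG,
      DS_DL = if (is.null(ann)) NA_real_ else ann$DS_DL,
      DP_AG = if (is.null(ann)) NA_integer_ else ann$DP_AG,
      DP_AL = if (is.null(ann)) NA_integer_ else ann$DP_AL,
      DP_DG = if (is.null(ann)) NA_integer_ else ann$DP_DG,
      DP_DL = if (is.null(ann)) NA_integer_ else ann$DP_DL)

    if (is.null(ann)) {
      out_lines <- c(out_lines, r$line)
    } else {
      fields <- strsplit(r$line, "\t", fixed = TRUE)[[1]]
      tag <- sprintf("%s=%s|%.4f|%.4f|%.4f|%.4f|%d|%d|%d|%d",
                     SPLICE_INFO_KEY, v$gene %||% ".",
                     ann$DS_AG, ann$DS_AL, ann$DS_DG, ann$DS_DL,
                     ann$DP_AG, ann$DP_AL, ann$DP_DG, ann$DP_DL)
      info <- if (length(fields) >= 8 && !fields[8] %in% c(".", "")) {
        paste0(fields[8], ";", tag)
      } else tag
      fields[8] <- info
      if (length(fields) < 8) fields <- c(fields, rep(".", 8 - length(fields)),
                                          tag)[1:8]
      out_lines <- c(out_lines, paste(fields, collapse = "\t"))
    }
  }

  if (!is.null(vcf_out)) {
    header <- vcf$header
    chrom_line <- which(startsWith(header, "#CHROM"))
    if (length(chrom_line)) {
      header <- append(header, SPLICE_INFO_HEADER, after = chrom_line[1] - 1L)
    } else {
      header <- c(header, SPLICE_INFO_HEADER)
    }
    writeLines(c(header, out_lines), vcf_out)
  }
  if (length(rows)) do.call(rbind, rows) else tibble::tibble()
}
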