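# Genome-scale prediction: memory-bounded chunking, core-tiled windowing
# with N padding, ensemble averaging and thresholded BED emission.

#' Plan memory-bounded chunks over a long target
#'
#' Sequences longer than `split_threshold` are cut into chunks whose owned
#' 5,000-nt cores tile the target disjointly; each chunk's context span
#' extends `flank/2` into its neighbours, so consecutive chunks share
#' `flank/2` of sequence per junction and every target position is
#' reported exactly once. Context windows read real sequence across chunk
#' junctions, so predictions are independent of the threshold.
#'
#' @param target_length Length of the target sequence (nt).
#' @param split_threshold Maximum chunk length (default 1,500,000).
#' @param flank Model flanking size (= cropping length; must be even).
#' @return Tibble with `chunk`, `own_start`, `own_end`, `ctx_start`,
#'   `ctx_end` (1-based inclusive) and `overlap` (nt shared with the next
#'   chunk).
#' @export
plan_chunks <- function(target_length, split_threshold = 1500000L,
                        flank = 10000L) {
  stopifnot(flank %% 2 == 0, target_length >= 1)
  n_cores <- as.integer(ceiling(target_length / CORE_LEN))
  cores_per_chunk <- max(1L, (split_threshold - flank) %/% CORE_LEN)
  n_chunks <- as.integer(ceiling(n_cores / cores_per_chunk))
  base <- n_cores %/% n_chunks
  extra <- n_cores %% n_chunks
  counts <- rep(base, n_chunks) + c(rep(1L, extra), rep(0L, n_chunks - extra))
  ends <- cumsum(counts) * CORE_LEN
  starts <- c(0L, utils::head(ends, -1L)) + 1L
  ends <- pmin(ends, target_length)
  half <- flank %/% 2L
  tibble::tibble(
    chunk = seq_len(n_chunks),
    own_start = as.integer(starts), own_end = as.integer(ends),
    ctx_start = as.integer(pmax(starts - half, 1L)),
    ctx_end = as.integer(pmin(ends + half, target_length)),
    overlap = c(rep(half, n_chunks - 1L), 0L))
}

# Extract one prediction window (core +/- flank/2) from a target sequence,
# N-padded where the window extends past the sequence ends.
extract_window <- function(seq_chars_vec, core_start, flank) {
  half <- flank %/% 2L
  n <- length(seq_chars_vec)
  idx <- (core_start - half):(core_start + CORE_LEN - 1L + half)
  out <- rep("N", length(idx))
  ok <- idx >= 1L & idx <= n
  out[ok] <- seq_chars_vec[idx[ok]]
  out
}

#' Window a chunk into model inputs
#'
#' Tiles the span `[own_start, own_end]` of the target with disjoint
#' 5,000-nt cores; each window carries `flank/2` context per side, drawn
#' from the target sequence where available and N-padded beyond its ends
#' (including a short final core). Each window is `5000 + flank` long, so
#' a scorer with `CL = flank` returns exactly 5,000 positions per window.
#'
#' @param seq Target sequence (character string).
#' @param flank Model flanking size (even).
#' @param own_start,own_end Span to cover (default: the whole sequence).
#' @return List with `windows` (one-hot array `n_win x (5000+flank) x 4`)
#'   and `core_starts`.
#' @export
window_chunk <- function(seq, flank, own_start = 1L, own_end = nchar(seq)) {
  stopifnot(flank %% 2 == 0)
  ch <- seq_chars(seq)
  core_starts <- seq.int(own_start, own_end, by = CORE_LEN)
  win_len <- CORE_LEN + flank
  X <- array(0, dim = c(length(core_starts), win_len, 4))
  for (i in seq_along(core_starts)) {
    w <- extract_window(ch, core_starts[i], flank)
    X[i, , ] <- encode_sequence(paste(w, collapse = ""))
  }
  list(windows = X, core_starts = core_starts)
}

#' Average predictions of an ensemble of scorers
#'
#' Runs every scorer over the windows in batches and returns the
#' arithmetic mean of the member probability outputs. All members must
#' share the same cropping length; results are independent of
#' `batch_size`.
#'
#' @param windows One-hot window array (`n_win x T x 4`).
#' @param scorers A single scorer or list of scorers.
#' @param batch_size Windows per forward pass.
#' @return Probability array `n_win x (T - CL) x 3`.
#' @export
ensemble_predict <- function(windows, scorers, batch_size = 8L) {
  if (!is.list(scorers) || inherits(scorers, c("splice_scorer", "mock_scorer"))) {
    scorers <- list(scorers)
  }
  cls <- vapply(scorers, scorer_cl, integer(1))
  if (length(unique(cls)) != 1L) {
    stop("ensemble members disagree on cropping length: ",
         paste(cls, collapse = ", "))
  }
  n <- dim(windows)[1]
  t_out <- dim(windows)[2] - cls[1]
  acc <- array(0, dim = c(n, t_out, 3))
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- windows[b, , , drop = FALSE]
    for (sc in scorers) {
      out <- forward(sc, xb)
      acc[b, , ] <- acc[b, , , drop = FALSE] + out
    }
  }
  acc / length(scorers)
}

#' Predict a per-base probability track for one sequence
#'
#' Core-tiled windowed ensemble prediction over the whole sequence,
#' chunked per [plan_chunks()]; the concatenated cores are trimmed to the
#' sequence length so every position receives exactly one probability
#' triplet.
#'
#' @param seq Target sequence (character string).
#' @param scorers Scorer or list of scorers (see [ensemble_predict()]).
#' @param split_threshold Maximum chunk length.
#' @param batch_size Windows per forward pass.
#' @return `nchar(seq) x 3` probability matrix (none, acceptor, donor).
#' @export
predict_track <- function(seq, scorers, split_threshold = 1500000L,
                          batch_size = 8L) {
  if (!is.list(scorers) || inherits(scorers, c("splice_scorer", "mock_scorer"))) {
    scorers <- list(scorers)
  }
  flank <- scorer_cl(scorers[[1]])
  L <- nchar(seq)
  plan <- plan_chunks(L, split_threshold, flank)
  track <- matrix(0, nrow = 0L, ncol = 3)
  for (i in seq_len(nrow(plan))) {
    wc <- window_chunk(seq, flank, plan$own_start[i], plan$own_end[i])
    probs <- ensemble_predict(wc$windows, scorers, batch_size)
    # concatenate cores, then trim to the owned span
    flat <- matrix(aperm(probs, c(2, 1, 3)), ncol = 3)
    keep <- plan$own_end[i] - plan$own_start[i] + 1L
    track <- rbind(track, flat[seq_len(keep), , drop = FALSE])
  }
  colnames(track) <- c("none", "acceptor", "donor")
  track
}

#' Write thresholded splice-site calls as BED
#'
#' Emits one record per position whose donor (or acceptor) probability
#' strictly exceeds the threshold. Coordinates are 0-based half-open; with
#' target metadata (`chrom`, `start`, `strand`) track positions are mapped
#' back to plus-strand genomic coordinates, otherwise they are relative to
#' the sequence with position 0 the first nucleotide. The score field
#' carries the probability.
#'
#' @param track `L x 3` probability matrix from [predict_track()].
#' @param threshold Minimum probability, exclusive (default 0.5).
#' @param name Feature name stem for the BED name column.
#' @param chrom Chromosome name (default: the sequence itself).
#' @param start 1-based genomic start of the target span.
#' @param strand `"+"` or `"-"` (track is assumed sense-strand).
#' @param output_dir Optional directory; when given,
#'   `<name>_donor.bed` / `<name>_acceptor.bed` are written.
#' @return List of tibbles `donor` and `acceptor` with BED6 columns.
#' @export
write_bed <- function(track, threshold = 0.5, name = "seq", chrom = name,
                      start = 1L, strand = "+", output_dir = NULL) {
  L <- nrow(track)
  bed_for <- function(class_col, label) {
    hit <- which(track[, class_col] > threshold)
    if (length(hit) == 0) {
      return(tibble::tibble(chrom = character(0), start = integer(0),
                            end = integer(0), name = character(0),
                            score = numeric(0), strand = character(0)))
    }
    gpos0 <- if (strand == "-") {
      (start - 1L) + (L - hit) # 0-based plus-strand coordinate
    } else {
      (start - 1L) + (hit - 1L)
    }
    ord <- order(gpos0)
    tibble::tibble(
      chrom = chrom,
      start = as.integer(gpos0[ord]), end = as.integer(gpos0[ord] + 1L),
      name = paste0(name, "_", label, "_", seq_along(hit)),
      score = track[hit[ord], class_col], strand = strand)
  }
  out <- list(donor = bed_for(3L, "donor"), acceptor = bed_for(2L, "acceptor"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (side in names(out)) {
      utils::write.table(
        out[[side]], file.path(output_dir, paste0(name, "_", side, ".bed")),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  out
}

#' Genome-wide splice-site prediction to BED
#'
#' Predicts splice sites for every sequence in a FASTA file, or, when an
#' annotation is supplied, for every (protein-coding) gene locus extracted
#' from it — minus-strand genes are scored on their sense strand and calls
#' mapped back to plus-strand genomic coordinates.
#'
#' @param fasta Path to the input FASTA.
#' @param scorers Scorer or list of scorers.
#' @param gff Optional GFF3/GTF annotation restricting prediction to gene
#'   loci.
#' @param threshold BED emission threshold (exclusive, default 0.5).
#' @param split_threshold Maximum chunk length (default 1,500,000).
#' @param biotype Biotype filter when `gff` is given.
#' @param output_dir Optional directory for BED files.
#' @param batch_size Windows per forward pass.
#' @return List with `donor` and `acceptor` call tibbles (all targets
#'   combined).
#' @export
predict_genome <- function(fasta, scorers, gff = NULL, threshold = 0.5,
                           split_threshold = 1500000L,
                           biotype = "protein-coding", output_dir = NULL,
                           batch_size = 8L) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`,
                          character(1), 1)
  targets <- if (is.null(gff)) {
    lapply(names(genome), function(nm) {
      list(id = nm, chrom = nm, start = 1L, strand = "+",
           seq = toupper(as.character(genome[[nm]])))
    })
  } else {
    loci <- filter_pseudogenes(parse_annotation(gff, biotype_filter = biotype))
    lapply(loci, function(l) {
      list(id = l$id, chrom = l$chrom, start = l$start, strand = l$strand,
           seq = gene_sequence(l, genome))
    })
  }
  donor <- list(); acceptor <- list()
  for (tg in targets) {
    track <- predict_track(tg$seq, scorers, split_threshold, batch_size)
    bed <- write_bed(track, threshold = threshold, name = tg$id,
                     chrom = tg$chrom, start = tg$start, strand = tg$strand,
                     output_dir = output_dir)
    donor[[length(donor) + 1L]] <- bed$donor
    acceptor[[length(acceptor) + 1L]] <- bed$acceptor
  }
  list(donor = do.call(rbind, donor), acceptor = do.call(rbind, acceptor))
}
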