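# Internal sequence helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character string (IUPAC ambiguity -> N is
# acceptable here because downstream encoding maps unknowns to zero rows).
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Split a string into a character vector of single bases, uppercased.
seq_chars <- function(seq) {
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

#' One-hot encode a nucleotide sequence
#'
#' Encodes A, C, G and T (or U) as unit vectors `[1,0,0,0]`, `[0,1,0,0]`,
#' `[0,0,1,0]` and `[0,0,0,1]`; any other symbol (N, IUPAC ambiguity codes,
#' gap characters) becomes an all-zero row. Lowercase (soft-masked) bases are
#' uppercased first.
#'
#' @param seq A single character string over the IUPAC alphabet.
#' @return A numeric matrix of dimension `nchar(seq) x 4` with columns in
#'   A, C, G, T order.
#' @examples
#' encode_sequence("ACGTN")
#' @export
encode_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- seq_chars(chartr("Uu", "Tt", seq))
  n <- length(ch)
  m <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
  idx <- match(ch, BASES)
  hit <- which(!is.na(idx))
  if (length(hit)) m[cbind(hit, idx[hit])] <- 1
  m
}

# Decode a one-hot matrix back to characters (zero rows -> "N").
decode_onehot <- function(m) {
  idx <- max.col(m, ties.method = "first")
  idx[rowSums(m) == 0] <- NA
  out <- BASES[idx]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

# Integer label codes used internally for splice-site tracks.
LBL_NONE <- 0L
LBL_ACCEPTOR <- 1L
LBL_DONOR <- 2L

# Convert an integer label track (0 none / 1 acceptor / 2 donor, NA pad)
# to the one-hot label scheme none=[1,0,0], acceptor=[0,1,0], donor=[0,0,1],
# pad=[0,0,0].
labels_to_onehot <- function(labels) {
  n <- length(labels)
  m <- matrix(0, nrow = n, ncol = 3,
              dimnames = list(NULL, c("none", "acceptor", "donor")))
  ok <- which(!is.na(labels))
  if (length(ok)) m[cbind(ok, labels[ok] + 1L)] <- 1
  m
}

# Inverse of labels_to_onehot: all-zero rows -> NA (pad).
onehot_to_labels <- function(m) {
  lab <- max.col(m, ties.method = "first") - 1L
  lab[rowSums(m) == 0] <- NA
  lab
}

# Deterministic child seed derived from a base seed and a tag; kept well
# below .Machine$integer.max.
derive_seed <- function(seed, tag) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(tag)) * 31L) %% 2147480000L
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
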