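# Dataset archives: segmented examples packed into batch groups of up to
# 100 genes, with metadata, written via R's native serialization.

ARCHIVE_BATCH_GENES <- 100L

#' Pack segmented examples into a dataset archive
#'
#' Concatenates the segment tensors of up to 100 genes per batch group
#' (along the first dimension), recording per-gene segment counts so the
#' packing is invertible. `write_archive(read = write(x))` restores label
#' tensors bitwise and feature tensors within float tolerance.
#'
#' @param examples List of `segmented_example` objects ([segment_gene()]).
#' @param path Optional file path; when given the archive is also written
#'   there.
#' @param meta Named list of metadata (flanking size, encoding version,
#'   split description, ...).
#' @return A `dataset_archive` object.
#' @export
write_archive <- function(examples, path = NULL, meta = list()) {
  if (length(examples) == 0) stop("cannot build an archive from zero examples")
  stopifnot(all(vapply(examples, inherits, logical(1), "segmented_example")))

  n_groups <- ceiling(length(examples) / ARCHIVE_BATCH_GENES)
  groups <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1L) * ARCHIVE_BATCH_GENES + 1L):
      min(g * ARCHIVE_BATCH_GENES, length(examples))
    exs <- examples[idx]
    segs <- vapply(exs, function(e) dim(e$X)[1], integer(1))
    X <- array(0, dim = c(sum(segs), SEG_LEN, 4))
    Y <- array(0, dim = c(sum(segs), CORE_LEN, 3))
    off <- 0L
    for (e in exs) {
      k <- dim(e$X)[1]
      X[off + seq_len(k), , ] <- e$X
      Y[off + seq_len(k), , ] <- e$Y
      off <- off + k
    }
    groups[[g]] <- list(
      X = X, Y = Y,
      gene_ids = vapply(exs, `[[`, character(1), "gene_id"),
      n_segments = segs,
      gene_lengths = vapply(exs, `[[`, numeric(1), "length"))
  }
  arch <- structure(list(meta = meta, groups = groups),
                    class = "dataset_archive")
  if (!is.null(path)) write_archive_file(arch, path)
  arch
}

#' @rdname write_archive
#' @param archive A `dataset_archive`.
#' @export
write_archive_file <- function(archive, path) {
  stopifnot(inherits(archive, "dataset_archive"))
  saveRDS(archive, path)
  invisible(path)
}

#' Read a dataset archive from disk
#'
#' @param path File written by [write_archive()] /
#'   [write_archive_file()].
#' @return The `dataset_archive`.
#' @export
read_archive <- function(path) {
  arch <- tryCatch(readRDS(path),
                   error = function(e) stop("corrupt or unreadable archive: ",
                                            conditionMessage(e)))
  if (!inherits(arch, "dataset_archive")) {
    stop("corrupt archive: not a dataset_archive object")
  }
  arch
}

#' Unpack an archive into per-gene segmented examples
#'
#' @param archive A `dataset_archive`.
#' @return List of `segmented_example` objects, in archive order.
#' @export
archive_examples <- function(archive) {
  stopifnot(inherits(archive, "dataset_archive"))
  out <- list()
  for (grp in archive$groups) {
    off <- 0L
    for (i in seq_along(grp$gene_ids)) {
      k <- grp$n_segments[i]
      out[[length(out) + 1L]] <- structure(
        list(gene_id = grp$gene_ids[i],
             X = grp$X[off + seq_len(k), , , drop = FALSE],
             Y = grp$Y[off + seq_len(k), , , drop = FALSE],
             length = grp$gene_lengths[i]),
        class = "segmented_example")
      off <- off + k
    }
  }
  out
}

#' @export
print.dataset_archive <- function(x, ...) {
  n_genes <- sum(vapply(x$groups, function(g) length(g$gene_ids), integer(1)))
  n_segs <- sum(vapply(x$groups, function(g) dim(g$X)[1], integer(1)))
  cat(sprintf("<dataset_archive> %d gene(s), %d segment(s), %d batch group(s)\n",
              n_genes, n_segs, length(x$groups)))
  invisible(x)
}
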