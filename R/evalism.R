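# Evaluation metrics (top-k, thresholded precision/recall/F1, AUPRC) and
# in-silico mutagenesis: per-position importance, aggregated mutation
# logos, and profile concordance.

#' Top-k splice-site accuracy
#'
#' For each class with `n_true` annotated sites, extracts the
#' `k * n_true` highest-scoring positions (ties broken by position index)
#' and reports the fraction of them that are true sites of that class.
#'
#' @param scores `n x 3` probability (or score) matrix.
#' @param labels Integer label track (0 none, 1 acceptor, 2 donor; NA
#'   pad) or one-hot `n x 3` matrix.
#' @param k Multiplier on the true-site count (default 1).
#' @return Tibble with `class`, `k`, `n_true`, `n_examined`, `accuracy`;
#'   classes with no true sites are skipped with a warning.
#' @export
topk_accuracy <- function(scores, labels, k = 1L) {
  if (is.matrix(labels)) labels <- onehot_to_labels(labels)
  stopifnot(nrow(scores) == length(labels))
  # pad positions (NA labels) are not sequence and never rank as candidates
  keep <- which(!is.na(labels))
  scores <- scores[keep, , drop = FALSE]
  labels <- labels[keep]
  rows <- list()
  for (cl in c(LBL_ACCEPTOR, LBL_DONOR)) {
    truth <- which(labels == cl)
    if (length(truth) == 0) {
      warning("no true sites for class ", cl, "; skipped")
      next
    }
    n_top <- k * length(truth)
    ord <- order(-scores[, cl + 1L], seq_len(nrow(scores)))
    top <- ord[seq_len(min(n_top, length(ord)))]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      class = if (cl == LBL_DONOR) "donor" else "acceptor",
      k = k, n_true = length(truth), n_examined = n_top,
      accuracy = sum(top %in% truth) / n_top)
  }
  do.call(rbind, rows)
}

#' Thresholded classification metrics per class
#'
#' Calls a position positive for a class when its probability strictly
#' exceeds the threshold, then reports accuracy `(TP+TN)/total`, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1.
#' Zero-denominator metrics are reported as 0 with a warning.
#'
#' @param scores `n x 3` probability matrix.
#' @param labels Integer label track or one-hot matrix (pad excluded).
#' @param threshold Decision threshold (exclusive; default 0.5).
#' @return Tibble with one row per class (acceptor, donor) and columns
#'   `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  if (is.matrix(labels)) labels <- onehot_to_labels(labels)
  stopifnot(nrow(scores) == length(labels))
  valid <- !is.na(labels)
  rows <- list()
  for (cl in c(LBL_ACCEPTOR, LBL_DONOR)) {
    pred <- scores[valid, cl + 1L] > threshold
    truth <- labels[valid] == cl
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
    safe_div <- function(num, den, what) {
      if (den == 0) {
        warning(what, " undefined (zero denominator); reported as 0")
        0
      } else num / den
    }
    precision <- safe_div(tp, tp + fp, "precision")
    recall <- safe_div(tp, tp + fn, "recall")
    f1 <- if (precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      class = if (cl == LBL_DONOR) "donor" else "acceptor",
      tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = (tp + tn) / (tp + fp + tn + fn),
      precision = precision, recall = recall, f1 = f1)
  }
  do.call(rbind, rows)
}

#' Area under the precision-recall curve
#'
#' Step-wise area over all distinct score thresholds (the average-
#' precision formulation): `sum_t P(t) * (R(t) - R(t_prev))` with
#' thresholds descending; positions sharing a score enter together.
#'
#' @param scores Numeric score vector.
#' @param labels Logical (or 0/1) vector of true positives.
#' @return Scalar in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0) stop("AUPRC undefined without positive labels")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores so each distinct threshold contributes one PR point
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  pred_pos <- grp_end
  precision <- tp / pred_pos
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Evaluate a trained scorer on a dataset archive
#'
#' Runs the scorer over every segment of the archive and reports per-class
#' top-k accuracy plus thresholded metrics over all labeled (non-pad)
#' positions.
#'
#' @param scorer A trained `splice_scorer`.
#' @param archive A `dataset_archive`.
#' @param k Top-k multiplier (default 1).
#' @param threshold Threshold for the confusion metrics (default 0.5).
#' @return List with `topk` and `threshold` tibbles plus the pooled
#'   `scores`/`labels` matrices.
#' @export
evaluate_scorer <- function(scorer, archive, k = 1L, threshold = 0.5) {
  te <- archive_tensors(archive, scorer$config)
  out <- net_forward(scorer$params, scorer$config, te$x)
  probs <- softmax3(out$logits)
  P <- matrix(aperm(probs, c(2, 3, 1)), ncol = 3)
  Y <- matrix(aperm(te$y, c(2, 3, 1)), ncol = 3)
  list(topk = topk_accuracy(P, Y, k = k),
       threshold = threshold_metrics(P, Y, threshold = threshold),
       scores = P, labels = Y)
}

#' In-silico mutagenesis importance profile around a splice site
#'
#' For every position in a window around the site, substitutes each
#' non-reference base, rescores the site's class probability, and records
#' the score decrease. The importance at a position is
#' `S_ref - mean(S_alt)` over the three possible point mutations
#' (`average = "three"`, default); `average = "four"` divides the four
#' base scores including the reference by 4 (scaling importance by 3/4).
#' Context is drawn from the real surrounding sequence, so the site must
#' be far enough from the sequence ends to satisfy the scorer's receptive
#' field.
#'
#' @param scorer A scorer (trained or mock).
#' @param seq Sequence containing the site (character string).
#' @param site_pos 1-based position of the labeled site in `seq`.
#' @param site_type `"donor"` or `"acceptor"`.
#' @param window Radius of the mutated window (positions
#'   `site_pos +/- window`).
#' @param average `"three"` or `"four"` (see above).
#' @return An `ism_profile`: offsets, importance vector, the
#'   per-(position, substitution) decrease matrix (4 x positions; the
#'   reference base's row entry is 0), reference score and window
#'   geometry.
#' @export
ism_importance <- function(scorer, seq, site_pos, site_type = c("donor",
                                                                "acceptor"),
                           window = 40L, average = c("three", "four")) {
  site_type <- match.arg(site_type)
  average <- match.arg(average)
  cl <- scorer_cl(scorer)
  half <- cl %/% 2L
  lo <- site_pos - window - half
  hi <- site_pos + window + half
  if (lo < 1L || hi > nchar(seq)) {
    stop("site too close to the sequence end for the required context (",
         "need positions ", lo, "-", hi, ")")
  }
  sub_seq <- substr(seq, lo, hi)
  site_local <- site_pos - lo + 1L
  out_idx <- site_local - half # output row of the site
  col <- if (site_type == "donor") 3L else 2L

  score_site <- function(s) forward(scorer, encode_sequence(s))[out_idx, col]

  s_ref <- score_site(sub_seq)
  offsets <- -window:window
  decrease <- matrix(0, nrow = 4, ncol = length(offsets),
                     dimnames = list(BASES, NULL))
  ref_chars <- seq_chars(sub_seq)
  for (j in seq_along(offsets)) {
    p_local <- site_local + offsets[j]
    ref_base <- ref_chars[p_local]
    for (b in BASES) {
      if (b == ref_base) next
      mut <- sub_seq
      substr(mut, p_local, p_local) <- b
      decrease[b, j] <- s_ref - score_site(mut)
    }
  }
  importance <- if (average == "three") {
    colSums(decrease) / 3
  } else {
    colSums(decrease) / 4
  }
  structure(list(site_type = site_type, offsets = offsets,
                 importance = importance, decrease = decrease,
                 s_ref = s_ref, window = window, average = average),
            class = "ism_profile")
}

#' Aggregate mutagenesis profiles into a mean mutation-effect matrix
#'
#' Element-wise mean of the per-(position, substitution) decrease matrices
#' over many sites of the same class and window geometry; the result is a
#' position-weight-style matrix suitable for logo rendering.
#'
#' @param profiles List of `ism_profile` objects.
#' @return List with the mean `decrease` matrix, `offsets`, `site_type`
#'   and `n_sites`.
#' @export
aggregate_logo <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  geom <- vapply(profiles, function(p) {
    paste(p$site_type, p$window, length(p$offsets))
  }, character(1))
  if (length(unique(geom)) != 1L) {
    stop("profiles mix window geometries or site classes")
  }
  acc <- Reduce(`+`, lapply(profiles, `[[`, "decrease"))
  list(decrease = acc / length(profiles),
       offsets = profiles[[1]]$offsets,
       site_type = profiles[[1]]$site_type,
       n_sites = length(profiles))
}

#' Pearson correlation between two importance profiles
#'
#' @param profile_a,profile_b Equal-length numeric vectors or
#'   `ism_profile` objects.
#' @return Pearson r in `[-1, 1]`, or `NA` with a warning when either
#'   profile has zero variance.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  a <- if (inherits(profile_a, "ism_profile")) profile_a$importance
       else profile_a
  b <- if (inherits(profile_b, "ism_profile")) profile_b$importance
       else profile_b
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance profile; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Mutation-effect logo plot
#'
#' @param logo Result of [aggregate_logo()] (or an `ism_profile`).
#' @return A ggplot object: per-base mean score decrease by position.
#' @export
plot_ism_logo <- function(logo) {
  if (inherits(logo, "ism_profile")) {
    logo <- list(decrease = logo$decrease, offsets = logo$offsets,
                 site_type = logo$site_type, n_sites = 1L)
  }
  df <- data.frame(
    offset = rep(logo$offsets, each = 4),
    base = rep(BASES, times = length(logo$offsets)),
    decrease = as.vector(logo$decrease))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$decrease,
                                   fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = sprintf("offset from %s site (nt)", logo$site_type),
                  y = "mean score decrease", fill = NULL) +
    ggplot2::theme_minimal()
}
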