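# Class-wise temperature scaling of scorer logits, with NLL/ECE
# diagnostics and reliability curves with binomial confidence intervals.

TEMP_BOUNDS <- c(0.05, 5.0)

#' Scale logits by per-class temperatures
#'
#' Divides each logit column by its class temperature before the softmax:
#' temperatures above 1 soften the predicted distribution, below 1 sharpen
#' it. Within a class, division by a positive constant preserves the
#' ranking of positions by that class's probability.
#'
#' @param z Logit rows (`n x 3` matrix).
#' @param temperature Numeric length-3 vector `[T_none, T_acceptor,
#'   T_donor]` or a `temperature_vector`.
#' @return Scaled logits, same shape as `z`.
#' @export
scale_logits <- function(z, temperature) {
  Tv <- if (inherits(temperature, "temperature_vector")) temperature$T
        else temperature
  stopifnot(length(Tv) == 3)
  if (any(Tv <= 0)) stop("temperatures must be positive")
  sweep(as_rows3(z), 2, Tv, "/")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Negative log-likelihood of probability rows
#'
#' Mean cross-entropy over non-pad positions; shares the training loss
#' implementation with `kind = "cross_entropy"`.
#'
#' @param probs Probability rows (`n x 3`).
#' @param labels One-hot label rows; pad rows (all zero) are excluded.
#' @return Non-negative scalar.
#' @export
nll <- function(probs, labels) {
  splice_loss(probs, labels, loss_spec("cross_entropy"))
}

#' Fit per-class temperatures on validation logits
#'
#' Full-batch gradient-based minimization (Adam, initial learning rate
#' 0.01) of the validation NLL over `T = [T0, T1, T2]`, initialized at 1
#' and constrained to `[0.05, 5]`. The learning rate is reduced by a
#' factor of 0.1 when the loss fails to improve over two consecutive
#' iterations, and optimization early-stops when the improvement falls
#' below 1e-6 over two iterations. The scorer itself is untouched: only
#' its logits are rescaled.
#'
#' @param logits Validation logit rows (`n x 3`).
#' @param labels One-hot label rows aligned with `logits`.
#' @param max_iter Iteration cap.
#' @param lr Initial learning rate.
#' @param min_delta Minimum improvement counted as progress.
#' @param patience Plateau length (epochs) before reducing the rate /
#'   stopping; one epoch of full-batch optimization is `eval_every`
#'   Adam iterations.
#' @param eval_every Iterations per convergence check.
#' @return A `temperature_vector`: fitted `T`, iteration count and NLL
#'   before/after.
#' @export
fit_temperature <- function(logits, labels, max_iter = 3000L, lr = 0.01,
                            min_delta = 1e-6, patience = 2L,
                            eval_every = 25L) {
  z <- as_rows3(logits)
  Y <- as_rows3(labels)
  valid <- rowSums(Y) > 0
  z <- z[valid, , drop = FALSE]
  Y <- Y[valid, , drop = FALSE]
  n <- nrow(z)
  if (n == 0) stop("no labeled positions to calibrate on")

  present <- colSums(Y) > 0
  if (!all(present)) {
    warning("class(es) absent from labels: temperature(s) left at 1 for ",
            paste(which(!present) - 1L, collapse = ", "))
  }

  nll_of <- function(Tv) {
    p <- softmax_rows(sweep(z, 2, Tv, "/"))
    nll(p, Y)
  }

  Tv <- rep(1, 3)
  nll_before <- nll_of(Tv)
  m <- numeric(3); v <- numeric(3)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best <- nll_before
  best_T <- Tv
  epoch_best <- nll_before
  plateau <- 0L
  iter <- 0L
  cur_lr <- lr

  while (iter < max_iter) {
    iter <- iter + 1L
    zs <- sweep(z, 2, Tv, "/")
    p <- softmax_rows(zs)
    # d NLL / d T_c = -(1/n) sum_i (p_ic - y_ic) * z_ic / T_c^2
    grad <- -colSums((p - Y) * z) / (n * Tv^2)
    grad[!present] <- 0
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    mhat <- m / (1 - beta1^iter)
    vhat <- v / (1 - beta2^iter)
    Tv <- Tv - cur_lr * mhat / (sqrt(vhat) + eps)
    Tv <- pmin(pmax(Tv, TEMP_BOUNDS[1]), TEMP_BOUNDS[2])
    cur <- nll_of(Tv)
    if (cur < best) {
      best <- cur
      best_T <- Tv
    }
    # convergence is judged per epoch of full-batch steps, not per step
    if (iter %% eval_every == 0L) {
      if (epoch_best - best < min_delta) {
        plateau <- plateau + 1L
        # a plateau of `patience` epochs reduces the rate by 0.1; a
        # second such plateau at the reduced rate stops optimization
        if (plateau == patience) cur_lr <- cur_lr * 0.1
        if (plateau >= 2L * patience || cur_lr < 1e-7) break
      } else {
        plateau <- 0L
      }
      epoch_best <- best
    }
  }
  Tv <- best_T

  structure(list(T = Tv, bounds = TEMP_BOUNDS, iterations = iter,
                 nll_before = nll_before, nll_after = nll_of(Tv)),
            class = "temperature_vector")
}

#' @export
print.temperature_vector <- function(x, ...) {
  cat(sprintf(
    "<temperature_vector> T=[%.3f, %.3f, %.3f] NLL %.4f -> %.4f (%d iters)\n",
    x$T[1], x$T[2], x$T[3], x$nll_before, x$nll_after, x$iterations))
  invisible(x)
}

# Confidence (max probability) and correctness per labeled position.
conf_correct <- function(probs, labels) {
  P <- as_rows3(probs)
  Y <- as_rows3(labels)
  valid <- rowSums(Y) > 0
  P <- P[valid, , drop = FALSE]
  Y <- Y[valid, , drop = FALSE]
  pred <- max.col(P, ties.method = "first")
  list(conf = P[cbind(seq_len(nrow(P)), pred)],
       correct = Y[cbind(seq_len(nrow(P)), pred)] == 1)
}

# Right-closed uniform bin index on [0, 1].
bin_index <- function(x, M) pmin(pmax(ceiling(x * M), 1L), M)

#' Expected calibration error
#'
#' Partitions predictions into `M` uniform-width confidence bins
#' (right-closed) and returns the bin-weighted mean absolute gap between
#' within-bin accuracy and within-bin confidence. 0 means perfectly
#' calibrated; the value always lies in `[0, 1]`.
#'
#' @param probs Probability rows (`n x 3`).
#' @param labels One-hot label rows; pad rows are excluded.
#' @param M Number of bins (default 30).
#' @return Scalar ECE.
#' @export
ece <- function(probs, labels, M = 30L) {
  cc <- conf_correct(probs, labels)
  N <- length(cc$conf)
  if (N == 0) stop("no labeled positions to evaluate")
  bins <- bin_index(cc$conf, M)
  out <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    out <- out + sum(idx) / N * abs(mean(cc$correct[idx]) - mean(cc$conf[idx]))
  }
  out
}

#' Reliability curve for one class with binomial confidence intervals
#'
#' One-vs-rest binarization of the chosen class; the predicted probability
#' of that class is binned into `M` uniform bins and the empirical
#' positive frequency per bin is reported with a normal-approximation 95%
#' interval (`SE = sqrt(p(1-p)/n)`, `z = 1.96`, bounds clamped to
#' `[0, 1]`). Empty bins are omitted.
#'
#' @param probs Probability rows (`n x 3`).
#' @param labels One-hot label rows.
#' @param class Class index: 0 none, 1 acceptor, 2 donor.
#' @param M Number of bins (default 30).
#' @param z Normal quantile (default 1.96 for 95%).
#' @return Tibble with `bin`, `conf`, `acc`, `n`, `se`, `ci_lower`,
#'   `ci_upper`.
#' @export
reliability_curve <- function(probs, labels, class, M = 30L, z = 1.96) {
  stopifnot(class %in% 0:2)
  P <- as_rows3(probs)
  Y <- as_rows3(labels)
  valid <- rowSums(Y) > 0
  p_class <- P[valid, class + 1L]
  y_class <- Y[valid, class + 1L] == 1
  bins <- bin_index(p_class, M)
  rows <- lapply(sort(unique(bins)), function(b) {
    idx <- bins == b
    n <- sum(idx)
    phat <- mean(y_class[idx])
    se <- sqrt(phat * (1 - phat) / n)
    tibble::tibble(bin = b, conf = mean(p_class[idx]), acc = phat, n = n,
                   se = se,
                   ci_lower = max(phat - z * se, 0),
                   ci_upper = min(phat + z * se, 1))
  })
  do.call(rbind, rows)
}

#' Calibrate a trained scorer by class-wise temperature scaling
#'
#' Runs the scorer over a calibration archive (typically the validation
#' split of training), fits the temperature vector on the resulting logits
#' and returns a report with NLL and ECE before/after plus per-class
#' reliability curves.
#'
#' @param scorer A trained `splice_scorer`.
#' @param archive Calibration `dataset_archive`.
#' @param bins Number of ECE/reliability bins (default 30).
#' @return A `calibration_report`.
#' @export
calibrate_scorer <- function(scorer, archive, bins = 30L) {
  te <- archive_tensors(archive, scorer$config)
  out <- net_forward(scorer$params, scorer$config, te$x)
  logits <- t(matrix(out$logits, 3))
  labels <- t(matrix(te$y, 3))
  tv <- fit_temperature(logits, labels)
  p_before <- softmax_rows(logits)
  p_after <- softmax_rows(scale_logits(logits, tv))
  argmax_changed <- sum(max.col(p_before, ties.method = "first") !=
                          max.col(p_after, ties.method = "first"))
  rel <- lapply(0:2, function(cl) {
    cbind(class = cl, reliability_curve(p_after, labels, cl, M = bins))
  })
  structure(list(
    temperature = tv,
    nll_before = nll(p_before, labels), nll_after = nll(p_after, labels),
    ece_before = ece(p_before, labels, bins),
    ece_after = ece(p_after, labels, bins),
    bins = bins, n = sum(rowSums(labels) > 0),
    argmax_changed = argmax_changed,
    reliability = do.call(rbind, rel)),
    class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<calibration_report> T=[%.3f, %.3f, %.3f]\n",
    "  NLL %.4f -> %.4f   ECE %.4f -> %.4f   (%d positions, %d bins)\n"),
    x$temperature$T[1], x$temperature$T[2], x$temperature$T[3],
    x$nll_before, x$nll_after, x$ece_before, x$ece_after, x$n, x$bins))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.calibration_report <- function(x, ...) x$reliability

#' @rdname glance
#' @export
glance.calibration_report <- function(x, ...) {
  tibble::tibble(T0 = x$temperature$T[1], T1 = x$temperature$T[2],
                 T2 = x$temperature$T[3],
                 nll_before = x$nll_before, nll_after = x$nll_after,
                 ece_before = x$ece_before, ece_after = x$ece_after,
                 argmax_changed = x$argmax_changed, n = x$n)
}

#' Reliability diagram
#'
#' @param report A `calibration_report`.
#' @return A ggplot object: per-class reliability curves with 95%
#'   confidence ribbons against the identity diagonal.
#' @export
plot_reliability <- function(report) {
  df <- report$reliability
  df$class <- factor(df$class, levels = 0:2,
                     labels = c("none", "acceptor", "donor"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conf, y = .data$acc)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper), alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "mean predicted probability",
                  y = "empirical frequency") +
    ggplot2::theme_minimal()
}
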