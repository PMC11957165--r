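# Training: losses, learning-rate schedules, validation split, the training
# loop and transfer-learning initialization.

#' Loss specification
#'
#' @param kind `"cross_entropy"` (default) or `"focal"`.
#' @param gamma Focusing exponent for the focal loss (default 2); the focal
#'   loss with `gamma = 0` equals cross-entropy.
#' @return A `loss_spec` list.
#' @export
loss_spec <- function(kind = c("cross_entropy", "focal"), gamma = 2) {
  kind <- match.arg(kind)
  stopifnot(gamma >= 0)
  structure(list(kind = kind, gamma = if (kind == "focal") gamma else 0),
            class = "loss_spec")
}

LOSS_EPS <- 1e-10

# Flatten (prob, label) inputs to aligned n x 3 matrices.
as_rows3 <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 3) return(matrix(aperm(x, c(2, 1, 3)), ncol = d[3]))
  stop("expected a matrix or 3-d array with 3 trailing channels")
}

#' Per-position classification loss
#'
#' Mean over non-pad positions of `-sum_class I * (1-P)^gamma * log(P)`
#' (cross-entropy when `gamma = 0`). Pad rows (all-zero labels) contribute
#' nothing; probabilities are clamped at 1e-10 inside the log.
#'
#' @param probs Probability rows (`n x 3` matrix or batch array).
#' @param labels One-hot label rows of the same shape; pad = `[0,0,0]`.
#' @param spec A [loss_spec()].
#' @return Non-negative scalar.
#' @export
splice_loss <- function(probs, labels, spec = loss_spec()) {
  P <- as_rows3(probs)
  Y <- as_rows3(labels)
  stopifnot(nrow(P) == nrow(Y))
  valid <- rowSums(Y) > 0
  if (!any(valid)) return(0)
  pt <- pmax(rowSums(P * Y)[valid], LOSS_EPS)
  mean(-(1 - pt)^spec$gamma * log(pt))
}

# Gradient of splice_loss wrt logits, as (3, T, N) matching a logits array.
loss_grad_logits <- function(probs3, labels3, spec) {
  d <- dim(probs3)
  P <- matrix(probs3, d[1])
  Y <- matrix(labels3, d[1])
  valid <- colSums(Y) > 0
  n_valid <- sum(valid)
  if (n_valid == 0) return(array(0, d))
  pt <- pmax(colSums(P * Y), LOSS_EPS)
  g <- spec$gamma
  # d/dpt of -(1-pt)^g log(pt), then chain through softmax
  gfac <- g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) - (1 - pt)^g / pt
  gfac[!valid] <- 0
  dz <- (Y - P) * rep(gfac * pt, each = d[1]) / n_valid
  array(dz, d)
}

#' Learning-rate schedule
#'
#' `"multistep"`: constant 1e-3 for epochs 1-5, halved at epoch 6 and
#' again at each subsequent epoch. `"cosine"`: cosine decay from 1e-3 to
#' `eta_min = 1e-5` with warm restarts of period `t0 = 5` epochs.
#'
#' @param epoch Epoch number (1-based).
#' @param kind `"multistep"` or `"cosine"`.
#' @param lr0 Initial learning rate.
#' @param eta_min Cosine floor.
#' @param decay_start First epoch of multistep decay.
#' @param t0 Cosine restart period in epochs.
#' @return The learning rate for that epoch.
#' @export
schedule <- function(epoch, kind = c("multistep", "cosine"), lr0 = 1e-3,
                     eta_min = 1e-5, decay_start = 6L, t0 = 5L) {
  stopifnot(epoch >= 1)
  kind <- match.arg(kind)
  if (kind == "multistep") {
    lr0 * 0.5^max(0L, epoch - decay_start + 1L)
  } else {
    t_cur <- (epoch - 1) %% t0
    eta_min + (lr0 - eta_min) * (1 + cos(pi * t_cur / t0)) / 2
  }
}

#' Split an archive into training and validation parts
#'
#' Gene-level, seeded, disjoint split; the validation part receives
#' `max(1, floor(fraction * n))` genes.
#'
#' @param archive A `dataset_archive`.
#' @param fraction Validation fraction (default 0.1, the 90:10 convention).
#' @param seed Split seed.
#' @return List with `train` and `validation` archives.
#' @export
split_validation <- function(archive, fraction = 0.1, seed = 10) {
  examples <- archive_examples(archive)
  n <- length(examples)
  if (n < 2) stop("too few genes (", n, ") to split off a validation set")
  n_val <- max(1L, floor(fraction * n))
  val_idx <- with_seed(seed, sample.int(n, n_val))
  list(train = write_archive(examples[-val_idx], meta = archive$meta),
       validation = write_archive(examples[val_idx], meta = archive$meta))
}

# Stack an archive into model-ready tensors for a given configuration:
# the 15,000-nt stored windows are trimmed to a 5,000-nt core plus CL/2
# context per side. Returns x (4, 5000+CL, N) and y (3, 5000, N).
archive_tensors <- function(archive, config) {
  CL <- config$CL
  if (CL > 2L * CTX_LEN) {
    stop("model flank ", CL, " exceeds the archive context ", 2L * CTX_LEN)
  }
  half <- CL %/% 2L
  cols <- (CTX_LEN - half + 1L):(CTX_LEN + CORE_LEN + half)
  xs <- list(); ys <- list()
  for (grp in archive$groups) {
    xs[[length(xs) + 1L]] <- grp$X[, cols, , drop = FALSE]
    ys[[length(ys) + 1L]] <- grp$Y
  }
  n_seg <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  Tlen <- length(cols)
  x <- array(0, c(4, Tlen, n_seg))
  y <- array(0, c(3, CORE_LEN, n_seg))
  off <- 0L
  for (g in seq_along(xs)) {
    k <- dim(xs[[g]])[1]
    x[, , off + seq_len(k)] <- aperm(xs[[g]], c(3, 2, 1))
    y[, , off + seq_len(k)] <- aperm(ys[[g]], c(3, 2, 1))
    off <- off + k
  }
  list(x = x, y = y)
}

#' Train a splice-site scorer
#'
#' AdamW (lr 1e-3, decoupled weight decay) with the chosen loss and
#' learning-rate schedule; a seeded 90:10 gene-level validation split;
#' early stopping when the validation loss fails to improve for `patience`
#' consecutive epochs; the best-validation parameters are retained.
#'
#' @param archive Training `dataset_archive`.
#' @param config A [splice_config()]; its `CL` must not exceed the archive
#'   context.
#' @param loss A [loss_spec()].
#' @param scheduler `"multistep"` or `"cosine"`.
#' @param epochs Maximum epochs (default 10).
#' @param patience Early-stopping patience in epochs (default 2, counting
#'   epochs without any improvement).
#' @param seed Seed controlling initialization, the validation split and
#'   shuffling.
#' @param batch_size Segments per optimization step.
#' @param val_fraction Validation fraction of the training genes.
#' @param scorer Optional pre-initialized scorer (e.g. from
#'   [transfer_init()]); frozen groups are not updated.
#' @param weight_decay AdamW decoupled weight decay.
#' @return A `splice_fit`: list with the trained `scorer` and per-epoch
#'   `logs` tibble.
#' @export
train_loop <- function(archive, config, loss = loss_spec(),
                       scheduler = c("multistep", "cosine"), epochs = 10L,
                       patience = 2L, seed = 10, batch_size = 16L,
                       val_fraction = 0.1, scorer = NULL,
                       weight_decay = 0.01) {
  scheduler <- match.arg(scheduler)
  if (is.null(scorer)) scorer <- build_scorer(config, seed = seed)
  bad <- config_matches(scorer$config, config)
  if (!is.null(bad)) stop("scorer/config mismatch in field '", bad, "'")

  sp <- split_validation(archive, fraction = val_fraction,
                         seed = derive_seed(seed, "valsplit"))
  tr <- archive_tensors(sp$train, config)
  va <- archive_tensors(sp$validation, config)

  params <- scorer$params
  state <- new_adamw_state(flatten_params(params))
  n <- dim(tr$x)[3]
  logs <- list()
  best_val <- Inf
  best_params <- params
  bad_epochs <- 0L
  stopped_early <- FALSE

  val_loss_of <- function(params) {
    out <- net_forward(params, config, va$x)
    splice_loss(aperm(softmax3(out$logits), c(3, 2, 1)),
                aperm(va$y, c(3, 2, 1)), loss)
  }

  for (epoch in seq_len(epochs)) {
    lr <- schedule(epoch, scheduler)
    ord <- with_seed(derive_seed(seed, paste0("epoch", epoch)),
                     sample.int(n))
    epoch_loss <- 0
    n_batches <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      xb <- tr$x[, , b, drop = FALSE]
      yb <- tr$y[, , b, drop = FALSE]
      out <- net_forward(params, config, xb, training = TRUE,
                         want_cache = TRUE)
      params <- out$params # updated BN running stats
      probs <- softmax3(out$logits)
      l <- splice_loss(aperm(probs, c(3, 2, 1)), aperm(yb, c(3, 2, 1)), loss)
      if (!is.finite(l)) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      dlogits <- loss_grad_logits(probs, yb, loss)
      grads <- net_backward(params, config, out$cache, dlogits)
      st <- adamw_step(params, grads, state, lr,
                       trainable = scorer$trainable,
                       weight_decay = weight_decay)
      params <- st$params
      state <- st$state
      epoch_loss <- epoch_loss + l
      n_batches <- n_batches + 1L
    }
    train_loss <- epoch_loss / n_batches
    val_loss <- val_loss_of(params)
    logs[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                    train_loss = train_loss,
                                    val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- params
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= patience) {
        stopped_early <- TRUE
        break
      }
    }
  }

  scorer$params <- best_params
  scorer$meta$trained <- TRUE
  scorer$meta$seed <- seed
  scorer$meta$best_val_loss <- best_val
  structure(list(scorer = scorer, logs = do.call(rbind, logs),
                 best_val_loss = best_val, stopped_early = stopped_early,
                 validation = sp$validation),
            class = "splice_fit")
}

#' Initialize a scorer for transfer learning
#'
#' Copies parameters from a pretrained checkpoint into a scorer whose
#' configuration must match exactly, then marks parameter groups trainable
#' according to the policy: `"unfreeze_all"` trains everything;
#' `"unfreeze_last_k"` trains only the last `k` groups in forward order
#' (so `k = 1` trains just the final 3-channel convolution). Frozen
#' groups are bit-identical after any amount of training.
#'
#' @param pretrained A `splice_scorer` or path to a checkpoint file.
#' @param config Target [splice_config()].
#' @param policy `"unfreeze_all"` or `"unfreeze_last_k"`.
#' @param k Number of trailing groups to unfreeze.
#' @return A `splice_scorer` with its `trainable` mask set.
#' @export
transfer_init <- function(pretrained, config,
                          policy = c("unfreeze_all", "unfreeze_last_k"),
                          k = 1L) {
  policy <- match.arg(policy)
  scorer <- if (is.character(pretrained)) {
    load_checkpoint(pretrained, config = config)
  } else {
    bad <- config_matches(pretrained$config, config)
    if (!is.null(bad)) stop("pretrained configuration mismatch in field '",
                            bad, "'")
    pretrained
  }
  groups <- names(scorer$params)
  mask <- stats::setNames(as.list(rep(TRUE, length(groups))), groups)
  if (policy == "unfreeze_last_k") {
    stopifnot(k >= 1, k <= length(groups))
    frozen <- groups[seq_len(length(groups) - k)]
    for (g in frozen) mask[[g]] <- FALSE
  }
  scorer$trainable <- mask
  scorer$meta$transfer_policy <- policy
  scorer
}

#' @export
print.splice_fit <- function(x, ...) {
  cat(sprintf("<splice_fit> %d epoch(s), best validation loss %.4g%s\n",
              nrow(x$logs), x$best_val_loss,
              if (x$stopped_early) " (stopped early)" else ""))
  invisible(x)
}

#' Tidy per-epoch training logs
#' @param x A `splice_fit`.
#' @param ... Unused.
#' @return Tibble with epoch, lr, train_loss, val_loss.
#' @export
tidy.splice_fit <- function(x, ...) x$logs

#' One-row training summary
#' @param x A `splice_fit`.
#' @param ... Unused.
#' @export
glance.splice_fit <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$logs),
                 best_val_loss = x$best_val_loss,
                 stopped_early = x$stopped_early)
}

#' Turn a fitted object into a tidy tibble
#' @param x A fitted object.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a fitted object
#' @param x A fitted object.
#' @param ... Method arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
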