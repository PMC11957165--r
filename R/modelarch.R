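# Model architecture: configuration, construction and the forward pass of
# the dilated residual convolutional splice-site scorer.

MODEL_PRESETS <- list(
  `80` = list(W = rep(11L, 4), AR = rep(1L, 4)),
  `400` = list(W = rep(11L, 8), AR = c(rep(1L, 4), rep(4L, 4))),
  `2000` = list(W = c(rep(11L, 8), rep(21L, 4)),
                AR = c(rep(1L, 4), rep(4L, 4), rep(10L, 4))),
  `10000` = list(W = c(rep(11L, 8), rep(21L, 4), rep(41L, 4)),
                 AR = c(rep(1L, 4), rep(4L, 4), rep(10L, 4), rep(25L, 4))))

#' Cropping length of a dilated convolutional stack
#'
#' The network's output is shorter than its input by the total receptive
#' margin `CL = 2 * sum(AR * (W - 1))`, removed as `CL/2` positions from
#' each end. For the four named configurations (flanking 80, 400, 2,000
#' and 10,000 nt) `CL` equals the flanking size.
#'
#' @param W Integer vector of kernel widths, one per residual unit.
#' @param AR Integer vector of dilation rates, same length as `W`.
#' @return The cropping length (always even).
#' @examples
#' compute_cropping(rep(11, 4), rep(1, 4)) # 80
#' @export
compute_cropping <- function(W, AR) {
  if (length(W) != length(AR)) {
    stop("W and AR must have the same length (got ", length(W), " and ",
         length(AR), ")")
  }
  stopifnot(all(W >= 1), all(AR >= 1))
  as.integer(2 * sum(AR * (W - 1)))
}

#' Model configuration
#'
#' Builds a scorer configuration either from one of the four named flanking
#' sizes (80, 400, 2,000, 10,000 nt) or from explicit kernel-width and
#' dilation vectors. Each residual unit applies its `W`/`AR` entry to both
#' of its convolutions; a skip-merge convolution follows every
#' `skip_every`-th unit.
#'
#' @param flank One of 80, 400, 2000, 10000 to use a preset, or `NULL` with
#'   explicit `W`/`AR`.
#' @param W,AR Kernel widths and dilation rates (ignored when `flank` names
#'   a preset).
#' @param channels Feature channels `L` throughout the trunk (default 32).
#' @param skip_every Residual units per skip merge (default 4; `length(W)`
#'   must be a positive multiple of it).
#' @return A `model_config` list with derived `CL`.
#' @export
splice_config <- function(flank = NULL, W = NULL, AR = NULL, channels = 32L,
                          skip_every = 4L) {
  if (!is.null(flank) && as.character(flank) %in% names(MODEL_PRESETS)) {
    preset <- MODEL_PRESETS[[as.character(flank)]]
    W <- preset$W
    AR <- preset$AR
  }
  if (is.null(W) || is.null(AR)) {
    stop("provide a preset flank (80/400/2000/10000) or explicit W and AR")
  }
  CL <- compute_cropping(W, AR)
  if (length(W) %% skip_every != 0L || length(W) < skip_every) {
    stop("number of residual units (", length(W), ") must be a positive ",
         "multiple of skip_every (", skip_every, ")")
  }
  structure(list(W = as.integer(W), AR = as.integer(AR),
                 channels = as.integer(channels),
                 skip_every = as.integer(skip_every), CL = CL),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %d residual units, %d skip merge(s), L=%d, CL=%d\n",
              length(x$W), length(x$W) %/% x$skip_every, x$channels, x$CL))
  invisible(x)
}

config_matches <- function(a, b) {
  for (field in c("W", "AR", "channels", "skip_every", "CL")) {
    if (!identical(as.integer(a[[field]]), as.integer(b[[field]]))) {
      return(field)
    }
  }
  NULL
}

#' Build an untrained splice-site scorer
#'
#' Instantiates the dilated residual convolutional network: an initial 1x1
#' convolution (4 -> L channels), one residual unit per `W` entry (each:
#' batch norm, LeakyReLU alpha = 0.1, dilated convolution, twice), a skip
#' path merged by 1x1 convolutions after every `skip_every`-th unit, a
#' trailing crop of `CL/2` per side, and a final 1x1 convolution to the
#' three class channels followed by a per-position softmax.
#'
#' @param config A [splice_config()].
#' @param seed Seed for weight initialization.
#' @return A `splice_scorer`.
#' @export
build_scorer <- function(config, seed = 10) {
  stopifnot(inherits(config, "model_config"))
  L <- config$channels
  params <- with_seed(seed, {
    p <- list(conv_in = init_conv(L, 4L, 1L), skip_in = init_conv(L, L, 1L))
    for (i in seq_along(config$W)) {
      p[[unit_name(i)]] <- list(
        bn1 = init_bn(L),
        conv1 = init_conv(L, L, config$W[i]),
        bn2 = init_bn(L),
        conv2 = init_conv(L, L, config$W[i]))
    }
    for (k in seq_len(length(config$W) %/% config$skip_every)) {
      p[[skip_name(k)]] <- init_conv(L, L, 1L)
    }
    p$conv_out <- init_conv(3L, L, 1L)
    p
  })
  trainable <- stats::setNames(rep(TRUE, length(params)), names(params))
  structure(list(config = config, params = params, seed = as.integer(seed),
                 trainable = as.list(trainable),
                 meta = list(trained = FALSE)),
            class = "splice_scorer")
}

#' Number of residual units and skip merges of a scorer
#' @param scorer A `splice_scorer`.
#' @return List with `residual_units` and `skip_connections`.
#' @export
architecture_census <- function(scorer) {
  cfg <- if (inherits(scorer, "model_config")) scorer else scorer$config
  list(residual_units = length(cfg$W),
       skip_connections = length(cfg$W) %/% cfg$skip_every)
}

#' Score a one-hot sequence with a splice-site scorer
#'
#' Generic forward pass shared by trained scorers and the fixture mock
#' scorer: input of length `n > CL` yields one probability simplex over
#' \{none, acceptor, donor\} per position `CL/2 + 1 ... n - CL/2` (output
#' length `n - CL`).
#'
#' @param scorer A `splice_scorer` or `mock_scorer`.
#' @param x One-hot matrix (`n x 4`) or batch array (`N x n x 4`).
#' @param ... Method arguments.
#' @return Probability matrix (`(n-CL) x 3`) or array (`N x (n-CL) x 3`);
#'   with `type = "logit"` the raw logits.
#' @export
forward <- function(scorer, x, ...) UseMethod("forward")

#' @rdname forward
#' @param type `"prob"` (default) or `"logit"`.
#' @param training Use batch statistics in normalization layers (internal;
#'   inference uses running statistics so the forward pass is
#'   deterministic).
#' @export
forward.splice_scorer <- function(scorer, x, type = c("prob", "logit"),
                                  training = FALSE, ...) {
  type <- match.arg(type)
  single <- is.matrix(x)
  xb <- if (single) array(x, c(1L, nrow(x), ncol(x))) else x
  stopifnot(length(dim(xb)) == 3, dim(xb)[3] == 4)
  xi <- aperm(xb, c(3, 2, 1)) # (4, T, N)
  out <- net_forward(scorer$params, scorer$config, xi, training = FALSE)
  res <- if (type == "prob") softmax3(out$logits) else out$logits
  res <- aperm(res, c(3, 2, 1)) # (N, T-CL, 3)
  if (single) res[1, , , drop = TRUE] else res
}

#' Cropping length of any scorer
#' @param scorer A scorer object.
#' @return Integer cropping length.
#' @export
scorer_cl <- function(scorer) UseMethod("scorer_cl")

#' @export
scorer_cl.splice_scorer <- function(scorer) scorer$config$CL

#' Save a scorer checkpoint
#'
#' The checkpoint stores parameters, the full configuration and the
#' training seed; [load_checkpoint()] refuses to load it into a mismatched
#' configuration, naming the differing field.
#'
#' @param scorer A `splice_scorer`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(scorer, path) {
  stopifnot(inherits(scorer, "splice_scorer"))
  saveRDS(list(params = scorer$params, config = scorer$config,
               seed = scorer$seed, meta = scorer$meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config Optional expected configuration to validate against.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!is.null(config)) {
    bad <- config_matches(ck$config, config)
    if (!is.null(bad)) {
      stop("checkpoint configuration mismatch in field '", bad, "'")
    }
  }
  trainable <- stats::setNames(rep(TRUE, length(ck$params)), names(ck$params))
  structure(list(config = ck$config, params = ck$params, seed = ck$seed,
                 trainable = as.list(trainable), meta = ck$meta),
            class = "splice_scorer")
}

#' @export
print.splice_scorer <- function(x, ...) {
  cen <- architecture_census(x)
  cat(sprintf(
    "<splice_scorer> CL=%d, %d residual units, %d skip merge(s), L=%d%s\n",
    x$config$CL, cen$residual_units, cen$skip_connections,
    x$config$channels, if (isTRUE(x$meta$trained)) " (trained)" else ""))
  invisible(x)
}
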