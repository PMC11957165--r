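# Internal neural-network primitives. Tensors are arrays of shape
# (channels, positions, batch); convolutions are expressed as sums of
# shifted BLAS matrix products so everything runs on base R.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
LRELU_ALPHA <- 0.1

# y[, t, ] = x[, t + o, ], zero-filled outside range.
shift3 <- function(x, o) {
  if (o == 0) return(x)
  d <- dim(x)
  y <- array(0, d)
  T <- d[2]
  if (abs(o) >= T) return(y)
  if (o > 0) {
    y[, seq_len(T - o), ] <- x[, (o + 1):T, ]
  } else {
    y[, (1 - o):T, ] <- x[, seq_len(T + o), ]
  }
  y
}

# Dilated 1D convolution, 'same' zero padding. W: (C_out, C_in, w).
conv1d_fwd <- function(x, W, b, dilation = 1L) {
  d <- dim(x)
  w <- dim(W)[3]
  center <- (w + 1L) %/% 2L
  TN <- d[2] * d[3]
  ym <- matrix(0, dim(W)[1], TN)
  for (k in seq_len(w)) {
    o <- (k - center) * dilation
    xs <- if (o == 0) x else shift3(x, o)
    ym <- ym + W[, , k, drop = TRUE] %*% matrix(xs, d[1], TN)
  }
  ym <- ym + b
  array(ym, c(dim(W)[1], d[2], d[3]))
}

# Backward pass of conv1d_fwd. Returns gradients wrt input, W and b.
conv1d_bwd <- function(dout, x, W, dilation = 1L) {
  d <- dim(x)
  w <- dim(W)[3]
  center <- (w + 1L) %/% 2L
  TN <- d[2] * d[3]
  dout_m <- matrix(dout, dim(W)[1], TN)
  dW <- array(0, dim(W))
  dx <- array(0, d)
  for (k in seq_len(w)) {
    o <- (k - center) * dilation
    xs <- if (o == 0) x else shift3(x, o)
    dW[, , k] <- dout_m %*% t(matrix(xs, d[1], TN))
    back <- array(t(W[, , k, drop = TRUE]) %*% dout_m, d)
    dx <- dx + (if (o == 0) back else shift3(back, -o))
  }
  list(dx = dx, dW = dW, db = rowSums(dout_m))
}

bn_fwd <- function(x, bn, training = FALSE) {
  if (training) {
    mu <- rowMeans(x, dims = 1)
    v <- rowMeans(x * x, dims = 1) - mu^2
    inv_std <- 1 / sqrt(v + BN_EPS)
    xhat <- (x - mu) * inv_std
    bn$rm <- (1 - BN_MOMENTUM) * bn$rm + BN_MOMENTUM * mu
    bn$rv <- (1 - BN_MOMENTUM) * bn$rv + BN_MOMENTUM * v
    list(y = bn$gamma * xhat + bn$beta, bn = bn,
         cache = list(xhat = xhat, inv_std = inv_std))
  } else {
    inv_std <- 1 / sqrt(bn$rv + BN_EPS)
    xhat <- (x - bn$rm) * inv_std
    list(y = bn$gamma * xhat + bn$beta, bn = bn, cache = NULL)
  }
}

bn_bwd <- function(dout, bn, cache) {
  xhat <- cache$xhat
  M <- prod(dim(dout)[2:3])
  dgamma <- rowSums(dout * xhat, dims = 1)
  dbeta <- rowSums(dout, dims = 1)
  dxhat <- dout * bn$gamma
  s1 <- rowSums(dxhat, dims = 1)
  s2 <- rowSums(dxhat * xhat, dims = 1)
  dx <- (cache$inv_std / M) * (M * dxhat - s1 - xhat * s2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x) x * ((x > 0) + LRELU_ALPHA * (x <= 0))
lrelu_bwd <- function(dout, x) dout * ((x > 0) + LRELU_ALPHA * (x <= 0))

softmax3 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1])
  m <- m - rep(apply(m, 2, max), each = d[1])
  e <- exp(m)
  array(e / rep(colSums(e), each = d[1]), d)
}

init_conv <- function(c_out, c_in, w) {
  sd <- sqrt(2 / (c_in * w))
  list(W = array(stats::rnorm(c_out * c_in * w, sd = sd), c(c_out, c_in, w)),
       b = numeric(c_out))
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), rm = numeric(c), rv = rep(1, c))
}

# Full network forward. x: (4, T, N). Returns logits (3, T-CL, N), updated
# params (running BN stats) and, when requested, the backward cache.
net_forward <- function(params, config, x, training = FALSE,
                        want_cache = FALSE) {
  CL <- config$CL
  T <- dim(x)[2]
  if (T <= CL) {
    stop("input length ", T, " must exceed the cropping length ", CL,
         " (minimum valid length ", CL + 1L, ")")
  }
  cache <- if (want_cache) list(x_input = x) else NULL

  h <- conv1d_fwd(x, params$conv_in$W, params$conv_in$b)
  skip <- conv1d_fwd(h, params$skip_in$W, params$skip_in$b)
  if (want_cache) {
    cache$conv_in_x <- x
    cache$skip_in_x <- h
    cache$units <- vector("list", length(config$W))
  }

  n_units <- length(config$W)
  skip_idx <- 0L
  for (i in seq_len(n_units)) {
    uname <- unit_name(i)
    u <- params[[uname]]
    b1 <- bn_fwd(h, u$bn1, training)
    a1 <- b1$y
    r1 <- lrelu_fwd(a1)
    c1 <- conv1d_fwd(r1, u$conv1$W, u$conv1$b, config$AR[i])
    b2 <- bn_fwd(c1, u$bn2, training)
    a2 <- b2$y
    r2 <- lrelu_fwd(a2)
    c2 <- conv1d_fwd(r2, u$conv2$W, u$conv2$b, config$AR[i])
    u$bn1 <- b1$bn
    u$bn2 <- b2$bn
    params[[uname]] <- u
    if (want_cache) {
      cache$units[[i]] <- list(x_in = h, bn1 = b1$cache, a1 = a1, r1 = r1,
                               c1 = c1, bn2 = b2$cache, a2 = a2, r2 = r2)
    }
    h <- h + c2
    if (i %% config$skip_every == 0L) {
      skip_idx <- skip_idx + 1L
      sname <- skip_name(skip_idx)
      skip <- skip + conv1d_fwd(h, params[[sname]]$W, params[[sname]]$b)
      if (want_cache) cache[[paste0(sname, "_x")]] <- h
    }
  }

  half <- CL %/% 2L
  cropped <- if (half > 0) skip[, (half + 1L):(T - half), , drop = FALSE]
             else skip
  logits <- conv1d_fwd(cropped, params$conv_out$W, params$conv_out$b)
  if (want_cache) cache$conv_out_x <- cropped

  list(logits = logits, params = params, cache = cache)
}

# Full backward pass; dlogits: (3, T-CL, N). Returns gradient structure
# mirroring params (conv W/b, bn gamma/beta).
net_backward <- function(params, config, cache, dlogits) {
  grads <- list()
  CL <- config$CL
  half <- CL %/% 2L

  co <- conv1d_bwd(dlogits, cache$conv_out_x, params$conv_out$W)
  grads$conv_out <- list(W = co$dW, b = co$db)

  d_in <- dim(cache$conv_in_x)
  Tfull <- d_in[2]
  dskip <- array(0, c(dim(params$conv_out$W)[2], Tfull, d_in[3]))
  dskip[, (half + 1L):(Tfull - half), ] <- co$dx

  n_units <- length(config$W)
  n_skips <- n_units %/% config$skip_every
  dh <- array(0, dim(dskip))

  for (i in rev(seq_len(n_units))) {
    if (i %% config$skip_every == 0L) {
      k <- i %/% config$skip_every
      sname <- skip_name(k)
      sk <- conv1d_bwd(dskip, cache[[paste0(sname, "_x")]],
                       params[[sname]]$W)
      grads[[sname]] <- list(W = sk$dW, b = sk$db)
      dh <- dh + sk$dx
    }
    u <- params[[unit_name(i)]]
    uc <- cache$units[[i]]
    # residual: h_out = h_in + c2
    c2b <- conv1d_bwd(dh, uc$r2, u$conv2$W, config$AR[i])
    da2 <- lrelu_bwd(c2b$dx, uc$a2)
    b2b <- bn_bwd(da2, u$bn2, uc$bn2)
    c1b <- conv1d_bwd(b2b$dx, uc$r1, u$conv1$W, config$AR[i])
    da1 <- lrelu_bwd(c1b$dx, uc$a1)
    b1b <- bn_bwd(da1, u$bn1, uc$bn1)
    grads[[unit_name(i)]] <- list(
      bn1 = list(gamma = b1b$dgamma, beta = b1b$dbeta),
      conv1 = list(W = c1b$dW, b = c1b$db),
      bn2 = list(gamma = b2b$dgamma, beta = b2b$dbeta),
      conv2 = list(W = c2b$dW, b = c2b$db))
    dh <- dh + b1b$dx
  }

  si <- conv1d_bwd(dskip, cache$skip_in_x, params$skip_in$W)
  grads$skip_in <- list(W = si$dW, b = si$db)
  dh <- dh + si$dx

  ci <- conv1d_bwd(dh, cache$conv_in_x, params$conv_in$W)
  grads$conv_in <- list(W = ci$dW, b = ci$db)
  grads
}

unit_name <- function(i) sprintf("unit%02d", i)
skip_name <- function(k) sprintf("skip%d", k)

# Flatten nested parameter lists to a named list of leaf arrays
# ("unit01.conv1.W"); BN running stats are excluded from optimization.
flatten_params <- function(params, prefix = NULL) {
  out <- list()
  for (nm in names(params)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    el <- params[[nm]]
    if (is.list(el)) {
      out <- c(out, flatten_params(el, key))
    } else {
      out[[key]] <- el
    }
  }
  out
}

assign_param <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- params
  # walk down, rebuild on the way up
  set_rec <- function(node, parts) {
    if (length(parts) == 1L) {
      node[[parts]] <- value
      return(node)
    }
    node[[parts[1]]] <- set_rec(node[[parts[1]]], parts[-1])
    node
  }
  set_rec(params, parts)
}

new_adamw_state <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

OPT_SKIP_RE <- "\\.(rm|rv)$"

# One AdamW step over the trainable parameter groups.
adamw_step <- function(params, grads, state, lr, trainable = NULL,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  flat_p <- flatten_params(params)
  flat_g <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (key in names(flat_g)) {
    if (grepl(OPT_SKIP_RE, key)) next
    group <- strsplit(key, ".", fixed = TRUE)[[1]][1]
    if (!is.null(trainable) && !isTRUE(trainable[[group]])) next
    g <- flat_g[[key]]
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g * 0
      state$v[[key]] <- g * 0
    }
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
    upd <- (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
    flat_p[[key]] <- flat_p[[key]] - lr * (upd + weight_decay * flat_p[[key]])
    params <- assign_param(params, key, flat_p[[key]])
  }
  list(params = params, state = state)
}
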