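#' @section Tensor conventions:
#' Network activations are dense arrays of dimension `(C, H, W, N)` —
#' channels first, batch last — so channel mixing is a single matrix
#' product against the flattened `(C, H*W*N)` view. All layers implement
#' an explicit forward (returning the output and a cache) and backward
#' (returning input gradients and, where applicable, parameter
#' gradients); both classifier branches are composed from these
#' primitives, so every forward pass is a pure function of (weights,
#' input) and is bit-reproducible.
#' @name nn-internals
NULL

as_nchw <- function(x) {
  # promote a matrix (H x W) or 3-D array (H, W, C) to (C, H, W, 1)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) == 3L) aperm(array(x, c(dim(x), 1L)), c(3, 1, 2, 4))
  else x
}

he_init <- function(n, fan_in) rnorm(n, 0, sqrt(2 / fan_in))

zero_pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

unpad_hw <- function(x, p, H, W) {
  if (p == 0) return(x)
  x[, (p + 1):(p + H), (p + 1):(p + W), , drop = FALSE]
}

conv_out_len <- function(H, k, s, p) (H + 2 * p - k) %/% s + 1L

# ---- convolution -----------------------------------------------------------

conv2d_init <- function(ci, co, k, seed_tag, seed) {
  list(W = array(with_seed(seed, seed_tag, 0L, he_init(co * ci * k * k, ci * k * k)),
                 c(co, ci, k, k)),
       b = numeric(co))
}

conv2d_forward <- function(x, W, b, stride = 1L, pad = NULL) {
  d <- dim(x); k <- dim(W)[3]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  xp <- zero_pad_hw(x, pad)
  Ho <- conv_out_len(d[2], k, stride, pad)
  Wo <- conv_out_len(d[3], k, stride, pad)
  co <- dim(W)[1]; ci <- d[1]
  out <- matrix(0, co, Ho * Wo * d[4])
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    rows <- seq(1L + di, by = stride, length.out = Ho)
    cols <- seq(1L + dj, by = stride, length.out = Wo)
    M <- matrix(xp[, rows, cols, , drop = FALSE], nrow = ci)
    out <- out + matrix(W[, , di + 1L, dj + 1L], co, ci) %*% M
  }
  out <- out + b
  dim(out) <- c(co, Ho, Wo, d[4])
  list(out = out,
       cache = list(xp = xp, dims = d, k = k, stride = stride, pad = pad,
                    Ho = Ho, Wo = Wo))
}

conv2d_backward <- function(dout, W, cache) {
  cc <- cache
  d <- cc$dims; k <- cc$k; s <- cc$stride
  co <- dim(W)[1]; ci <- d[1]
  dmat <- matrix(dout, nrow = co)
  dxp <- array(0, dim(cc$xp))
  dW <- array(0, dim(W))
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    rows <- seq(1L + di, by = s, length.out = cc$Ho)
    cols <- seq(1L + dj, by = s, length.out = cc$Wo)
    M <- matrix(cc$xp[, rows, cols, , drop = FALSE], nrow = ci)
    Wk <- matrix(W[, , di + 1L, dj + 1L], co, ci)
    dW[, , di + 1L, dj + 1L] <- dmat %*% t(M)
    dM <- t(Wk) %*% dmat
    dim(dM) <- c(ci, cc$Ho, cc$Wo, d[4])
    dxp[, rows, cols, ] <-
      dxp[, rows, cols, , drop = FALSE] + dM
  }
  list(dx = unpad_hw(dxp, cc$pad, d[2], d[3]), dW = dW, db = rowSums(dmat))
}

# depthwise convolution: one k x k filter per channel, weights (C, k, k)
dwconv_forward <- function(x, W, b, stride = 1L, pad = NULL) {
  d <- dim(x); k <- dim(W)[2]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  xp <- zero_pad_hw(x, pad)
  Ho <- conv_out_len(d[2], k, stride, pad)
  Wo <- conv_out_len(d[3], k, stride, pad)
  out <- array(0, c(d[1], Ho, Wo, d[4]))
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    rows <- seq(1L + di, by = stride, length.out = Ho)
    cols <- seq(1L + dj, by = stride, length.out = Wo)
    out <- out + xp[, rows, cols, , drop = FALSE] * W[, di + 1L, dj + 1L]
  }
  out <- out + b
  list(out = out, cache = list(xp = xp, dims = d, k = k, stride = stride,
                               pad = pad, Ho = Ho, Wo = Wo))
}

dwconv_backward <- function(dout, W, cache) {
  cc <- cache; d <- cc$dims; k <- cc$k; s <- cc$stride
  dxp <- array(0, dim(cc$xp))
  dW <- array(0, dim(W))
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    rows <- seq(1L + di, by = s, length.out = cc$Ho)
    cols <- seq(1L + dj, by = s, length.out = cc$Wo)
    xs <- cc$xp[, rows, cols, , drop = FALSE]
    dW[, di + 1L, dj + 1L] <- rowSums(matrix(dout * xs, nrow = d[1]))
    dxp[, rows, cols, ] <-
      dxp[, rows, cols, , drop = FALSE] + dout * W[, di + 1L, dj + 1L]
  }
  list(dx = unpad_hw(dxp, cc$pad, d[2], d[3]), dW = dW,
       db = rowSums(matrix(dout, nrow = d[1])))
}

# ---- normalisation ---------------------------------------------------------

#' Batch normalisation of a feature map
#'
#' Standard per-channel normalisation
#' `(Z - delta_B) / sqrt(sigma_B^2 + eps)`: the batch mean is removed and
#' the batch variance (plus the stabiliser `eps`) rescales to unit spread.
#'
#' @param z numeric vector, matrix or array of activations.
#' @param mean,variance batch statistics `delta_B`, `sigma_B^2`; computed
#'   from `z` when omitted.
#' @param eps numerical stabiliser.
#' @return normalised values, same shape as `z`.
#' @export
batch_norm <- function(z, mean = base::mean(z),
                       variance = base::mean((z - mean)^2), eps = 1e-5) {
  (z - mean) / sqrt(variance + eps)
}

bn_forward <- function(x, gamma, beta, state, name, train, eps = 1e-5,
                       momentum = 0.9) {
  d <- dim(x)
  m <- prod(d[-1])
  xm <- matrix(x, nrow = d[1])
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    state[[paste0(name, ".mean")]] <-
      momentum * (state[[paste0(name, ".mean")]] %||% mu) + (1 - momentum) * mu
    state[[paste0(name, ".var")]] <-
      momentum * (state[[paste0(name, ".var")]] %||% v) + (1 - momentum) * v
  } else {
    mu <- state[[paste0(name, ".mean")]] %||% numeric(d[1])
    v <- state[[paste0(name, ".var")]] %||% rep(1, d[1])
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * inv_sd
  out <- gamma * xhat + beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, m = m,
                               train = train))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims
  dm <- matrix(dout, nrow = d[1])
  dgamma <- rowSums(dm * cache$xhat)
  dbeta <- rowSums(dm)
  if (cache$train) {
    dx <- (gamma * cache$inv_sd) *
      (dm - dbeta / cache$m - cache$xhat * (dgamma / cache$m))
  } else {
    dx <- gamma * cache$inv_sd * dm
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted average pooling (WAP)
#'
#' `S_J = (1 - gamma) * mean(A_i)` over the pooling window. With the
#' degenerate setting `gamma = 1` the statistic is identically zero
#' whatever the window.
#'
#' @param values numeric window values `A_i`.
#' @param gamma weighting coefficient in `[0, 1]`.
#' @return pooled scalar.
#' @export
#' @examples
#' wap(c(1, 2, 3, 4), gamma = 0)    # plain mean, 2.5
#' wap(c(1, 2, 3, 4), gamma = 0.5)  # 1.25
wap <- function(values, gamma = 0.5) {
  stopifnot(length(values) > 0, gamma >= 0, gamma <= 1)
  (1 - gamma) * mean(values)
}

#' Weighted-average-pooling batch normalisation (WAP-BN)
#'
#' Batch-normalisation variant whose numerator is scaled by the pooled
#' statistic `S_J` ([wap()] of the window) and whose denominator is
#' inflated by `sigmoid(S_J)`:
#' `(Z S_J - delta_B S_J) / sqrt(sigma_B^2 + sigmoid(S_J) + eps)`.
#' This reference form treats `z` as one channel's window; the network
#' layer applies it per channel with per-sample spatial pooling.
#'
#' @param z numeric vector/matrix of activations `Z_i`.
#' @param gamma pooling coefficient for `S_J` (default 0.5; the
#'   degenerate value 1 nulls the output).
#' @param eps numerical stabiliser.
#' @param s_j optionally force the pooled statistic instead of computing
#'   [wap()] over `z`.
#' @return normalised values, same shape as `z`.
#' @export
wap_bn <- function(z, gamma = 0.5, eps = 1e-5, s_j = NULL) {
  if (is.null(s_j)) s_j <- wap(z, gamma)
  delta <- mean(z)
  sig2 <- mean((z - delta)^2)
  (z * s_j - delta * s_j) / sqrt(sig2 + 1 / (1 + exp(-s_j)) + eps)
}

# network layer: per-channel, per-sample S_J over the full spatial map;
# batch statistics per channel. Backward treats S_J and the batch
# statistics as constants (straight-through).
wapbn_forward <- function(x, gamma_pool, state, name, train, eps = 1e-5,
                          momentum = 0.9) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  # per (channel, sample) spatial mean
  hw <- d[2] * d[3]
  xs <- array(x, c(d[1], hw, d[4]))
  sj <- (1 - gamma_pool) * apply(xs, c(1, 3), mean)          # (C, N)
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans((xm - mu)^2)
    state[[paste0(name, ".mean")]] <-
      momentum * (state[[paste0(name, ".mean")]] %||% mu) + (1 - momentum) * mu
    state[[paste0(name, ".var")]] <-
      momentum * (state[[paste0(name, ".var")]] %||% v) + (1 - momentum) * v
  } else {
    mu <- state[[paste0(name, ".mean")]] %||% numeric(d[1])
    v <- state[[paste0(name, ".var")]] %||% rep(1, d[1])
  }
  sj_full <- sj[, rep(seq_len(d[4]), each = hw), drop = FALSE]
  dim(sj_full) <- d
  scale <- sj_full / sqrt(v + 1 / (1 + exp(-sj_full)) + eps)
  out <- scale * (x - mu)
  list(out = out, cache = list(scale = scale, dims = d))
}

wapbn_backward <- function(dout, cache) {
  list(dx = dout * cache$scale)
}

# ---- activations -----------------------------------------------------------

act_forward <- function(x, kind, alpha = 0.1) {
  out <- switch(kind,
    relu = pmax(x, 0),
    leaky_relu = ifelse(x > 0, x, alpha * x),
    elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    swish = x / (1 + exp(-x)),
    sigmoid = 1 / (1 + exp(-x)),
    identity = x,
    stop("unknown activation ", kind))
  dim(out) <- dim(x)
  list(out = out, cache = list(x = x, kind = kind, alpha = alpha, out = out))
}

act_backward <- function(dout, cache) {
  x <- cache$x
  g <- switch(cache$kind,
    relu = (x > 0) * 1,
    leaky_relu = ifelse(x > 0, 1, cache$alpha),
    elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
    swish = {
      s <- 1 / (1 + exp(-x))
      s + x * s * (1 - s)
    },
    sigmoid = cache$out * (1 - cache$out),
    identity = 1)
  dout * g
}

# ---- pooling ---------------------------------------------------------------

pool_prep <- function(x, k, stride, pad, pad_val) {
  d <- dim(x)
  xp <- if (pad > 0) {
    out <- array(pad_val, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
    out[, (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3]), ] <- x
    out
  } else x
  list(xp = xp, Ho = conv_out_len(d[2], k, stride, pad),
       Wo = conv_out_len(d[3], k, stride, pad), dims = d)
}

avgpool_forward <- function(x, k = 2L, stride = k, pad = 0L) {
  pp <- pool_prep(x, k, stride, pad, 0)
  out <- 0
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    rows <- seq(1L + di, by = stride, length.out = pp$Ho)
    cols <- seq(1L + dj, by = stride, length.out = pp$Wo)
    out <- out + pp$xp[, rows, cols, , drop = FALSE]
  }
  list(out = out / (k * k),
       cache = list(k = k, stride = stride, pad = pad, dims = pp$dims,
                    Ho = pp$Ho, Wo = pp$Wo))
}

avgpool_backward <- function(dout, cache) {
  cc <- cache; d <- cc$dims; k <- cc$k
  dxp <- array(0, c(d[1], d[2] + 2 * cc$pad, d[3] + 2 * cc$pad, d[4]))
  g <- dout / (k * k)
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    rows <- seq(1L + di, by = cc$stride, length.out = cc$Ho)
    cols <- seq(1L + dj, by = cc$stride, length.out = cc$Wo)
    dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] + g
  }
  unpad_hw(dxp, cc$pad, d[2], d[3])
}

maxpool_forward <- function(x, k = 2L, stride = k, pad = 0L) {
  pp <- pool_prep(x, k, stride, pad, -Inf)
  out <- NULL; arg <- NULL
  o <- 0L
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    o <- o + 1L
    rows <- seq(1L + di, by = stride, length.out = pp$Ho)
    cols <- seq(1L + dj, by = stride, length.out = pp$Wo)
    xs <- pp$xp[, rows, cols, , drop = FALSE]
    if (is.null(out)) {
      out <- xs
      arg <- array(1L, dim(xs))
    } else {
      better <- xs > out
      out[better] <- xs[better]
      arg[better] <- o
    }
  }
  list(out = out, cache = list(k = k, stride = stride, pad = pad,
                               dims = pp$dims, Ho = pp$Ho, Wo = pp$Wo,
                               arg = arg))
}

maxpool_backward <- function(dout, cache) {
  cc <- cache; d <- cc$dims; k <- cc$k
  dxp <- array(0, c(d[1], d[2] + 2 * cc$pad, d[3] + 2 * cc$pad, d[4]))
  o <- 0L
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    o <- o + 1L
    rows <- seq(1L + di, by = cc$stride, length.out = cc$Ho)
    cols <- seq(1L + dj, by = cc$stride, length.out = cc$Wo)
    dxp[, rows, cols, ] <-
      dxp[, rows, cols, , drop = FALSE] + dout * (cc$arg == o)
  }
  unpad_hw(dxp, cc$pad, d[2], d[3])
}

#' Mixed pooling of a feature map
#'
#' Convex combination `lambda * maxpool + (1 - lambda) * avgpool` over the
#' same windows; `lambda = 1` is exactly max pooling, `lambda = 0` exactly
#' average pooling.
#'
#' @param x numeric matrix (one channel) or `(C, H, W, N)` array.
#' @param lambda mixing coefficient in `[0, 1]`.
#' @param window,stride pooling geometry.
#' @return pooled map of the same kind as the input.
#' @export
mixed_pool <- function(x, lambda = 0.5, window = 2L, stride = window) {
  stopifnot(lambda >= 0, lambda <= 1)
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, c(1L, dim(x), 1L))
  mx <- maxpool_forward(x, window, stride)$out
  av <- avgpool_forward(x, window, stride)$out
  out <- lambda * mx + (1 - lambda) * av
  if (was_matrix) out <- matrix(out, dim(out)[2], dim(out)[3])
  out
}

mixedpool_forward <- function(x, lambda, k = 2L, stride = k, pad = 0L) {
  mx <- maxpool_forward(x, k, stride, pad)
  av <- avgpool_forward(x, k, stride, pad)
  list(out = lambda * mx$out + (1 - lambda) * av$out,
       cache = list(mx = mx$cache, av = av$cache, lambda = lambda))
}

mixedpool_backward <- function(dout, cache) {
  cache$lambda * maxpool_backward(dout, cache$mx) +
    (1 - cache$lambda) * avgpool_backward(dout, cache$av)
}

global_avgpool_forward <- function(x) {
  d <- dim(x)
  xs <- array(x, c(d[1], d[2] * d[3], d[4]))
  list(out = apply(xs, c(1, 3), mean), cache = list(dims = d))
}

global_avgpool_backward <- function(dout, cache) {
  d <- cache$dims
  hw <- d[2] * d[3]
  g <- dout[, rep(seq_len(d[4]), each = hw), drop = FALSE] / hw
  dim(g) <- d
  g
}

upsample_forward <- function(x, f = 2L) {
  d <- dim(x)
  out <- x[, rep(seq_len(d[2]), each = f), rep(seq_len(d[3]), each = f), ,
           drop = FALSE]
  list(out = out, cache = list(dims = d, f = f))
}

upsample_backward <- function(dout, cache) {
  d <- cache$dims; f <- cache$f
  dx <- array(0, d)
  for (di in 0:(f - 1L)) for (dj in 0:(f - 1L)) {
    dx <- dx + dout[, seq(1L + di, by = f, length.out = d[2]),
                    seq(1L + dj, by = f, length.out = d[3]), , drop = FALSE]
  }
  dx
}

# ---- dense / loss ----------------------------------------------------------

dense_forward <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x))
}

dense_backward <- function(dout, W, cache) {
  list(dx = t(W) %*% dout, dW = dout %*% t(cache$x), db = rowSums(dout))
}

softmax_cols <- function(logits) {
  z <- logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
                       byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(e), ncol(e), byrow = TRUE)
}

# cross-entropy over a (K, N) logit matrix; y is an integer class vector
softmax_ce <- function(logits, y) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# soft XOR fusion |a - b| (differentiable a.e.); binary mode thresholds
# both maps at `threshold` and XORs the bits
xor_fuse <- function(a, b, mode = c("soft", "binary"), threshold = 0) {
  mode <- match.arg(mode)
  if (!identical(dim(a), dim(b))) stop("xor_fuse: unalignable shapes")
  if (mode == "soft") abs(a - b)
  else (xor(a > threshold, b > threshold)) * 1
}

xor_fuse_backward <- function(dout, a, b) {
  s <- sign(a - b)
  list(da = dout * s, db = -dout * s)
}

# ---- optimiser -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
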