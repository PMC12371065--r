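#' Gabor kernel
#'
#' Oriented band-pass kernel
#' `exp(-(x'^2 + g^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`
#' with `x', y'` the coordinates rotated by `theta`. Used as the fixed
#' (non-trainable) front filters of the MDSCM module.
#'
#' @param theta orientation, radians.
#' @param lambda wavelength, pixels.
#' @param psi phase, radians.
#' @param sigma Gaussian envelope scale, pixels.
#' @param gamma spatial aspect ratio.
#' @param half_width kernel half-width.
#' @return square weight matrix.
#' @export
gabor_kernel <- function(theta = 0, lambda = 8, psi = 0, sigma = 4,
                         gamma = 0.5, half_width = 3L) {
  off <- seq(-half_width, half_width)
  xg <- matrix(off, length(off), length(off), byrow = TRUE)
  yg <- matrix(off, length(off), length(off))
  xr <- xg * cos(theta) + yg * sin(theta)
  yr <- -xg * sin(theta) + yg * cos(theta)
  exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda + psi)
}

#' MDSCM module specification
#'
#' Multi-branch descriptor module: three parallel branches apply a fixed
#' Gabor filter (orientations 0, 45, 90 degrees by default), a
#' convolution with kernel size 3/5/7, and batch normalisation; each
#' branch output is XOR-fused with the matching (upsampled) encoder
#' output and the three fusions are concatenated channel-wise.
#'
#' @param channels branch output channels (must match the encoder widths
#'   they fuse with).
#' @param kernels branch convolution kernel sizes.
#' @param gabor_bank list of three argument lists for [gabor_kernel()].
#' @param xor_mode `"soft"` (`|a - b|`, differentiable) or `"binary"`
#'   (threshold then bitwise XOR).
#' @param binarize_threshold threshold for binary mode.
#' @return list of class `pd_mdscm_spec`.
#' @export
mdscm_spec <- function(channels = c(32L, 64L, 128L), kernels = c(3L, 5L, 7L),
                       gabor_bank = list(list(theta = 0), list(theta = pi / 4),
                                         list(theta = pi / 2)),
                       xor_mode = c("soft", "binary"),
                       binarize_threshold = 0) {
  stopifnot(length(channels) == 3L, length(kernels) == 3L,
            length(gabor_bank) == 3L)
  structure(list(channels = as.integer(channels), kernels = as.integer(kernels),
                 gabor_bank = gabor_bank, xor_mode = match.arg(xor_mode),
                 binarize_threshold = binarize_threshold),
            class = "pd_mdscm_spec")
}

mdscm_init <- function(spec, in_channels, seed) {
  p <- list()
  for (i in 1:3) {
    cv <- conv2d_init(in_channels, spec$channels[i], spec$kernels[i],
                      paste0("mdscm", i), seed)
    p[[paste0("mdscm", i, ".W")]] <- cv$W
    p[[paste0("mdscm", i, ".b")]] <- cv$b
    p[[paste0("mdscm", i, "bn.gamma")]] <- rep(1, spec$channels[i])
    p[[paste0("mdscm", i, "bn.beta")]] <- numeric(spec$channels[i])
  }
  p
}

mdscm_gabors <- function(spec) {
  lapply(spec$gabor_bank, function(a) do.call(gabor_kernel, a))
}

# internal forward; enc_ups are the encoder maps already upsampled to the
# input resolution with matching channel counts
mdscm_forward_internal <- function(x, enc_ups, spec, params, state, train,
                                   gabors) {
  branches <- list(); caches <- list()
  for (i in 1:3) {
    gk <- gabors[[i]]
    Wg <- array(0, c(1L, dim(x)[1], nrow(gk), ncol(gk)))
    for (c_in in seq_len(dim(x)[1])) Wg[1, c_in, , ] <- gk / dim(x)[1]
    gb <- conv2d_forward(x, Wg, 0)
    cv <- conv2d_forward(gb$out, params[[paste0("mdscm", i, ".W")]],
                         params[[paste0("mdscm", i, ".b")]])
    bn <- bn_forward(cv$out, params[[paste0("mdscm", i, "bn.gamma")]],
                     params[[paste0("mdscm", i, "bn.beta")]], state,
                     paste0("mdscm", i, "bn"), train)
    br <- bn$out
    enc <- enc_ups[[i]]
    if (!identical(dim(br), dim(enc)))
      stop("mdscm branch ", i, " and encoder map have unalignable shapes")
    fused <- if (spec$xor_mode == "soft") abs(br - enc)
             else xor_fuse(br, enc, "binary", spec$binarize_threshold)
    branches[[i]] <- fused
    caches[[i]] <- list(gb = gb$cache, cv = cv$cache, bn = bn$cache,
                        br = br, enc = enc, Wg = Wg)
  }
  d <- dim(branches[[1]])
  ch <- vapply(branches, function(b) dim(b)[1], integer(1))
  out <- array(0, c(sum(ch), d[2], d[3], d[4]))
  at <- 0L
  for (i in 1:3) {
    out[at + seq_len(ch[i]), , , ] <- branches[[i]]
    at <- at + ch[i]
  }
  list(out = out, cache = list(branches = caches, ch = ch, spec = spec))
}

# returns list(dx = gradient wrt module input, denc = list of gradients
# wrt the three upsampled encoder maps)
mdscm_backward_internal <- function(dout, cache, params, acc) {
  ch <- cache$ch
  dx <- NULL
  denc <- vector("list", 3L)
  at <- 0L
  for (i in 1:3) {
    cc <- cache$branches[[i]]
    dfused <- dout[at + seq_len(ch[i]), , , , drop = FALSE]
    at <- at + ch[i]
    s <- sign(cc$br - cc$enc)      # straight-through for binary mode too
    dbr <- dfused * s
    denc[[i]] <- -dfused * s
    bb <- bn_backward(dbr, params[[paste0("mdscm", i, "bn.gamma")]], cc$bn)
    acc_add(acc, paste0("mdscm", i, "bn.gamma"), bb$dgamma)
    acc_add(acc, paste0("mdscm", i, "bn.beta"), bb$dbeta)
    cvb <- conv2d_backward(bb$dx, params[[paste0("mdscm", i, ".W")]], cc$cv)
    acc_add(acc, paste0("mdscm", i, ".W"), cvb$dW)
    acc_add(acc, paste0("mdscm", i, ".b"), cvb$db)
    gbb <- conv2d_backward(cvb$dx, cc$Wg, cc$gb)
    dx <- if (is.null(dx)) gbb$dx else dx + gbb$dx
  }
  list(dx = dx, denc = denc)
}

#' Apply the MDSCM module
#'
#' Functional form for inspection and testing: branch `i` computes
#' `BN(conv_{k_i}(gabor_i(x)))`, XOR-fuses it with `encoder_outputs[[i]]`
#' (upsampled to the input resolution if needed), and the three fusions
#' are concatenated channel-wise.
#'
#' @param x input map (`(C, H, W, N)` array or matrix).
#' @param encoder_outputs list of three encoder maps whose channel counts
#'   match `spec$channels`.
#' @param spec a [mdscm_spec()].
#' @param params optional named parameter list (seeded when omitted).
#' @param seed weight seed.
#' @return fused feature map with `sum(spec$channels)` channels.
#' @export
mdscm_forward <- function(x, encoder_outputs, spec = mdscm_spec(),
                          params = NULL, seed = 1L) {
  x <- as_nchw(x)
  encoder_outputs <- lapply(encoder_outputs, as_nchw)
  enc_ups <- lapply(encoder_outputs, function(e) {
    f <- dim(x)[2] / dim(e)[2]
    if (f != round(f)) stop("mdscm: encoder map not resamplable to input size")
    if (f > 1) upsample_forward(e, as.integer(f))$out else e
  })
  if (is.null(params)) params <- mdscm_init(spec, dim(x)[1], seed)
  state <- new.env(parent = emptyenv())
  mdscm_forward_internal(x, enc_ups, spec, params, state, FALSE,
                         mdscm_gabors(spec))$out
}

# ---- improved LinkNet ------------------------------------------------------

#' Improved LinkNet classifier specification
#'
#' Three encoders with distinct activations (LeakyReLU / ELU / Swish) and
#' pooling (average / average + mixed / none), the MDSCM module fused from
#' the input and all three encoders, and three decoders with WAP-BN
#' normalisation and LinkNet-style additive skips; the MDSCM output feeds
#' the final (full-resolution) decoder. The input side must be divisible
#' by 4.
#'
#' @param in_channels input channel count.
#' @param num_classes output classes.
#' @param enc_channels the three encoder widths.
#' @param gamma_wap pooling coefficient of the WAP-BN layers (the printed
#'   setting 1 makes WAP-BN vanish identically; see [wap()]).
#' @param lambda_mix mixing coefficient of encoder 2's mixed pooling.
#' @param mdscm a [mdscm_spec()]; its channels must equal `enc_channels`.
#' @return list of class `pd_ilinknet_spec`.
#' @export
ilinknet_spec <- function(in_channels = 1L, num_classes = 2L,
                          enc_channels = c(32L, 64L, 128L), gamma_wap = 0.5,
                          lambda_mix = 0.5,
                          mdscm = mdscm_spec(channels = enc_channels)) {
  stopifnot(length(enc_channels) == 3L,
            identical(as.integer(mdscm$channels), as.integer(enc_channels)))
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 enc_channels = as.integer(enc_channels),
                 gamma_wap = gamma_wap, lambda_mix = lambda_mix,
                 mdscm = mdscm),
            class = "pd_ilinknet_spec")
}

ilinknet_init <- function(spec = ilinknet_spec(), seed = 1L) {
  ec <- spec$enc_channels
  p <- list()
  add_conv <- function(name, ci, co, k) {
    cv <- conv2d_init(ci, co, k, name, seed)
    p[[paste0(name, ".W")]] <<- cv$W
    p[[paste0(name, ".b")]] <<- cv$b
  }
  add_bn <- function(name, c) {
    p[[paste0(name, ".gamma")]] <<- rep(1, c)
    p[[paste0(name, ".beta")]] <<- numeric(c)
  }
  add_conv("enc1", spec$in_channels, ec[1], 3L); add_bn("enc1bn", ec[1])
  add_conv("enc2", ec[1], ec[2], 3L);            add_bn("enc2bn", ec[2])
  add_conv("enc3", ec[2], ec[3], 3L);            add_bn("enc3bn", ec[3])
  p <- c(p, mdscm_init(spec$mdscm, spec$in_channels, seed))
  add_conv("dec1", ec[3], ec[2], 3L)
  add_conv("dec2", ec[2], ec[1], 3L)
  add_conv("mproj", sum(spec$mdscm$channels), ec[1], 1L)
  add_conv("dec3", ec[1], ec[1], 3L)
  p[["fc.W"]] <- matrix(with_seed(seed, "fc", 0L,
                                  he_init(spec$num_classes * ec[1], ec[1])),
                        spec$num_classes, ec[1])
  p[["fc.b"]] <- numeric(spec$num_classes)
  list(params = p, state = new.env(parent = emptyenv()), spec = spec,
       arch = "ilinknet", gabors = mdscm_gabors(spec$mdscm))
}

ilinknet_apply <- function(model, x, train = FALSE) {
  p <- model$params; st <- model$state; spec <- model$spec
  gw <- spec$gamma_wap
  cc <- list()
  # encoder 1: conv -> BN -> LeakyReLU -> average pool
  c1 <- conv2d_forward(x, p[["enc1.W"]], p[["enc1.b"]])
  b1 <- bn_forward(c1$out, p[["enc1bn.gamma"]], p[["enc1bn.beta"]], st,
                   "enc1bn", train)
  a1 <- act_forward(b1$out, "leaky_relu")
  p1 <- avgpool_forward(a1$out, 2L, 2L)
  e1 <- p1$out
  # encoder 2: conv -> BN -> ELU -> average pool -> mixed pool
  c2 <- conv2d_forward(e1, p[["enc2.W"]], p[["enc2.b"]])
  b2 <- bn_forward(c2$out, p[["enc2bn.gamma"]], p[["enc2bn.beta"]], st,
                   "enc2bn", train)
  a2 <- act_forward(b2$out, "elu")
  p2 <- avgpool_forward(a2$out, 2L, 2L)
  m2 <- mixedpool_forward(p2$out, spec$lambda_mix, 3L, 1L, 1L)
  e2 <- m2$out
  # encoder 3: conv -> BN -> Swish (no pooling)
  c3 <- conv2d_forward(e2, p[["enc3.W"]], p[["enc3.b"]])
  b3 <- bn_forward(c3$out, p[["enc3bn.gamma"]], p[["enc3bn.beta"]], st,
                   "enc3bn", train)
  a3 <- act_forward(b3$out, "swish")
  e3 <- a3$out
  # MDSCM over the input and upsampled encoder maps
  u1 <- upsample_forward(e1, 2L)
  u2 <- upsample_forward(e2, 4L)
  u3 <- upsample_forward(e3, 4L)
  md <- mdscm_forward_internal(x, list(u1$out, u2$out, u3$out), spec$mdscm,
                               p, st, train, model$gabors)
  # decoder 1 (quarter resolution): conv -> WAP-BN -> ReLU, skip-add e2
  d1c <- conv2d_forward(e3, p[["dec1.W"]], p[["dec1.b"]])
  d1w <- wapbn_forward(d1c$out, gw, st, "dec1wbn", train)
  d1a <- act_forward(d1w$out, "relu")
  d1u <- upsample_forward(d1a$out + e2, 2L)
  # decoder 2 (half resolution): conv -> WAP-BN -> ReLU, skip-add e1
  d2c <- conv2d_forward(d1u$out, p[["dec2.W"]], p[["dec2.b"]])
  d2w <- wapbn_forward(d2c$out, gw, st, "dec2wbn", train)
  d2a <- act_forward(d2w$out, "relu")
  d2u <- upsample_forward(d2a$out + e1, 2L)
  # decoder 3 (full resolution): MDSCM projection joins here
  mp <- conv2d_forward(md$out, p[["mproj.W"]], p[["mproj.b"]])
  d3in <- d2u$out + mp$out
  d3c <- conv2d_forward(d3in, p[["dec3.W"]], p[["dec3.b"]])
  d3w <- wapbn_forward(d3c$out, gw, st, "dec3wbn", train)
  d3a <- act_forward(d3w$out, "relu")
  gp <- global_avgpool_forward(d3a$out)
  fc <- dense_forward(gp$out, p[["fc.W"]], p[["fc.b"]])
  cc <- list(c1 = c1$cache, b1 = b1$cache, a1 = a1$cache, p1 = p1$cache,
             c2 = c2$cache, b2 = b2$cache, a2 = a2$cache, p2 = p2$cache,
             m2 = m2$cache, c3 = c3$cache, b3 = b3$cache, a3 = a3$cache,
             u1 = u1$cache, u2 = u2$cache, u3 = u3$cache, md = md$cache,
             d1c = d1c$cache, d1w = d1w$cache, d1a = d1a$cache, d1u = d1u$cache,
             d2c = d2c$cache, d2w = d2w$cache, d2a = d2a$cache, d2u = d2u$cache,
             mp = mp$cache, d3c = d3c$cache, d3w = d3w$cache, d3a = d3a$cache,
             gp = gp$cache, fc = fc$cache)
  list(logits = fc$out, caches = cc)
}

ilinknet_backprop <- function(model, cc, dlogits) {
  p <- model$params
  acc <- new.env(parent = emptyenv())
  fb <- dense_backward(dlogits, p[["fc.W"]], cc$fc)
  acc_add(acc, "fc.W", fb$dW); acc_add(acc, "fc.b", fb$db)
  g <- global_avgpool_backward(fb$dx, cc$gp)
  # decoder 3
  g <- act_backward(g, cc$d3a)
  g <- wapbn_backward(g, cc$d3w)$dx
  d3b <- conv2d_backward(g, p[["dec3.W"]], cc$d3c)
  acc_add(acc, "dec3.W", d3b$dW); acc_add(acc, "dec3.b", d3b$db)
  dd3in <- d3b$dx
  mpb <- conv2d_backward(dd3in, p[["mproj.W"]], cc$mp)
  acc_add(acc, "mproj.W", mpb$dW); acc_add(acc, "mproj.b", mpb$db)
  mdb <- mdscm_backward_internal(mpb$dx, cc$md, p, acc)
  de1 <- upsample_backward(mdb$denc[[1]], cc$u1)
  de2 <- upsample_backward(mdb$denc[[2]], cc$u2)
  de3 <- upsample_backward(mdb$denc[[3]], cc$u3)
  # decoder 2
  g <- upsample_backward(dd3in, cc$d2u)
  de1 <- de1 + g                               # skip-add e1
  g <- act_backward(g, cc$d2a)
  g <- wapbn_backward(g, cc$d2w)$dx
  d2b <- conv2d_backward(g, p[["dec2.W"]], cc$d2c)
  acc_add(acc, "dec2.W", d2b$dW); acc_add(acc, "dec2.b", d2b$db)
  # decoder 1
  g <- upsample_backward(d2b$dx, cc$d1u)
  de2 <- de2 + g                               # skip-add e2
  g <- act_backward(g, cc$d1a)
  g <- wapbn_backward(g, cc$d1w)$dx
  d1b <- conv2d_backward(g, p[["dec1.W"]], cc$d1c)
  acc_add(acc, "dec1.W", d1b$dW); acc_add(acc, "dec1.b", d1b$db)
  de3 <- de3 + d1b$dx
  # encoder 3
  g <- act_backward(de3, cc$a3)
  b3b <- bn_backward(g, p[["enc3bn.gamma"]], cc$b3)
  acc_add(acc, "enc3bn.gamma", b3b$dgamma); acc_add(acc, "enc3bn.beta", b3b$dbeta)
  c3b <- conv2d_backward(b3b$dx, p[["enc3.W"]], cc$c3)
  acc_add(acc, "enc3.W", c3b$dW); acc_add(acc, "enc3.b", c3b$db)
  de2 <- de2 + c3b$dx
  # encoder 2
  g <- mixedpool_backward(de2, cc$m2)
  g <- avgpool_backward(g, cc$p2)
  g <- act_backward(g, cc$a2)
  b2b <- bn_backward(g, p[["enc2bn.gamma"]], cc$b2)
  acc_add(acc, "enc2bn.gamma", b2b$dgamma); acc_add(acc, "enc2bn.beta", b2b$dbeta)
  c2b <- conv2d_backward(b2b$dx, p[["enc2.W"]], cc$c2)
  acc_add(acc, "enc2.W", c2b$dW); acc_add(acc, "enc2.b", c2b$db)
  de1 <- de1 + c2b$dx
  # encoder 1
  g <- avgpool_backward(de1, cc$p1)
  g <- act_backward(g, cc$a1)
  b1b <- bn_backward(g, p[["enc1bn.gamma"]], cc$b1)
  acc_add(acc, "enc1bn.gamma", b1b$dgamma); acc_add(acc, "enc1bn.beta", b1b$dbeta)
  c1b <- conv2d_backward(b1b$dx, p[["enc1.W"]], cc$c1)
  acc_add(acc, "enc1.W", c1b$dW); acc_add(acc, "enc1.b", c1b$db)
  as.list(acc)
}

#' Run the improved LinkNet branch on an input map
#'
#' Builds a seeded model (weights are a pure function of `seed`) and
#' returns the per-class probability scores `ILn^o`.
#'
#' @param input `(C, H, W, N)` array, or a matrix / `(H, W, C)` array for
#'   a single sample. The spatial side must be divisible by 4.
#' @param spec an [ilinknet_spec()].
#' @param seed weight seed.
#' @return matrix of class scores (`num_classes` x N), columns summing
#'   to 1.
#' @export
improved_linknet_forward <- function(input, spec = ilinknet_spec(), seed = 1L) {
  x <- as_nchw(input)
  check_pool_chain(dim(x)[2:3], 4L, "improved LinkNet")
  model <- ilinknet_init(spec, seed)
  scores_from_logits(ilinknet_apply(model, x, train = FALSE)$logits,
                     spec$num_classes)
}
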