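#' Ghost module specification
#'
#' A ghost module emits `out_channels / ratio` "primary" feature maps
#' with an ordinary convolution and manufactures the remaining
#' `(ratio - 1) / ratio` share with cheap depthwise transforms of the
#' primary maps, cutting parameters roughly by the ratio `s`.
#'
#' @param in_channels,out_channels channel counts; `out_channels` must be
#'   divisible by `ratio`.
#' @param ratio primary:cheap split `s` (>= 2).
#' @param primary_kernel dense convolution kernel size.
#' @param cheap_kernel depthwise kernel size.
#' @param stride 1 or 2 (applied in the primary convolution).
#' @param activation apply BN + ReLU after each part (the projection
#'   module of a bottleneck disables this).
#' @return list of class `pd_ghost_spec`.
#' @export
ghost_module_spec <- function(in_channels, out_channels, ratio = 2L,
                              primary_kernel = 1L, cheap_kernel = 3L,
                              stride = 1L, activation = TRUE) {
  if (out_channels %% ratio != 0)
    stop("out_channels (", out_channels, ") not divisible by ratio ", ratio)
  stopifnot(stride %in% c(1L, 2L), ratio >= 2)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel),
                 stride = as.integer(stride), activation = activation),
            class = "pd_ghost_spec")
}

#' Convolution-weight count of a ghost module
#'
#' Counts primary + cheap convolution weights and biases (normalisation
#' parameters excluded), for comparison against the
#' `out * in * k^2 + out` cost of the equivalent dense convolution.
#'
#' @param spec a [ghost_module_spec()].
#' @return integer parameter count.
#' @export
ghost_module_params <- function(spec) {
  m <- spec$out_channels %/% spec$ratio
  cheap <- spec$out_channels - m
  m * spec$in_channels * spec$primary_kernel^2 + m +
    cheap * spec$cheap_kernel^2 + cheap
}

gm_init <- function(prefix, spec, seed) {
  m <- spec$out_channels %/% spec$ratio
  cheap <- spec$out_channels - m
  p <- list()
  cv <- conv2d_init(spec$in_channels, m, spec$primary_kernel,
                    paste0(prefix, ".primary"), seed)
  p[[paste0(prefix, ".primary.W")]] <- cv$W
  p[[paste0(prefix, ".primary.b")]] <- cv$b
  p[[paste0(prefix, ".cheap.W")]] <-
    array(with_seed(seed, paste0(prefix, ".cheap"), 0L,
                    he_init(cheap * spec$cheap_kernel^2, spec$cheap_kernel^2)),
          c(cheap, spec$cheap_kernel, spec$cheap_kernel))
  p[[paste0(prefix, ".cheap.b")]] <- numeric(cheap)
  p[[paste0(prefix, ".bn1.gamma")]] <- rep(1, m)
  p[[paste0(prefix, ".bn1.beta")]] <- numeric(m)
  p[[paste0(prefix, ".bn2.gamma")]] <- rep(1, cheap)
  p[[paste0(prefix, ".bn2.beta")]] <- numeric(cheap)
  p
}

gm_forward <- function(x, spec, params, state, prefix, train) {
  m <- spec$out_channels %/% spec$ratio
  rep_k <- spec$ratio - 1L
  cv <- conv2d_forward(x, params[[paste0(prefix, ".primary.W")]],
                       params[[paste0(prefix, ".primary.b")]],
                       stride = spec$stride)
  b1 <- bn_forward(cv$out, params[[paste0(prefix, ".bn1.gamma")]],
                   params[[paste0(prefix, ".bn1.beta")]], state,
                   paste0(prefix, ".bn1"), train)
  a1 <- if (spec$activation) act_forward(b1$out, "relu")
        else list(out = b1$out, cache = NULL)
  # cheap branch: depthwise transforms of the (activated) primary maps,
  # channel multiplier ratio - 1
  prim <- a1$out
  rep_idx <- rep(seq_len(m), rep_k)
  cheap_in <- prim[rep_idx, , , , drop = FALSE]
  dw <- dwconv_forward(cheap_in, params[[paste0(prefix, ".cheap.W")]],
                       params[[paste0(prefix, ".cheap.b")]])
  b2 <- bn_forward(dw$out, params[[paste0(prefix, ".bn2.gamma")]],
                   params[[paste0(prefix, ".bn2.beta")]], state,
                   paste0(prefix, ".bn2"), train)
  a2 <- if (spec$activation) act_forward(b2$out, "relu")
        else list(out = b2$out, cache = NULL)
  d1 <- dim(prim); d2 <- dim(a2$out)
  out <- array(0, c(d1[1] + d2[1], d1[2], d1[3], d1[4]))
  out[seq_len(d1[1]), , , ] <- prim
  out[d1[1] + seq_len(d2[1]), , , ] <- a2$out
  list(out = out,
       cache = list(cv = cv$cache, b1 = b1$cache, a1 = a1$cache,
                    dw = dw$cache, b2 = b2$cache, a2 = a2$cache,
                    m = m, rep_idx = rep_idx, spec = spec))
}

gm_backward <- function(dout, cache, params, prefix, acc) {
  m <- cache$m
  spec <- cache$spec
  d_prim_cat <- dout[seq_len(m), , , , drop = FALSE]
  d_cheap <- dout[m + seq_len(dim(dout)[1] - m), , , , drop = FALSE]
  if (spec$activation) d_cheap <- act_backward(d_cheap, cache$a2)
  bb2 <- bn_backward(d_cheap, params[[paste0(prefix, ".bn2.gamma")]], cache$b2)
  acc_add(acc, paste0(prefix, ".bn2.gamma"), bb2$dgamma)
  acc_add(acc, paste0(prefix, ".bn2.beta"), bb2$dbeta)
  dwb <- dwconv_backward(bb2$dx, params[[paste0(prefix, ".cheap.W")]], cache$dw)
  acc_add(acc, paste0(prefix, ".cheap.W"), dwb$dW)
  acc_add(acc, paste0(prefix, ".cheap.b"), dwb$db)
  # cheap input was the primary maps replicated; fold gradients back
  d_prim <- d_prim_cat
  for (r in seq_along(cache$rep_idx)) {
    ch <- cache$rep_idx[r]
    d_prim[ch, , , ] <- d_prim[ch, , , ] + dwb$dx[r, , , ]
  }
  if (spec$activation) d_prim <- act_backward(d_prim, cache$a1)
  bb1 <- bn_backward(d_prim, params[[paste0(prefix, ".bn1.gamma")]], cache$b1)
  acc_add(acc, paste0(prefix, ".bn1.gamma"), bb1$dgamma)
  acc_add(acc, paste0(prefix, ".bn1.beta"), bb1$dbeta)
  cvb <- conv2d_backward(bb1$dx, params[[paste0(prefix, ".primary.W")]],
                         cache$cv)
  acc_add(acc, paste0(prefix, ".primary.W"), cvb$dW)
  acc_add(acc, paste0(prefix, ".primary.b"), cvb$db)
  cvb$dx
}

acc_add <- function(acc, name, value) {
  acc[[name]] <- if (is.null(acc[[name]])) value else acc[[name]] + value
  invisible(NULL)
}

#' Apply a ghost module to a feature map
#'
#' Functional form with seeded weights (or supplied ones); primarily for
#' inspection and testing — the full network manages parameters itself.
#'
#' @param x input array `(C, H, W, N)` (a matrix is promoted to a
#'   one-channel, one-sample map).
#' @param spec a [ghost_module_spec()].
#' @param params optional named parameter list from a previous call.
#' @param seed weight-initialisation seed.
#' @return output feature map with `out_channels` channels; attribute
#'   `params` carries the weights used.
#' @export
ghost_module <- function(x, spec, params = NULL, seed = 1L) {
  x <- as_nchw(x)
  if (dim(x)[1] != spec$in_channels)
    stop("input has ", dim(x)[1], " channels; spec expects ", spec$in_channels)
  if (is.null(params)) params <- gm_init("gm", spec, seed)
  state <- new.env(parent = emptyenv())
  out <- gm_forward(x, spec, params, state, "gm", train = FALSE)$out
  attr(out, "params") <- params
  out
}

# ---- ghost bottleneck ------------------------------------------------------

gb_init <- function(prefix, ci, co, exp_ch, stride, seed) {
  p <- c(gm_init(paste0(prefix, ".gm1"),
                 ghost_module_spec(ci, exp_ch, activation = TRUE), seed),
         gm_init(paste0(prefix, ".gm2"),
                 ghost_module_spec(exp_ch, co, activation = FALSE), seed))
  if (stride == 2L) {
    p[[paste0(prefix, ".dw.W")]] <-
      array(with_seed(seed, paste0(prefix, ".dw"), 0L, he_init(exp_ch * 9, 9)),
            c(exp_ch, 3L, 3L))
    p[[paste0(prefix, ".dw.b")]] <- numeric(exp_ch)
    p[[paste0(prefix, ".dwbn.gamma")]] <- rep(1, exp_ch)
    p[[paste0(prefix, ".dwbn.beta")]] <- numeric(exp_ch)
  }
  if (stride == 2L || ci != co) {
    sc <- conv2d_init(ci, co, 1L, paste0(prefix, ".sc"), seed)
    p[[paste0(prefix, ".sc.W")]] <- sc$W
    p[[paste0(prefix, ".sc.b")]] <- sc$b
    p[[paste0(prefix, ".scbn.gamma")]] <- rep(1, co)
    p[[paste0(prefix, ".scbn.beta")]] <- numeric(co)
  }
  p
}

gb_forward <- function(x, blk, params, state, prefix, train) {
  spec1 <- ghost_module_spec(blk$ci, blk$exp, activation = TRUE)
  spec2 <- ghost_module_spec(blk$exp, blk$out, activation = FALSE)
  g1 <- gm_forward(x, spec1, params, state, paste0(prefix, ".gm1"), train)
  mid <- g1$out
  dw <- NULL; dwbn <- NULL
  if (blk$stride == 2L) {
    dw <- dwconv_forward(mid, params[[paste0(prefix, ".dw.W")]],
                         params[[paste0(prefix, ".dw.b")]], stride = 2L)
    dwbn <- bn_forward(dw$out, params[[paste0(prefix, ".dwbn.gamma")]],
                       params[[paste0(prefix, ".dwbn.beta")]], state,
                       paste0(prefix, ".dwbn"), train)
    mid <- dwbn$out
  }
  g2 <- gm_forward(mid, spec2, params, state, paste0(prefix, ".gm2"), train)
  has_proj <- blk$stride == 2L || blk$ci != blk$out
  if (has_proj) {
    xs <- if (blk$stride == 2L) avgpool_forward(x, 2L, 2L) else NULL
    sc_in <- if (is.null(xs)) x else xs$out
    sc <- conv2d_forward(sc_in, params[[paste0(prefix, ".sc.W")]],
                         params[[paste0(prefix, ".sc.b")]], stride = 1L)
    scbn <- bn_forward(sc$out, params[[paste0(prefix, ".scbn.gamma")]],
                       params[[paste0(prefix, ".scbn.beta")]], state,
                       paste0(prefix, ".scbn"), train)
    short <- scbn$out
  } else {
    xs <- NULL; sc <- NULL; scbn <- NULL
    short <- x
  }
  list(out = g2$out + short,
       cache = list(g1 = g1$cache, g2 = g2$cache, dw = if (!is.null(dw)) dw$cache,
                    dwbn = if (!is.null(dwbn)) dwbn$cache,
                    xs = if (!is.null(xs)) xs$cache,
                    sc = if (!is.null(sc)) sc$cache,
                    scbn = if (!is.null(scbn)) scbn$cache,
                    blk = blk, has_proj = has_proj))
}

gb_backward <- function(dout, cache, params, prefix, acc) {
  blk <- cache$blk
  # main path
  dmid <- gm_backward(dout, cache$g2, params, paste0(prefix, ".gm2"), acc)
  if (blk$stride == 2L) {
    bb <- bn_backward(dmid, params[[paste0(prefix, ".dwbn.gamma")]], cache$dwbn)
    acc_add(acc, paste0(prefix, ".dwbn.gamma"), bb$dgamma)
    acc_add(acc, paste0(prefix, ".dwbn.beta"), bb$dbeta)
    dwb <- dwconv_backward(bb$dx, params[[paste0(prefix, ".dw.W")]], cache$dw)
    acc_add(acc, paste0(prefix, ".dw.W"), dwb$dW)
    acc_add(acc, paste0(prefix, ".dw.b"), dwb$db)
    dmid <- dwb$dx
  }
  dx <- gm_backward(dmid, cache$g1, params, paste0(prefix, ".gm1"), acc)
  # shortcut path
  if (cache$has_proj) {
    bb <- bn_backward(dout, params[[paste0(prefix, ".scbn.gamma")]], cache$scbn)
    acc_add(acc, paste0(prefix, ".scbn.gamma"), bb$dgamma)
    acc_add(acc, paste0(prefix, ".scbn.beta"), bb$dbeta)
    cvb <- conv2d_backward(bb$dx, params[[paste0(prefix, ".sc.W")]], cache$sc)
    acc_add(acc, paste0(prefix, ".sc.W"), cvb$dW)
    acc_add(acc, paste0(prefix, ".sc.b"), cvb$db)
    dsc <- if (!is.null(cache$xs)) avgpool_backward(cvb$dx, cache$xs)
           else cvb$dx
    dx <- dx + dsc
  } else {
    dx <- dx + dout
  }
  dx
}

# ---- full network ----------------------------------------------------------

#' GhostNet classifier specification
#'
#' Stem convolution, a stack of ghost bottlenecks (identity shortcut at
#' stride 1, downsampling shortcut at stride 2), a pointwise head, global
#' average pooling and a softmax classification head. The default widths
#' (stem 16, bottlenecks 16/24/40/80) are desk-scale; the input side must
#' be divisible by the cumulative stride (4).
#'
#' @param in_channels input channel count.
#' @param num_classes output classes (2: healthy, patient).
#' @param stem stem convolution width.
#' @param blocks list of bottleneck descriptors
#'   `list(out =, exp =, stride =)`.
#' @param head pointwise head width.
#' @return list of class `pd_ghostnet_spec`.
#' @export
ghostnet_spec <- function(in_channels = 1L, num_classes = 2L, stem = 16L,
                          blocks = list(list(out = 16L, exp = 32L, stride = 1L),
                                        list(out = 24L, exp = 48L, stride = 2L),
                                        list(out = 40L, exp = 72L, stride = 1L),
                                        list(out = 80L, exp = 120L, stride = 2L)),
                          head = 128L) {
  ci <- stem
  for (i in seq_along(blocks)) {
    blocks[[i]]$ci <- ci
    ci <- blocks[[i]]$out
  }
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes), stem = as.integer(stem),
                 blocks = blocks, head = as.integer(head), final = ci),
            class = "pd_ghostnet_spec")
}

ghostnet_init <- function(spec = ghostnet_spec(), seed = 1L) {
  p <- list()
  st <- conv2d_init(spec$in_channels, spec$stem, 3L, "stem", seed)
  p[["stem.W"]] <- st$W; p[["stem.b"]] <- st$b
  p[["stembn.gamma"]] <- rep(1, spec$stem)
  p[["stembn.beta"]] <- numeric(spec$stem)
  for (i in seq_along(spec$blocks)) {
    blk <- spec$blocks[[i]]
    p <- c(p, gb_init(paste0("gb", i), blk$ci, blk$out, blk$exp, blk$stride,
                      derive_seed(seed, "gb", i)))
  }
  hd <- conv2d_init(spec$final, spec$head, 1L, "head", seed)
  p[["head.W"]] <- hd$W; p[["head.b"]] <- hd$b
  p[["headbn.gamma"]] <- rep(1, spec$head)
  p[["headbn.beta"]] <- numeric(spec$head)
  p[["fc.W"]] <- matrix(with_seed(seed, "fc", 0L,
                                  he_init(spec$num_classes * spec$head,
                                          spec$head)),
                        spec$num_classes, spec$head)
  p[["fc.b"]] <- numeric(spec$num_classes)
  list(params = p, state = new.env(parent = emptyenv()), spec = spec,
       arch = "ghostnet")
}

ghostnet_apply <- function(model, x, train = FALSE) {
  p <- model$params; st <- model$state; spec <- model$spec
  caches <- list()
  cv <- conv2d_forward(x, p[["stem.W"]], p[["stem.b"]])
  bn <- bn_forward(cv$out, p[["stembn.gamma"]], p[["stembn.beta"]], st,
                   "stembn", train)
  ac <- act_forward(bn$out, "relu")
  caches$stem <- list(cv = cv$cache, bn = bn$cache, ac = ac$cache)
  h <- ac$out
  for (i in seq_along(spec$blocks)) {
    gb <- gb_forward(h, spec$blocks[[i]], p, st, paste0("gb", i), train)
    caches[[paste0("gb", i)]] <- gb$cache
    h <- gb$out
  }
  cv2 <- conv2d_forward(h, p[["head.W"]], p[["head.b"]])
  bn2 <- bn_forward(cv2$out, p[["headbn.gamma"]], p[["headbn.beta"]], st,
                    "headbn", train)
  ac2 <- act_forward(bn2$out, "relu")
  gp <- global_avgpool_forward(ac2$out)
  fc <- dense_forward(gp$out, p[["fc.W"]], p[["fc.b"]])
  caches$head <- list(cv = cv2$cache, bn = bn2$cache, ac = ac2$cache,
                      gp = gp$cache, fc = fc$cache)
  list(logits = fc$out, caches = caches)
}

ghostnet_backprop <- function(model, caches, dlogits) {
  p <- model$params; spec <- model$spec
  acc <- new.env(parent = emptyenv())
  hd <- caches$head
  fb <- dense_backward(dlogits, p[["fc.W"]], hd$fc)
  acc_add(acc, "fc.W", fb$dW); acc_add(acc, "fc.b", fb$db)
  g <- global_avgpool_backward(fb$dx, hd$gp)
  g <- act_backward(g, hd$ac)
  bb <- bn_backward(g, p[["headbn.gamma"]], hd$bn)
  acc_add(acc, "headbn.gamma", bb$dgamma); acc_add(acc, "headbn.beta", bb$dbeta)
  cb <- conv2d_backward(bb$dx, p[["head.W"]], hd$cv)
  acc_add(acc, "head.W", cb$dW); acc_add(acc, "head.b", cb$db)
  g <- cb$dx
  for (i in rev(seq_along(spec$blocks))) {
    g <- gb_backward(g, caches[[paste0("gb", i)]], p, paste0("gb", i), acc)
  }
  g <- act_backward(g, caches$stem$ac)
  bb <- bn_backward(g, p[["stembn.gamma"]], caches$stem$bn)
  acc_add(acc, "stembn.gamma", bb$dgamma); acc_add(acc, "stembn.beta", bb$dbeta)
  cb <- conv2d_backward(bb$dx, p[["stem.W"]], caches$stem$cv)
  acc_add(acc, "stem.W", cb$dW); acc_add(acc, "stem.b", cb$db)
  as.list(acc)
}

#' Run the GhostNet branch on an input map
#'
#' Builds a seeded model (weights are a pure function of `seed`) and
#' returns the per-class probability scores `Gn^o`.
#'
#' @param input `(C, H, W, N)` array, or a matrix / `(H, W, C)` array for
#'   a single sample. The spatial side must be divisible by 4.
#' @param spec a [ghostnet_spec()].
#' @param seed weight seed.
#' @return matrix of class scores (`num_classes` x N), columns summing
#'   to 1; rows named `healthy`, `patient` for 2-class specs.
#' @export
ghostnet_forward <- function(input, spec = ghostnet_spec(), seed = 1L) {
  x <- as_nchw(input)
  check_pool_chain(dim(x)[2:3], 4L, "ghostnet")
  model <- ghostnet_init(spec, seed)
  scores_from_logits(ghostnet_apply(model, x, train = FALSE)$logits,
                     spec$num_classes)
}

check_pool_chain <- function(hw, divisor, what) {
  if (any(hw %% divisor != 0))
    stop(what, " needs spatial dimensions divisible by ", divisor,
         "; got ", hw[1], " x ", hw[2],
         " (pad the input map to a multiple of ", divisor, ")")
  invisible(TRUE)
}

scores_from_logits <- function(logits, num_classes) {
  s <- softmax_cols(logits)
  if (num_classes == 2L) rownames(s) <- c("healthy", "patient")
  s
}
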