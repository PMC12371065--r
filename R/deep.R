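#' Deep-feature configuration
#'
#' Backbone embeddings of the pre-processed drawing: a VGG16-style
#' encoder (13 convolution layers in five blocks, 64 to 512 channels,
#' max-pooled between blocks) yielding a 512-length embedding, and/or a
#' ResNet-50-style encoder (bottleneck residual stages 256/512/1024/2048)
#' yielding a 2048-length embedding, each truncated at global average
#' pooling. Weights default to seeded random initialisation (so the
#' feature extractor is deterministic and self-contained); a pretrained
#' weights file can be supplied instead and is required to exist in that
#' mode.
#'
#' @param backbones subset of `c("vgg16", "resnet50")`.
#' @param input_size square input side fed to the backbone (a multiple
#'   of 32).
#' @param weights_mode `"random-seeded"` or `"pretrained-file"`.
#' @param weights_file RDS file with named weight arrays (pretrained
#'   mode only).
#' @param seed weight seed for random mode.
#' @return list of class `pd_deep_config`.
#' @export
deep_config <- function(backbones = c("resnet50", "vgg16"), input_size = 64L,
                        weights_mode = c("random-seeded", "pretrained-file"),
                        weights_file = NULL, seed = 1L) {
  weights_mode <- match.arg(weights_mode)
  backbones <- match.arg(backbones, c("vgg16", "resnet50"), several.ok = TRUE)
  if (input_size %% 32 != 0) stop("input_size must be a multiple of 32")
  if (weights_mode == "pretrained-file" &&
      (is.null(weights_file) || !file.exists(weights_file)))
    stop("pretrained weights file not found: ",
         if (is.null(weights_file)) "<missing path>" else weights_file)
  structure(list(backbones = backbones, input_size = as.integer(input_size),
                 weights_mode = weights_mode, weights_file = weights_file,
                 seed = as.integer(seed)),
            class = "pd_deep_config")
}

VGG16_BLOCKS <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                     c(512, 512, 512), c(512, 512, 512))
RESNET50_STAGES <- list(list(n = 3L, out = 256L, stride = 1L),
                        list(n = 4L, out = 512L, stride = 2L),
                        list(n = 6L, out = 1024L, stride = 2L),
                        list(n = 3L, out = 2048L, stride = 2L))

vgg16_init <- function(seed) {
  p <- list()
  ci <- 3L
  li <- 0L
  for (blk in VGG16_BLOCKS) for (co in blk) {
    li <- li + 1L
    cv <- conv2d_init(ci, co, 3L, paste0("vgg", li), seed)
    p[[paste0("vgg", li, ".W")]] <- cv$W
    p[[paste0("vgg", li, ".b")]] <- cv$b
    ci <- co
  }
  p
}

vgg16_embed <- function(x, p) {
  li <- 0L
  for (blk in VGG16_BLOCKS) {
    for (co in blk) {
      li <- li + 1L
      x <- act_forward(conv2d_forward(x, p[[paste0("vgg", li, ".W")]],
                                      p[[paste0("vgg", li, ".b")]])$out,
                       "relu")$out
    }
    x <- maxpool_forward(x, 2L, 2L)$out
  }
  global_avgpool_forward(x)$out
}

resnet50_init <- function(seed) {
  p <- list()
  st <- conv2d_init(3L, 64L, 7L, "stem", seed)
  p[["stem.W"]] <- st$W; p[["stem.b"]] <- st$b
  ci <- 64L
  for (s in seq_along(RESNET50_STAGES)) {
    stage <- RESNET50_STAGES[[s]]
    mid <- stage$out %/% 4L
    for (b in seq_len(stage$n)) {
      pre <- paste0("r", s, "b", b)
      sd <- derive_seed(seed, pre)
      c1 <- conv2d_init(ci, mid, 1L, paste0(pre, "c1"), sd)
      c2 <- conv2d_init(mid, mid, 3L, paste0(pre, "c2"), sd)
      c3 <- conv2d_init(mid, stage$out, 1L, paste0(pre, "c3"), sd)
      p[[paste0(pre, ".c1.W")]] <- c1$W; p[[paste0(pre, ".c1.b")]] <- c1$b
      p[[paste0(pre, ".c2.W")]] <- c2$W; p[[paste0(pre, ".c2.b")]] <- c2$b
      p[[paste0(pre, ".c3.W")]] <- c3$W; p[[paste0(pre, ".c3.b")]] <- c3$b
      if (b == 1L) {
        pj <- conv2d_init(ci, stage$out, 1L, paste0(pre, "proj"), sd)
        p[[paste0(pre, ".proj.W")]] <- pj$W
        p[[paste0(pre, ".proj.b")]] <- pj$b
      }
      ci <- stage$out
    }
  }
  p
}

resnet50_embed <- function(x, p) {
  x <- act_forward(conv2d_forward(x, p[["stem.W"]], p[["stem.b"]],
                                  stride = 2L, pad = 3L)$out, "relu")$out
  x <- maxpool_forward(x, 3L, 2L, 1L)$out
  for (s in seq_along(RESNET50_STAGES)) {
    stage <- RESNET50_STAGES[[s]]
    for (b in seq_len(stage$n)) {
      pre <- paste0("r", s, "b", b)
      stride <- if (b == 1L) stage$stride else 1L
      h <- act_forward(conv2d_forward(x, p[[paste0(pre, ".c1.W")]],
                                      p[[paste0(pre, ".c1.b")]])$out,
                       "relu")$out
      h <- act_forward(conv2d_forward(h, p[[paste0(pre, ".c2.W")]],
                                      p[[paste0(pre, ".c2.b")]],
                                      stride = stride)$out, "relu")$out
      h <- conv2d_forward(h, p[[paste0(pre, ".c3.W")]],
                          p[[paste0(pre, ".c3.b")]])$out
      short <- if (b == 1L)
        conv2d_forward(x, p[[paste0(pre, ".proj.W")]],
                       p[[paste0(pre, ".proj.b")]], stride = stride,
                       pad = 0L)$out
      else x
      x <- act_forward(h + short, "relu")$out
    }
  }
  global_avgpool_forward(x)$out
}

.pdhand_cache <- new.env(parent = emptyenv())

backbone_weights <- function(backbone, config) {
  if (config$weights_mode == "pretrained-file") {
    w <- readRDS(config$weights_file)
    if (is.null(w[[backbone]])) stop("weights file lacks backbone '", backbone, "'")
    return(w[[backbone]])
  }
  key <- paste0(backbone, "-", config$seed)
  if (is.null(.pdhand_cache[[key]])) {
    sd <- derive_seed(config$seed, backbone)
    .pdhand_cache[[key]] <- switch(backbone,
                                   vgg16 = vgg16_init(sd),
                                   resnet50 = resnet50_init(sd))
  }
  .pdhand_cache[[key]]
}

#' Deep-feature embedding of one image
#'
#' Resizes the image to the configured input side, replicates the
#' grayscale channel to RGB, runs the configured backbone(s) and
#' concatenates their global-pooled embeddings (VGG16 contributes 512
#' dimensions, ResNet-50 2048; both enabled give 2560).
#'
#' @param image grayscale matrix in `[0, 255]`.
#' @param config a [deep_config()].
#' @return numeric embedding vector.
#' @export
deep_features <- function(image, config = deep_config()) {
  img <- EBImage::imageData(EBImage::resize(EBImage::Image(image / 255),
                                            config$input_size,
                                            config$input_size))
  x <- array(0, c(3L, dim(img), 1L))
  for (c_i in 1:3) x[c_i, , , 1] <- img
  out <- numeric(0)
  for (bb in config$backbones) {
    w <- backbone_weights(bb, config)
    emb <- switch(bb, vgg16 = vgg16_embed(x, w), resnet50 = resnet50_embed(x, w))
    out <- c(out, as.numeric(emb))
  }
  out
}

#' Embedding length of a deep-feature configuration
#'
#' @param config a [deep_config()].
#' @return integer total embedding length.
#' @export
deep_feature_length <- function(config = deep_config()) {
  sum(vapply(config$backbones,
             function(b) switch(b, vgg16 = 512L, resnet50 = 2048L), integer(1)))
}
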