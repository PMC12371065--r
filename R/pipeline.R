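#' Feature-extraction configuration for the detection pipeline
#'
#' Every image is pre-processed with the modified Wiener filter, then
#' described by the modified PHOG descriptor and the contour shape
#' features; deep backbone embeddings are appended when `backbones` is
#' non-empty. The default (PHOG levels 2, 8 orientation bins, no
#' backbones) gives a 168 + 5 = 173-length fused vector.
#'
#' @param phog_levels,phog_bins PHOG pyramid depth and orientation bins.
#' @param angle_mode orientation folding, `"unsigned"` or `"signed"`.
#' @param entropy_bins histogram bins of the improved entropy.
#' @param wiener a [wiener_config()].
#' @param backbones deep backbones to append (empty by default).
#' @param deep a [deep_config()] used when `backbones` is non-empty.
#' @return list of class `pd_feature_config`.
#' @export
feature_config <- function(phog_levels = 2L, phog_bins = 8L,
                           angle_mode = "unsigned", entropy_bins = 8L,
                           wiener = wiener_config(), backbones = character(0),
                           deep = NULL) {
  if (length(backbones) && is.null(deep))
    deep <- deep_config(backbones = backbones)
  structure(list(phog_levels = as.integer(phog_levels),
                 phog_bins = as.integer(phog_bins), angle_mode = angle_mode,
                 entropy_bins = as.integer(entropy_bins), wiener = wiener,
                 backbones = backbones, deep = deep),
            class = "pd_feature_config")
}

#' Extract fused features for every image in a manifest
#'
#' Runs modified-Wiener pre-processing, modified PHOG, shape features and
#' (optionally) deep embeddings per image, then fuses and standardises
#' the segments with [fuse_features()]. Pass the training call's
#' `$layout` when extracting test features so both share the training
#' standardisation.
#'
#' @param manifest a `pd_manifest`.
#' @param config a [feature_config()].
#' @param layout optional layout from the training extraction.
#' @return a `pd_fused_features` with extra fields `labels` and `paths`.
#' @export
extract_features <- function(manifest, config = feature_config(),
                             layout = NULL) {
  stopifnot(nrow(manifest) > 0)
  n <- nrow(manifest)
  phog_list <- vector("list", n)
  shape_m <- matrix(0, n, 5L)
  deep_m <- if (length(config$backbones))
    matrix(0, n, deep_feature_length(config$deep)) else NULL
  for (i in seq_len(n)) {
    img <- read_gray(manifest$path[i])
    hip <- modified_wiener(img, config$wiener)
    field <- modified_gradients(hip, bins = config$entropy_bins)
    phog_list[[i]] <- phog(field, levels = config$phog_levels,
                           bins = config$phog_bins,
                           angle_mode = config$angle_mode)
    shape_m[i, ] <- shape_vector(shape_features(hip))
    if (!is.null(deep_m)) deep_m[i, ] <- deep_features(hip, config$deep)
  }
  fused <- fuse_features(do.call(rbind, phog_list), shape_m, deep_m, layout)
  fused$labels <- manifest$label
  fused$paths <- manifest$path
  fused
}

#' Training configuration for the hybrid classifier
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed master seed (weights, shuffling).
#' @param gnet_spec,iln_spec network specifications (defaults are the
#'   desk-scale widths).
#' @return list of class `pd_train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 16L, learning_rate = 1e-3,
                         seed = 1L, gnet_spec = ghostnet_spec(),
                         iln_spec = ilinknet_spec()) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 gnet_spec = gnet_spec, iln_spec = iln_spec),
            class = "pd_train_config")
}

# side of the square map a length-F feature vector is tiled onto
# (zero-padded; divisible by the networks' pooling chain)
feature_map_side <- function(n_features, divisor = 4L) {
  s <- ceiling(sqrt(n_features))
  as.integer(s + (divisor - s %% divisor) %% divisor)
}

# tile standardised feature rows into a (1, side, side, N) input array
feature_maps <- function(x, side = feature_map_side(ncol(x))) {
  n <- nrow(x)
  out <- array(0, c(1L, side, side, n))
  for (i in seq_len(n)) {
    v <- numeric(side * side)
    v[seq_len(ncol(x))] <- x[i, ]
    out[1L, , , i] <- matrix(v, side, side)
  }
  out
}

label_int <- function(labels) match(labels, LABELS)  # healthy=1, patient=2

train_one_network <- function(arch, spec, x, y, config) {
  model <- switch(arch,
                  ghostnet = ghostnet_init(spec, derive_seed(config$seed, "gnet")),
                  ilinknet = ilinknet_init(spec, derive_seed(config$seed, "iln")))
  apply_fn <- switch(arch, ghostnet = ghostnet_apply, ilinknet = ilinknet_apply)
  back_fn <- switch(arch, ghostnet = ghostnet_backprop, ilinknet = ilinknet_backprop)
  opt <- adam_init(model$params)
  n <- dim(x)[4]
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(config$seed, paste0("shuffle-", arch), ep, sample.int(n))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      fwd <- apply_fn(model, xb, train = TRUE)
      ce <- softmax_ce(fwd$logits, y[idx])
      if (!is.finite(ce$loss))
        stop(arch, " training diverged (non-finite loss) at epoch ", ep)
      grads <- back_fn(model, fwd$caches, ce$dlogits)
      step <- adam_step(model$params, grads, opt, lr = config$learning_rate)
      model$params <- step$params
      opt <- step$state
      ep_loss <- ep_loss + ce$loss
      nb <- nb + 1L
    }
    losses[ep] <- ep_loss / nb
  }
  list(model = model, loss = losses)
}

#' Train the hybrid detector on a manifest
#'
#' Extracts fused features from the training manifest, tiles them onto
#' square single-channel maps, and trains the GhostNet and improved
#' LinkNet branches independently with cross-entropy and Adam. The
#' returned object carries both branch weights, the feature layout
#' (standardisation statistics), and the per-epoch loss logs; it is fully
#' reproducible from the config seed.
#'
#' @param manifest training `pd_manifest` (both classes present).
#' @param config a [train_config()].
#' @param features a [feature_config()].
#' @return list of class `pd_hybrid_model`.
#' @export
train_hybrid <- function(manifest, config = train_config(),
                         features = feature_config()) {
  if (length(unique(manifest$label)) < 2)
    stop("training manifest must contain both classes")
  fused <- extract_features(manifest, features)
  fit_hybrid(fused$x, manifest$label, config, layout = fused$layout,
             features = features)
}

#' Train the hybrid detector on a prepared feature matrix
#'
#' Lower-level entry point of [train_hybrid()] for already-extracted
#' (standardised) features.
#'
#' @param x numeric matrix (samples x features), standardised.
#' @param labels character labels.
#' @param config a [train_config()].
#' @param layout optional feature layout to store for later extraction.
#' @param features optional [feature_config()] to store.
#' @return list of class `pd_hybrid_model` with elements `gnet`, `iln`
#'   (trained models), `side`, `layout`, `features`, `history`.
#' @export
fit_hybrid <- function(x, labels, config = train_config(), layout = NULL,
                       features = NULL) {
  y <- label_int(labels)
  if (anyNA(y)) stop("labels must be 'healthy' or 'patient'")
  side <- feature_map_side(ncol(x))
  maps <- feature_maps(x, side)
  gn <- train_one_network("ghostnet", config$gnet_spec, maps, y, config)
  il <- train_one_network("ilinknet", config$iln_spec, maps, y, config)
  structure(list(gnet = gn$model, iln = il$model, side = side,
                 layout = layout, features = features, config = config,
                 history = list(ghostnet = gn$loss, ilinknet = il$loss)),
            class = "pd_hybrid_model")
}

#' Score samples with the hybrid detector
#'
#' @param model a `pd_hybrid_model`.
#' @param x standardised feature matrix (samples x features).
#' @return list with score matrices `iln`, `gnet`, `fused` (classes x
#'   samples) and the character vector `predicted`.
#' @export
predict_hybrid <- function(model, x) {
  maps <- feature_maps(x, model$side)
  gl <- ghostnet_apply(model$gnet, maps, train = FALSE)$logits
  il <- ilinknet_apply(model$iln, maps, train = FALSE)$logits
  gs <- scores_from_logits(gl, 2L)
  is <- scores_from_logits(il, 2L)
  fused <- fuse_scores(is, gs)
  list(iln = is, gnet = gs, fused = fused,
       predicted = LABELS[apply(fused, 2, which.max)])
}

#' Evaluate a trained hybrid detector on a test manifest
#'
#' Extracts features with the training layout, scores the samples, and
#' assembles the full report: confusion matrix, classification metrics
#' and ROC/AUC of the fused scores (branch scores are reported too).
#'
#' @param manifest test `pd_manifest` (non-empty).
#' @param model a `pd_hybrid_model` from [train_hybrid()].
#' @return list of class `pd_evaluation` with `metrics`, `confusion`,
#'   `roc`, `scores`, `labels`.
#' @export
evaluate_hybrid <- function(manifest, model) {
  stopifnot(nrow(manifest) > 0)
  fused <- extract_features(manifest, model$features %||% feature_config(),
                            layout = model$layout)
  sc <- predict_hybrid(model, fused$x)
  report_scores(sc, manifest$label)
}

#' Assemble an evaluation report from scores and labels
#'
#' @param sc score list from [predict_hybrid()].
#' @param labels true labels.
#' @return a `pd_evaluation`.
#' @export
report_scores <- function(sc, labels) {
  cm <- confusion(sc$predicted, labels)
  structure(list(metrics = classification_metrics(cm), confusion = cm,
                 roc = roc_curve(sc$fused["patient", ], labels),
                 scores = sc, labels = labels),
            class = "pd_evaluation")
}

#' Serialise an evaluation report as JSON
#'
#' Keys: the ten metric names, `auc`, and `confusion` with `tp`, `fp`,
#' `fn`, `tn`. Undefined metrics serialise as `null`.
#'
#' @param evaluation a `pd_evaluation`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(evaluation, path) {
  m <- evaluation$metrics
  out <- list(accuracy = m$accuracy, sensitivity = m$sensitivity,
              specificity = m$specificity, precision = m$precision,
              f_measure = m$f_measure, mcc = m$mcc, npv = m$npv,
              fpr = m$fpr, fnr = m$fnr, fdr = m$fdr,
              auc = evaluation$roc$auc,
              confusion = evaluation$confusion[c("tp", "fp", "fn", "tn")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Save / load a trained hybrid model
#'
#' Stores weights, running statistics and configuration in one RDS file.
#'
#' @param model a `pd_hybrid_model`.
#' @param path RDS file path.
#' @return `save_hybrid` returns `path` invisibly; `load_hybrid` the
#'   restored model.
#' @export
save_hybrid <- function(model, path) {
  freeze <- function(m) {
    m$state <- as.list(m$state)
    m
  }
  obj <- model
  obj$gnet <- freeze(obj$gnet)
  obj$iln <- freeze(obj$iln)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_hybrid
#' @export
load_hybrid <- function(path) {
  obj <- readRDS(path)
  thaw <- function(m) {
    m$state <- list2env(m$state, parent = emptyenv())
    m
  }
  obj$gnet <- thaw(obj$gnet)
  obj$iln <- thaw(obj$iln)
  obj
}

#' Logistic baseline on the simulator's tremor statistic
#'
#' Fits `patient ~ radial_dev` on the training manifest and reports
#' held-out accuracy — the single-feature reference the hybrid detector
#' is expected to at least match on synthetic data.
#'
#' @param train,test `pd_manifest`s carrying the `radial_dev` column from
#'   [generate_dataset()].
#' @return held-out accuracy in `[0, 1]`.
#' @export
baseline_radial_accuracy <- function(train, test) {
  stopifnot(!is.null(train$radial_dev), !is.null(test$radial_dev))
  # perfect separation is routine at the default effect sizes; the
  # non-convergence warning glm emits for it is expected
  fit <- suppressWarnings(glm(I(label == "patient") ~ radial_dev, binomial(),
                              data = as.data.frame(train)))
  p <- suppressWarnings(predict(fit, newdata = as.data.frame(test),
                                type = "response"))
  mean((p > 0.5) == (test$label == "patient"))
}

#' Run the scaled-down synthetic detection experiment
#'
#' Generates a balanced synthetic dataset at the default effect sizes,
#' splits it (stratified), trains the hybrid detector and evaluates it on
#' the held-out fraction, alongside the single-feature logistic baseline.
#'
#' @param n_per_class drawings per class.
#' @param seed master seed.
#' @param train_fraction training share ("TD").
#' @param config a [train_config()] (its seed is overridden by `seed`).
#' @param features a [feature_config()].
#' @param image_size synthetic drawing side, pixels.
#' @param out_dir where the drawings are written.
#' @return list with `model`, `evaluation`, `baseline_accuracy`,
#'   `split`, `manifest`.
#' @export
run_synthetic_experiment <- function(n_per_class = 200L, seed = 1L,
                                     train_fraction = 0.9,
                                     config = train_config(),
                                     features = feature_config(),
                                     image_size = 96L,
                                     out_dir = tempfile("pdhand")) {
  specs <- list(drawing_spec("spiral", image_size = image_size),
                drawing_spec("meander", image_size = image_size))
  man <- generate_dataset(n_per_class, seed = derive_seed(seed, "data"),
                          specs = specs, out_dir = out_dir)
  sp <- split_manifest(man, split_spec(train_fraction,
                                       seed = derive_seed(seed, "split")))
  # re-attach the simulator statistic (split keeps manifest columns only)
  sp$train$radial_dev <- man$radial_dev[match(sp$train$path, man$path)]
  sp$test$radial_dev <- man$radial_dev[match(sp$test$path, man$path)]
  config$seed <- derive_seed(seed, "train")
  model <- train_hybrid(sp$train, config, features)
  ev <- evaluate_hybrid(sp$test, model)
  list(model = model, evaluation = ev,
       baseline_accuracy = baseline_radial_accuracy(sp$train, sp$test),
       split = sp, manifest = man)
}
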