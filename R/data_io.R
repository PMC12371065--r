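#' @section Dataset manifests:
#' A manifest is a plain `data.frame` (class `pd_manifest`) with one row
#' per image and columns `exam_id`, `image_id`, `pattern`, `label`,
#' `path`, `provenance`, `augmentation_op`, `aug_index`. `exam_id` and
#' `image_id` follow the `ID_EXAM-ID_IMAGE.jpg` naming convention of the
#' public HandPD spiral/meander sets; `aug_index` is 0 for original images
#' and 1,2,... for augmented copies of the same original.
#' @name manifest
NULL

MANIFEST_COLS <- c("exam_id", "image_id", "pattern", "label", "path",
                   "provenance", "augmentation_op", "aug_index")
PATTERNS <- c("spiral", "meander")
LABELS <- c("healthy", "patient")
AUG_OPS <- c("rotation", "translation", "shearing")

#' Parse a HandPD-style image filename
#'
#' Filenames follow `ID_EXAM-ID_IMAGE.ext`, e.g. `"103-4.jpg"`, where the
#' first integer identifies the exam (subject visit) and the second the
#' repetition of the drawing within that exam.
#'
#' @param name filename (directories are stripped).
#' @return list with integer components `exam_id` and `image_id`.
#' @export
#' @examples
#' parse_filename("103-4.jpg")
parse_filename <- function(name) {
  base <- basename(name)
  stem <- sub("\\.[A-Za-z0-9]+$", "", base)
  parts <- strsplit(stem, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(grepl("^[0-9]+$", parts))) {
    stop("malformed HandPD filename '", base,
         "': expected '<exam>-<image>.<ext>' with integer identifiers, got token '",
         stem, "'")
  }
  list(exam_id = as.integer(parts[[1]]), image_id = as.integer(parts[[2]]))
}

#' Format a HandPD-style image filename
#'
#' Inverse of [parse_filename()].
#'
#' @param exam_id,image_id non-negative integers.
#' @param ext file extension without the dot.
#' @return filename string.
#' @export
format_filename <- function(exam_id, image_id, ext = "jpg") {
  stopifnot(exam_id >= 0, image_id >= 1)
  sprintf("%d-%d.%s", as.integer(exam_id), as.integer(image_id), ext)
}

new_manifest <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(records))
  if ("aug_index" %in% missing && nrow(records) > 0) records$aug_index <- 0L
  if ("aug_index" %in% missing && nrow(records) == 0) records$aug_index <- integer(0)
  missing <- setdiff(MANIFEST_COLS, names(records))
  if (length(missing)) stop("manifest missing columns: ", paste(missing, collapse = ", "))
  records <- records[, MANIFEST_COLS]
  validate_manifest(records)
  class(records) <- c("pd_manifest", "data.frame")
  records
}

validate_manifest <- function(records) {
  if (nrow(records) == 0) return(invisible(TRUE))
  stopifnot(all(records$exam_id >= 0), all(records$image_id >= 1),
            all(records$pattern %in% PATTERNS),
            all(records$label %in% LABELS),
            all(records$provenance %in% c("original", "augmented")),
            all(records$aug_index >= 0))
  key <- with(records, paste(exam_id, image_id, pattern, provenance, aug_index))
  if (anyDuplicated(key)) stop("duplicate manifest keys: ", key[duplicated(key)][1])
  aug <- records$provenance == "augmented"
  if (any(aug & is.na(records$augmentation_op)))
    stop("augmented records must carry an augmentation_op")
  invisible(TRUE)
}

#' Class and pattern tallies of a manifest
#'
#' @param manifest a `pd_manifest`.
#' @return list with `class_counts` and `pattern_counts` named integer vectors.
#' @export
manifest_counts <- function(manifest) {
  list(
    class_counts = vapply(LABELS, function(l) sum(manifest$label == l), integer(1)),
    pattern_counts = vapply(PATTERNS, function(p) sum(manifest$pattern == p), integer(1))
  )
}

#' Build a dataset manifest from a directory tree
#'
#' Scans per-class subdirectories of `root` for image files named in the
#' HandPD `ID_EXAM-ID_IMAGE.ext` convention and assembles a manifest.
#' Files whose names cannot be parsed are skipped with a warning.
#'
#' @param root directory containing one subdirectory per class.
#' @param label_map named character vector mapping subdirectory name to
#'   label (`"healthy"` or `"patient"`).
#' @param pattern drawing pattern for all records (`"spiral"` or
#'   `"meander"`), or a named vector mapping subdirectory to pattern.
#' @return a `pd_manifest`.
#' @export
build_manifest <- function(root, label_map, pattern = "spiral") {
  stopifnot(dir.exists(root), length(label_map) > 0, !is.null(names(label_map)))
  rows <- list()
  for (sub in names(label_map)) {
    dirpath <- file.path(root, sub)
    files <- if (dir.exists(dirpath))
      list.files(dirpath, pattern = "\\.(jpg|jpeg|png)$", ignore.case = TRUE,
                 full.names = TRUE)
    else character(0)
    pat <- if (length(pattern) > 1L) unname(pattern[[sub]]) else pattern
    for (f in files) {
      ids <- tryCatch(parse_filename(f), error = function(e) {
        warning("skipping unparseable file ", basename(f), ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(ids)) next
      rows[[length(rows) + 1L]] <- data.frame(
        exam_id = ids$exam_id, image_id = ids$image_id, pattern = pat,
        label = unname(label_map[[sub]]), path = f, provenance = "original",
        augmentation_op = NA_character_, aug_index = 0L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no images found under ", root, ": returning an empty manifest")
    return(new_manifest(data.frame(
      exam_id = integer(0), image_id = integer(0), pattern = character(0),
      label = character(0), path = character(0), provenance = character(0),
      augmentation_op = character(0), aug_index = integer(0))))
  }
  new_manifest(do.call(rbind, rows))
}

#' Augmentation specification
#'
#' `multiplier_per_class` counts total copies per original including the
#' original itself; the defaults (healthy x9, patient x2) expand the
#' 72 + 296 originals of one HandPD drawing pattern to the published
#' post-augmentation sizes 648 + 592 = 1240.
#'
#' @param multiplier_per_class named integer vector (labels to multipliers,
#'   each >= 1).
#' @param rotation_range max absolute rotation, degrees.
#' @param translation_range max absolute translation, as a fraction of the
#'   image side.
#' @param shear_range max absolute shear, degrees.
#' @param seed integer seed for transform sampling.
#' @return list of class `pd_augmentation_spec`.
#' @export
augmentation_spec <- function(multiplier_per_class = c(healthy = 9L, patient = 2L),
                              rotation_range = 15, translation_range = 0.1,
                              shear_range = 10, seed = 1L) {
  if (any(multiplier_per_class < 1)) stop("augmentation multipliers must be >= 1")
  stopifnot(rotation_range >= 0, translation_range >= 0, shear_range >= 0)
  structure(list(multiplier_per_class = multiplier_per_class,
                 rotation_range = rotation_range,
                 translation_range = translation_range,
                 shear_range = shear_range, seed = as.integer(seed)),
            class = "pd_augmentation_spec")
}

# Apply one sampled geometric jitter to a [0,1] grayscale matrix.
# Background fills with white (1), matching paper-form drawings.
apply_augmentation <- function(img, op, magnitude) {
  x <- EBImage::Image(img)
  out <- switch(op,
    rotation = EBImage::rotate(x, magnitude, output.dim = dim(img), bg.col = 1),
    translation = EBImage::translate(x, magnitude * dim(img), bg.col = 1),
    shearing = {
      sh <- tan(magnitude * pi / 180)
      m <- matrix(c(1, sh, 0, 0, 1, 0), nrow = 3)
      EBImage::affine(x, m, output.dim = dim(img), bg.col = 1)
    },
    stop("unknown augmentation op: ", op))
  pmin(pmax(EBImage::imageData(out), 0), 1)
}

#' Augment a dataset class-wise
#'
#' Each original record of label l yields `multiplier_per_class[l]`
#' records in total: the original plus multiplier - 1 geometrically
#' jittered copies (rotation, translation or shearing, drawn uniformly
#' from the spec's ranges, deterministically from the spec seed). When
#' `write_images` is TRUE the transformed images are written as 8-bit PNG
#' under `out_dir`.
#'
#' @param manifest a `pd_manifest` of original records.
#' @param spec a [augmentation_spec()].
#' @param out_dir directory for augmented images (created if needed).
#' @param write_images write transformed PNGs (set FALSE for count-level
#'   bookkeeping, e.g. when planning storage).
#' @return the augmented `pd_manifest`.
#' @export
augment_dataset <- function(manifest, spec, out_dir = tempfile("aug"),
                            write_images = TRUE) {
  stopifnot(inherits(spec, "pd_augmentation_spec"))
  labels_present <- unique(manifest$label)
  if (!all(labels_present %in% names(spec$multiplier_per_class)))
    stop("multiplier undefined for label(s): ",
         paste(setdiff(labels_present, names(spec$multiplier_per_class)), collapse = ", "))
  if (write_images && nrow(manifest) > 0) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(manifest)
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    mult <- spec$multiplier_per_class[[rec$label]]
    if (mult <= 1) next
    img <- if (write_images) read_gray(rec$path) / 255 else NULL
    for (k in seq_len(mult - 1L)) {
      draws <- with_seed(spec$seed, "augment", derive_seed(i, "rec", k), {
        op <- sample(AUG_OPS, 1L)
        mag <- switch(op,
          rotation = runif(1, -spec$rotation_range, spec$rotation_range),
          translation = runif(2, -spec$translation_range, spec$translation_range),
          shearing = runif(1, -spec$shear_range, spec$shear_range))
        list(op = op, mag = mag)
      })
      path <- file.path(out_dir, sprintf("%d-%d_%s_aug%d.png",
                                         rec$exam_id, rec$image_id, rec$pattern, k))
      if (write_images) {
        png::writePNG(apply_augmentation(img, draws$op, draws$mag), path)
      }
      out <- rec
      out$path <- path
      out$provenance <- "augmented"
      out$augmentation_op <- draws$op
      out$aug_index <- k
      rows[[length(rows) + 1L]] <- out
    }
  }
  new_manifest(do.call(rbind, rows))
}

#' Split specification
#'
#' @param train_fraction fraction of records assigned to training, in (0,1).
#'   The published evaluation sweeps 0.60-0.90 ("TD", training-data
#'   percentage).
#' @param stratify preserve per-class proportions (default TRUE).
#' @param seed integer seed.
#' @return list of class `pd_split_spec`.
#' @export
split_spec <- function(train_fraction = 0.9, stratify = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, stratify = isTRUE(stratify),
                 seed = as.integer(seed)),
            class = "pd_split_spec")
}

#' Split a manifest into train and test partitions
#'
#' The partition is disjoint and exhaustive; under stratification each
#' class contributes `round(train_fraction * n_class)` records to training
#' (rounding ties toward the training set) and the split is reproducible
#' from the spec seed.
#'
#' @param manifest a non-empty `pd_manifest`.
#' @param spec a [split_spec()].
#' @return list with `pd_manifest` elements `train` and `test`.
#' @export
split_manifest <- function(manifest, spec) {
  stopifnot(inherits(spec, "pd_split_spec"), nrow(manifest) > 0)
  idx_train <- integer(0)
  groups <- if (spec$stratify) split(seq_len(nrow(manifest)), manifest$label)
            else list(all = seq_len(nrow(manifest)))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (spec$stratify && length(g) < 2)
      stop("stratified split needs at least 2 records per class; a class has ",
           length(g))
    n_tr <- floor(spec$train_fraction * length(g) + 0.5)  # ties toward train
    n_tr <- max(1L, min(length(g) - 1L, n_tr))
    picked <- with_seed(spec$seed, "split", gi, sample(g, n_tr))
    idx_train <- c(idx_train, picked)
  }
  idx_train <- sort(idx_train)
  list(train = new_manifest(manifest[idx_train, , drop = FALSE]),
       test = new_manifest(manifest[setdiff(seq_len(nrow(manifest)), idx_train), ,
                                    drop = FALSE]))
}

#' Write / read a manifest as CSV
#'
#' Round-trips are lossless (fixed header, no row names).
#'
#' @param manifest a `pd_manifest`.
#' @param path CSV file path.
#' @return `read_manifest` returns a `pd_manifest`; `write_manifest`
#'   returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest)[, MANIFEST_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(exam_id = "integer", image_id = "integer",
                                pattern = "character", label = "character",
                                path = "character", provenance = "character",
                                augmentation_op = "character",
                                aug_index = "integer"))
  new_manifest(df)
}

#' Read an image as a grayscale intensity matrix
#'
#' Reads PNG directly and other formats through EBImage; multi-channel
#' images are averaged to one channel. Values are returned on `[0, 255]`.
#'
#' @param path image file.
#' @return numeric matrix (rows x cols) in `[0, 255]`.
#' @export
read_gray <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))
  }
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  a * 255
}

#' Write a grayscale intensity matrix as 8-bit PNG
#'
#' @param img numeric matrix in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
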