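tiny_png <- function(path, size = 8L) {
  png::writePNG(matrix(1, size, size), path)
  path
}

make_tree <- function(n_healthy, n_patient, patterns = "spiral") {
  root <- tempfile("tree")
  for (sub in c("healthy", "patient")) dir.create(file.path(root, sub),
                                                  recursive = TRUE)
  img <- matrix(1, 8, 8)
  k <- 0L
  for (pat in patterns) {
    for (i in seq_len(n_healthy))
      png::writePNG(img, file.path(root, "healthy",
                                   sprintf("%d-%d.png", i + k, 1L)))
    for (i in seq_len(n_patient))
      png::writePNG(img, file.path(root, "patient",
                                   sprintf("%d-%d.png", n_healthy + i + k, 1L)))
    k <- k + n_healthy + n_patient
  }
  root
}

test_that("filename parsing follows the ID_EXAM-ID_IMAGE convention", {
  expect_equal(parse_filename("103-4.jpg"), list(exam_id = 103L, image_id = 4L))
  expect_equal(parse_filename("0-1.jpg"), list(exam_id = 0L, image_id = 1L))
  expect_equal(parse_filename("some/dir/12-3.png"),
               list(exam_id = 12L, image_id = 3L))
  expect_equal(parse_filename(format_filename(12, 3, "png")),
               list(exam_id = 12L, image_id = 3L))
  expect_error(parse_filename("spiral_A.jpg"), "spiral_A")
  expect_error(parse_filename("1-2-3.jpg"), "malformed")
})

test_that("manifests tally the class structure of a directory tree", {
  root <- make_tree(72, 296)
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))
  cnt <- manifest_counts(man)
  expect_equal(unname(cnt$class_counts["healthy"]), 72L)
  expect_equal(unname(cnt$class_counts["patient"]), 296L)
  expect_equal(nrow(man), 368L)

  empty <- tempfile("empty")
  dir.create(file.path(empty, "healthy"), recursive = TRUE)
  expect_warning(m0 <- build_manifest(empty, c(healthy = "healthy")), "empty")
  expect_equal(nrow(m0), 0L)
})

test_that("a two-pattern tree of 92 subjects x 4 repetitions gives 736 records", {
  root <- tempfile("tree736")
  for (sub in c("healthy", "patient")) dir.create(file.path(root, sub),
                                                  recursive = TRUE)
  img <- matrix(1, 8, 8)
  # 18 healthy + 74 patient subjects, 4 repetitions, 2 patterns
  for (pat in c("spiral", "meander")) {
    off <- if (pat == "spiral") 0L else 1000L
    for (s in 1:18) for (r in 1:4)
      png::writePNG(img, file.path(root, "healthy",
                                   sprintf("%d-%d.png", off + s, r)))
    for (s in 19:92) for (r in 1:4)
      png::writePNG(img, file.path(root, "patient",
                                   sprintf("%d-%d.png", off + s, r)))
  }
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))
  expect_equal(nrow(man), 736L)
})

test_that("class-wise augmentation reproduces the published counts", {
  root <- make_tree(72, 296)
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))
  aug <- augment_dataset(man, augmentation_spec(), write_images = FALSE)
  cnt <- manifest_counts(aug)
  expect_equal(nrow(aug), 1240L)
  expect_equal(unname(cnt$class_counts["healthy"]), 648L)
  expect_equal(unname(cnt$class_counts["patient"]), 592L)
})

test_that("augmentation respects multipliers, identity and determinism", {
  root <- make_tree(5, 5)
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))

  id <- augment_dataset(man, augmentation_spec(c(healthy = 1L, patient = 1L)),
                        write_images = FALSE)
  expect_equal(nrow(id), nrow(man))
  expect_true(all(id$provenance == "original"))

  m3 <- augment_dataset(man[man$label == "healthy", ],
                        augmentation_spec(c(healthy = 3L, patient = 3L),
                                          seed = 9L),
                        out_dir = tempfile())
  expect_equal(nrow(m3), 15L)
  expect_equal(sum(m3$provenance == "augmented"), 10L)
  expect_true(all(file.exists(m3$path)))
  expect_true(all(m3$augmentation_op[m3$provenance == "augmented"] %in%
                    c("rotation", "translation", "shearing")))

  # deterministic from the spec seed: same ops, same pixels
  m3b <- augment_dataset(man[man$label == "healthy", ],
                         augmentation_spec(c(healthy = 3L, patient = 3L),
                                           seed = 9L),
                         out_dir = tempfile())
  expect_identical(m3$augmentation_op, m3b$augmentation_op)
  i <- which(m3$provenance == "augmented")[1]
  expect_identical(read_gray(m3$path[i]), read_gray(m3b$path[i]))

  expect_error(augmentation_spec(c(healthy = 0L)), "multipliers")
  expect_error(augment_dataset(man, augmentation_spec(c(healthy = 2L)),
                               write_images = FALSE),
               "patient")
})

test_that("augmented record counts match a brute-force tally on random manifests", {
  root <- make_tree(7, 11)
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))
  for (seed in 1:4) {
    set.seed(seed)
    mult <- c(healthy = sample(1:4, 1), patient = sample(1:4, 1))
    keep <- sort(sample(nrow(man), sample(5:18, 1)))
    sub <- man[keep, , drop = FALSE]
    aug <- augment_dataset(sub, augmentation_spec(mult), write_images = FALSE)
    expected <- sum(vapply(seq_len(nrow(sub)),
                           function(i) mult[[sub$label[i]]], numeric(1)))
    expect_equal(nrow(aug), expected)
  }
})

test_that("stratified splits are exhaustive, proportional and reproducible", {
  root <- make_tree(50, 50)
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))
  sp <- split_manifest(man, split_spec(0.8, seed = 3L))
  expect_equal(nrow(sp$train), 80L)
  expect_equal(nrow(sp$test), 20L)
  expect_equal(sum(sp$train$label == "healthy"), 40L)
  expect_equal(sum(sp$test$label == "healthy"), 10L)
  # partition: disjoint and exhaustive
  expect_length(intersect(sp$train$path, sp$test$path), 0L)
  expect_setequal(c(sp$train$path, sp$test$path), man$path)
  # determinism
  sp2 <- split_manifest(man, split_spec(0.8, seed = 3L))
  expect_identical(sp$train$path, sp2$train$path)

  one <- man[c(1, which(man$label == "patient")), ]
  expect_error(split_manifest(one, split_spec(0.8)), "at least 2")
})

test_that("a 0.9 split of 1240 records lands within one record per class", {
  root <- make_tree(40, 40)
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))
  aug <- augment_dataset(man,
                         augmentation_spec(c(healthy = 18L, patient = 13L)),
                         write_images = FALSE)
  expect_equal(nrow(aug), 40L * 18L + 40L * 13L)  # 1240
  sp <- split_manifest(aug, split_spec(0.9, seed = 1L))
  expect_equal(nrow(sp$train), 1116L)
  expect_equal(nrow(sp$test), 124L)
  expect_true(abs(sum(sp$train$label == "healthy") - 0.9 * 720) <= 1)
})

test_that("manifest CSV round-trips are lossless", {
  root <- make_tree(4, 6)
  man <- build_manifest(root, c(healthy = "healthy", patient = "patient"))
  aug <- augment_dataset(man, augmentation_spec(c(healthy = 2L, patient = 1L)),
                         write_images = FALSE)
  f <- tempfile(fileext = ".csv")
  write_manifest(aug, f)
  back <- read_manifest(f)
  orig <- as.data.frame(aug)
  rownames(orig) <- NULL
  expect_equal(as.data.frame(back), orig)
})
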