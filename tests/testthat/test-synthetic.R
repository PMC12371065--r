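test_that("a zero-perturbation spiral lies exactly on the analytic curve", {
  spec <- drawing_spec("spiral", image_size = 96, turns = 3, a = 0, b = 2)
  still <- tremor_model(amplitude = 0, jitter_sd = 0, micrographia_decay = 1)
  path <- generate_path(spec, still, seed = 1)
  theta <- seq(0, 3 * 2 * pi, length.out = nrow(path))
  ctr <- (96 + 1) / 2
  expect_lt(max(abs(path[, 1] - (ctr + 2 * theta * cos(theta)))), 1e-9)
  expect_lt(max(abs(path[, 2] - (ctr + 2 * theta * sin(theta)))), 1e-9)
  # final radius of r = 2 theta at 3 turns
  r_final <- sqrt(sum((path[nrow(path), ] - ctr)^2))
  expect_equal(r_final, 2 * 3 * 2 * pi, tolerance = 1e-9)
})

test_that("path generation is deterministic in the seed", {
  spec <- drawing_spec("spiral")
  p1 <- generate_path(spec, patient_tremor(), seed = 11)
  p2 <- generate_path(spec, patient_tremor(), seed = 11)
  p3 <- generate_path(spec, patient_tremor(), seed = 12)
  expect_identical(unclass(p1), unclass(p2))
  expect_false(identical(unclass(p1), unclass(p3)))
})

test_that("micrographia decay shrinks the spiral radius per turn", {
  spec <- drawing_spec("spiral", image_size = 96, turns = 3, a = 0, b = 2)
  still <- tremor_model(amplitude = 0, jitter_sd = 0, micrographia_decay = 0.9)
  path <- generate_path(spec, still, seed = 1)
  theta <- seq(0, 3 * 2 * pi, length.out = nrow(path))
  ctr <- (96 + 1) / 2
  r <- sqrt(rowSums((path - ctr)^2))
  expect_equal(r, 2 * theta * 0.9^(theta / (2 * pi)), tolerance = 1e-9)
})

test_that("rendering is reproducible and ink grows with stroke width", {
  base_spec <- drawing_spec("spiral", image_size = 96)
  path <- generate_path(base_spec, healthy_tremor(), seed = 2)
  img <- render_drawing(path, base_spec)
  expect_identical(render_drawing(path, base_spec), img)
  expect_true(all(img >= 0 & img <= 255))
  expect_gt(mean(img < 128), 0)                      # some ink
  tab <- table(img)
  expect_equal(as.numeric(names(tab)[which.max(tab)]), 255)  # white mode
  inks <- vapply(1:5, function(w) {
    sp <- drawing_spec("spiral", image_size = 96, stroke_width = w)
    sum(render_drawing(path, sp) < 255)
  }, numeric(1))
  expect_true(all(diff(inks) > 0))
})

test_that("noise injection matches its specification", {
  img <- matrix(128, 64, 64)
  expect_identical(inject_noise(img, noise_spec(0, 0)), img)
  salted <- inject_noise(img, noise_spec(0, 1, seed = 4))
  expect_true(all(salted %in% c(0, 255)))
  big <- matrix(128, 256, 256)
  noisy <- inject_noise(big, noise_spec(gaussian_sd = 10, seed = 5))
  expect_equal(dim(noisy), dim(big))
  expect_lt(abs(sd(noisy - big) - 10) / 10, 0.1)
  # same seed, same noise
  expect_identical(noisy, inject_noise(big, noise_spec(gaussian_sd = 10, seed = 5)))
})

test_that("generated datasets are balanced, deterministic and class-separated", {
  man <- generate_dataset(10, seed = 3, out_dir = tempfile())
  expect_equal(nrow(man), 20L)
  expect_equal(sum(man$label == "healthy"), 10L)
  expect_true(all(file.exists(man$path)))
  man2 <- generate_dataset(10, seed = 3, out_dir = tempfile())
  expect_equal(man$radial_dev, man2$radial_dev)
  expect_identical(read_gray(man$path[1]), read_gray(man2$path[1]))
  # patient tremor (amplitude 6 px) deviates more than healthy (1 px)
  expect_gt(mean(man$radial_dev[man$label == "patient"]),
            mean(man$radial_dev[man$label == "healthy"]))
  expect_error(generate_dataset(0), "positive")
  expect_error(generate_dataset(4, healthy = patient_tremor(),
                                patient = healthy_tremor()),
               "amplitude")
})

test_that("classes are separable from the tremor statistic alone", {
  man <- generate_dataset(40, seed = 21, out_dir = tempfile())
  sp <- split_manifest(man, split_spec(0.5, seed = 1))
  sp$train$radial_dev <- man$radial_dev[match(sp$train$path, man$path)]
  sp$test$radial_dev <- man$radial_dev[match(sp$test$path, man$path)]
  expect_gte(baseline_radial_accuracy(sp$train, sp$test), 0.9)
})
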