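test_that("geometric mean and local variance behave on hand cases", {
  expect_equal(geometric_mean(matrix(5, 3, 3)), 5)
  expect_equal(geometric_mean(matrix(c(1, 2, 4, 8), 2)), 64^(1 / 4))
  w <- c(0, 3, 9, 27)
  expect_lte(geometric_mean(w, 1e-6), mean(w))   # AM-GM with a floored zero
  expect_equal(local_variance(matrix(7, 3, 3), 7), 0)
  expect_equal(local_variance(c(0, 2), 1), 1)
  set.seed(1)
  for (i in 1:5) {
    w <- rnorm(9)
    expect_gte(local_variance(w, rnorm(1)), 0)
  }
})

test_that("median filter removes impulses and matches a sort oracle", {
  expect_equal(median_filter(matrix(9, 6, 6)), matrix(9, 6, 6))
  z <- matrix(0, 7, 7)
  z[4, 4] <- 255
  expect_equal(median_filter(z, 3), matrix(0, 7, 7))
  set.seed(2)
  for (i in 1:5) {
    m <- matrix(runif(64, 0, 255), 8)
    expect_equal(median_filter(m, 3), ref_median_filter(m, 3), tolerance = 1e-12)
  }
  m <- matrix(runif(100, 0, 255), 10)
  expect_equal(median_filter(m, 5), ref_median_filter(m, 5), tolerance = 1e-12)
})

test_that("Gaussian kernel matches its closed form and normalises", {
  for (sg in c(0.8, 1, 2)) {
    spec <- kernel_spec(sigma = sg, half_width = 3)
    raw <- gaussian_kernel(spec, normalize = FALSE)
    expect_equal(raw[4, 4], 1 / (2 * pi * sg^2))
    expect_equal(raw, t(raw))
    expect_equal(raw, raw[7:1, 7:1])
    expect_equal(sum(gaussian_kernel(spec)), 1, tolerance = 1e-12)
  }
})

test_that("improved Gaussian kernel follows the printed formula with clamping", {
  spec <- kernel_spec(sigma = 1, half_width = 3)
  raw <- improved_gaussian_kernel(spec, normalize = FALSE)
  expect_true(all(is.finite(raw)))
  # independent scalar evaluation at (c, r) = (2, 2), sigma = 1
  d2 <- 8
  expected <- (exp(-d2 / 2) / (2 * pi) + (d2 - 2) / (2 * pi) * exp(-d2 / 2)) /
    sqrt(d2 - 2 * exp(-d2))
  expect_equal(raw[4 + 2, 4 + 2], expected, tolerance = 1e-12)
  # clamped radicand at the origin still yields a finite centre weight
  expect_true(is.finite(raw[4, 4]))
  expect_equal(raw, t(raw))
  expect_equal(raw, raw[7:1, 7:1])
  norm <- improved_gaussian_kernel(spec)
  expect_equal(sum(abs(norm)), 1, tolerance = 1e-12)
})

test_that("conventional Wiener collapses to its limiting cases", {
  set.seed(3)
  img <- matrix(runif(64, 0, 255), 8)
  # u^2 = 0: shrink factor 1, output = input
  expect_equal(conventional_wiener(img, wiener_config(noise_variance = 0)),
               img, tolerance = 1e-9)
  # u^2 above every local variance: output = local median image
  expect_equal(conventional_wiener(img, wiener_config(noise_variance = 1e9)),
               median_filter(img, 3), tolerance = 1e-9)
})

test_that("both Wiener filters match unvectorised per-pixel oracles", {
  set.seed(4)
  for (i in 1:3) {
    img <- matrix(runif(64, 0, 255), 8)
    expect_equal(conventional_wiener(img), ref_conventional_wiener(img),
                 tolerance = 1e-9)
    kern <- improved_gaussian_kernel(kernel_spec())
    expect_equal(modified_wiener(img), ref_modified_wiener(img, kern),
                 tolerance = 1e-9)
  }
})

test_that("modified Wiener preserves shape, range and constants", {
  set.seed(5)
  img <- matrix(runif(96 * 80, 0, 255), 96, 80)
  out <- modified_wiener(img)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 255))

  # constant input: branch A returns c; branch B returns c * gain * sum(K)
  # (the improved kernel's weights do not sum to 1), so before
  # renormalisation Q = c * (1 + gain * sum(K)); the degenerate min-max
  # rescale then falls back to the input constant
  cfg <- wiener_config(noise_variance = 0, output_norm = "clip",
                       value_range = c(-1e9, 1e9))
  const <- matrix(100, 16, 16)
  k_sum <- sum(improved_gaussian_kernel(kernel_spec()))
  expect_equal(modified_wiener(const, cfg),
               matrix(100 * (1 + 1.2 * k_sum), 16, 16), tolerance = 1e-9)
  expect_equal(modified_wiener(const, wiener_config(noise_variance = 0)),
               const, tolerance = 1e-9)
})

test_that("PSNR matches its closed form", {
  img <- matrix(runif(64, 0, 255), 8)
  expect_identical(psnr(img, img), Inf)
  shifted <- img + 1          # MSE exactly 1
  expect_equal(psnr(img, shifted), 20 * log10(255), tolerance = 1e-9)
  expect_equal(psnr(img, shifted), 48.1308, tolerance = 1e-3)
  expect_error(psnr(img, matrix(0, 4, 4)), "shape")
})

test_that("SSIM is 1 on identical images, symmetric, and low on inverses", {
  img <- make_drawing(1)
  expect_equal(ssim(img, img), 1, tolerance = 1e-9)
  noisy <- inject_noise(img, noise_spec(gaussian_sd = 20, seed = 1))
  expect_equal(ssim(img, noisy), ssim(noisy, img), tolerance = 1e-12)
  expect_lt(ssim(img, 255 - img), 0.5)
  expect_error(ssim(img, matrix(0, 4, 4)), "shape")
})

test_that("modified Wiener denoises synthetic drawings best, in PSNR and SSIM", {
  res <- vapply(1:4, function(i) {
    img <- make_drawing(i, if (i %% 2) "spiral" else "meander", patient = i > 2)
    noisy <- inject_noise(img, noise_spec(gaussian_sd = 15, seed = i))
    c(noisy = psnr(img, noisy),
      cwf = psnr(img, conventional_wiener(noisy)),
      mwf = psnr(img, modified_wiener(noisy)),
      s_noisy = ssim(img, noisy), s_mwf = ssim(img, modified_wiener(noisy)))
  }, numeric(5))
  m <- rowMeans(res)
  expect_gt(m[["mwf"]], m[["cwf"]])
  expect_gt(m[["cwf"]], m[["noisy"]])
  expect_gt(m[["s_mwf"]], m[["s_noisy"]])
})

test_that("compare_filters reports the full comparator table", {
  img <- make_drawing(3)
  noisy <- inject_noise(img, noise_spec(gaussian_sd = 15, seed = 3))
  tab <- compare_filters(img, noisy)
  expect_setequal(tab$method, c("noisy", "median", "gaussian",
                                "conventional_wiener", "modified_wiener"))
  expect_true(all(is.finite(tab$psnr)))
  expect_true(all(tab$ssim <= 1))
})
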