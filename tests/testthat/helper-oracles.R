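# Straight-line (unvectorised) reference implementations used as oracles.
# They share the package's stated conventions (symmetric padding, window
# definitions) but are written as explicit per-pixel loops, independent of
# the vectorised code paths they check.

# symmetric (mirror, edge-included) index mapping for a padded axis
ref_reflect <- function(t, n) {
  if (t < 1) 1 - t
  else if (t > n) 2 * n + 1 - t
  else t
}

ref_window <- function(img, i, j, k) {
  p <- (k - 1) %/% 2
  w <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    w[a, b] <- img[ref_reflect(i + a - 1 - p, nrow(img)),
                   ref_reflect(j + b - 1 - p, ncol(img))]
  }
  w
}

ref_median_filter <- function(img, k = 3) {
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    out[i, j] <- median(ref_window(img, i, j, k))
  out
}

ref_geomean <- function(w, floor = 1e-6) exp(mean(log(pmax(w, floor))))

ref_noise_var <- function(img, k = 3) {
  med <- ref_median_filter(img, k)
  vs <- numeric(length(img))
  t <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    w <- ref_window(med, i, j, k)
    t <- t + 1
    vs[t] <- mean((w - mean(w))^2)
  }
  median(vs)
}

ref_conventional_wiener <- function(img, k = 3, eps = 1e-6, floor = 1e-6,
                                    rng = c(0, 255)) {
  u2 <- ref_noise_var(img, k)
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    w <- ref_window(img, i, j, k)
    med <- median(w)
    mu <- ref_geomean(w, floor)
    v <- mean((w - mu)^2)
    f <- min(max((v - u2) / max(v, eps), 0), 1)
    out[i, j] <- med + f * (img[i, j] - med)
  }
  pmin(pmax(out, rng[1]), rng[2])
}

ref_conv_kernel <- function(img, kern) {
  k <- nrow(kern)
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    out[i, j] <- sum(ref_window(img, i, j, k) * kern)
  out
}

ref_modified_wiener <- function(img, kern, k = 3, gain = 1.2, eps = 1e-6,
                                floor = 1e-6, rng = c(0, 255),
                                norm = "rescale") {
  u2 <- ref_noise_var(img, k)
  medA <- ref_median_filter(img, k)
  bright <- pmin(pmax(img * gain, rng[1]), rng[2])
  filt <- ref_conv_kernel(bright, kern)
  med1 <- ref_median_filter(filt, k)
  q <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    wA <- ref_window(medA, i, j, k)
    muA <- ref_geomean(wA, floor)
    vA <- mean((wA - muA)^2)
    fA <- min(max((vA - u2) / max(vA, eps), 0), 1)
    qa <- medA[i, j] + fA * (img[i, j] - medA[i, j])
    wB <- ref_window(filt, i, j, k)
    rho <- med1[i, j]
    vB <- mean((wB - rho)^2)
    fB <- min(max((vB - u2) / max(vB, eps), 0), 1)
    qb <- med1[i, j] + fB * (img[i, j] - rho)
    q[i, j] <- qa + qb
  }
  if (norm == "clip") return(pmin(pmax(q, rng[1]), rng[2]))
  span <- max(q) - min(q)
  if (span < eps) return(pmin(pmax(img, rng[1]), rng[2]))
  (q - min(q)) / span * (rng[2] - rng[1]) + rng[1]
}

ref_gradients <- function(img) {
  H <- nrow(img); W <- ncol(img)
  ux <- uy <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ux[i, j] <- img[i, ref_reflect(j + 1, W)] - img[i, ref_reflect(j - 1, W)]
    uy[i, j] <- img[ref_reflect(i + 1, H), j] - img[ref_reflect(i - 1, H), j]
  }
  o <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (ux[i, j] == 0 && uy[i, j] == 0) o[i, j] <- 0
    else if (ux[i, j] == 0) o[i, j] <- sign(uy[i, j]) * pi / 2
    else o[i, j] <- atan(uy[i, j] / ux[i, j])
  }
  list(ux = ux, uy = uy, orientation = o, magnitude = sqrt(ux^2 + uy^2))
}

# direct transcription of the improved-entropy functional on a singleton
# mass vector (|M| = 1 for every focal element, so 2^|M| - 1 = 1)
ref_improved_entropy_mass <- function(a, eps = 1e-12) {
  num <- 0
  den <- 0
  for (m in a[a > 0]) {
    inner <- max(abs(m * log2(m)), eps)
    num <- num - m * log2((m + 1) / inner) + m * log2(2^1 - 1)
    den <- den + m * log2(m) + 1 / (1 + exp(-log2(m)))
  }
  if (abs(den) < eps) den <- sign(den + eps) * eps
  max(num / den, 0)
}

ref_mass <- function(gmap, bins = 8) {
  v <- abs(as.numeric(gmap))
  if (max(v) == 0) return(NULL)
  idx <- pmin(floor(v / max(v) * bins) + 1, bins)
  tabulate(idx, bins) / length(v)
}

ref_modified_gradients <- function(img, bins = 8, tol = 1e-6) {
  g <- ref_gradients(img)
  ex <- {
    m <- ref_mass(g$ux, bins)
    if (is.null(m)) 0 else ref_improved_entropy_mass(m)
  }
  ey <- {
    m <- ref_mass(g$uy, bins)
    if (is.null(m)) 0 else ref_improved_entropy_mass(m)
  }
  ie <- if (abs(ex - ey) > tol) max(ex, ey) else (ex + ey) / 2
  list(ux = g$ux + ie, uy = g$uy + ie, ie = ie)
}

# scalar transcription of the WAP-BN formula on a plain numeric window
ref_wap_bn <- function(z, gamma = 0, eps = 1e-5) {
  sj <- (1 - gamma) * mean(z)
  delta <- mean(z)
  sig2 <- mean((z - delta)^2)
  ((z * sj) - (delta * sj)) / sqrt((sig2 + 1 / (1 + exp(-sj))) + eps)
}

ref_mixed_pool <- function(m, lambda, w = 2, stride = 2) {
  Ho <- (nrow(m) - w) %/% stride + 1
  Wo <- (ncol(m) - w) %/% stride + 1
  out <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    win <- m[(i - 1) * stride + seq_len(w), (j - 1) * stride + seq_len(w)]
    out[i, j] <- lambda * max(win) + (1 - lambda) * mean(win)
  }
  out
}

# deterministic small drawing fixture
make_drawing <- function(i, pattern = "spiral", patient = FALSE, size = 96) {
  spec <- drawing_spec(pattern, image_size = size)
  tr <- if (patient) patient_tremor() else healthy_tremor()
  tr$phase <- i
  render_drawing(generate_path(spec, tr, seed = i), spec)
}
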