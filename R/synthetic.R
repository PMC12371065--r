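#' Drawing specification for the tremor simulator
#'
#' Describes the guided drawing a subject is asked to trace: an
#' Archimedean spiral `r(theta) = a + b * theta` or a meander (square-wave
#' path of alternating horizontal/vertical strokes of decreasing extent,
#' mimicking the printed meander forms of pen-and-paper PD exams).
#'
#' @param pattern `"spiral"` or `"meander"`.
#' @param image_size square canvas side in pixels (>= 64).
#' @param turns spiral turns (positive real).
#' @param segment_count meander stroke count (positive integer).
#' @param stroke_width pen stroke width in pixels.
#' @param a,b spiral coefficients of `r = a + b * theta` (pixels,
#'   pixels/radian). `b = NULL` auto-fits the requested turns inside the
#'   canvas with a small margin.
#' @return list of class `pd_drawing_spec`.
#' @export
drawing_spec <- function(pattern = c("spiral", "meander"), image_size = 96,
                         turns = 3, segment_count = 12, stroke_width = 2,
                         a = 0, b = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(image_size >= 64, turns > 0, segment_count >= 1, stroke_width >= 1)
  structure(list(pattern = pattern, image_size = image_size, turns = turns,
                 segment_count = as.integer(segment_count),
                 stroke_width = stroke_width, a = a, b = b),
            class = "pd_drawing_spec")
}

#' Tremor and micrographia model
#'
#' Radial perturbation of the pen trace: a sinusoid of `amplitude` pixels
#' completing `frequency` cycles per path turn (starting at `phase`), plus
#' a seeded random walk with per-step standard deviation `jitter_sd`.
#' `micrographia_decay` in (0, 1] multiplicatively shrinks the stroke
#' scale per turn, emulating the progressive smallness of PD handwriting.
#'
#' @param amplitude tremor amplitude, pixels (>= 0).
#' @param frequency tremor cycles per path turn.
#' @param phase phase offset, radians.
#' @param jitter_sd random-walk scale, pixels: the walk accumulates
#'   roughly this much drift per path turn (step size is normalised by
#'   the sampling density, so the drawing does not depend on it).
#' @param micrographia_decay per-turn multiplicative shrink in (0, 1].
#' @return list of class `pd_tremor_model`.
#' @export
tremor_model <- function(amplitude = 1, frequency = 8, phase = 0,
                         jitter_sd = 0.05, micrographia_decay = 1) {
  stopifnot(amplitude >= 0, frequency >= 0, jitter_sd >= 0,
            micrographia_decay > 0, micrographia_decay <= 1)
  structure(list(amplitude = amplitude, frequency = frequency, phase = phase,
                 jitter_sd = jitter_sd, micrographia_decay = micrographia_decay),
            class = "pd_tremor_model")
}

#' Default class conditions for the simulator
#'
#' Healthy controls draw with small tremor (1 px) and no shrinkage;
#' patients with large tremor (6 px), more jitter and per-turn
#' micrographia decay 0.93. These effect sizes make the two classes
#' clearly but not trivially separable at desk scale.
#'
#' @name class_tremor_defaults
#' @export
healthy_tremor <- function() tremor_model(amplitude = 1, jitter_sd = 0.05)

#' @rdname class_tremor_defaults
#' @export
patient_tremor <- function() tremor_model(amplitude = 6, jitter_sd = 0.2,
                                          micrographia_decay = 0.93)

#' Noise specification
#'
#' @param gaussian_sd additive Gaussian noise standard deviation
#'   (intensity units on `[0, 255]`).
#' @param impulse_density fraction of pixels flipped to 0 or 255.
#' @param seed integer seed.
#' @return list of class `pd_noise_spec`.
#' @export
noise_spec <- function(gaussian_sd = 0, impulse_density = 0, seed = 1L) {
  stopifnot(gaussian_sd >= 0, impulse_density >= 0, impulse_density <= 1)
  structure(list(gaussian_sd = gaussian_sd, impulse_density = impulse_density,
                 seed = as.integer(seed)),
            class = "pd_noise_spec")
}

# Base (untrembled) spiral in canvas coordinates; returns x, y, theta, r.
spiral_base <- function(spec, n = NULL) {
  theta_max <- spec$turns * 2 * pi
  if (is.null(n)) n <- max(256L, ceiling(720 * spec$turns))
  theta <- seq(0, theta_max, length.out = n)
  # 0.40 margin leaves headroom for patient-scale tremor excursions
  b <- spec$b
  if (is.null(b)) b <- (0.40 * spec$image_size - spec$a) / theta_max
  list(theta = theta, r = spec$a + b * theta, b = b)
}

#' Generate a perturbed pen path
#'
#' Points trace the base curve plus the tremor model's radial sinusoid and
#' random walk; the spiral radius is additionally scaled by
#' `micrographia_decay^(theta / 2pi)`. With a zero-perturbation tremor the
#' points lie exactly on the analytic base curve.
#'
#' @param spec a [drawing_spec()].
#' @param tremor a [tremor_model()].
#' @param seed integer seed driving the random walk.
#' @return n x 2 matrix of (x, y) pixel coordinates, with attributes
#'   `ideal` (the unperturbed path) and `radial_dev` (mean absolute
#'   deviation from it, the simulator's ground-truth tremor statistic).
#' @export
generate_path <- function(spec, tremor, seed = 1L) {
  stopifnot(inherits(spec, "pd_drawing_spec"), inherits(tremor, "pd_tremor_model"))
  ctr <- (spec$image_size + 1) / 2
  if (spec$pattern == "spiral") {
    base <- spiral_base(spec)
    theta <- base$theta
    decay <- tremor$micrographia_decay ^ (theta / (2 * pi))
    r_ideal <- base$r * decay
    step_sd <- tremor$jitter_sd / sqrt(length(theta) / max(spec$turns, 1))
    walk <- with_seed(seed, "path-walk", 0L,
                      cumsum(rnorm(length(theta), 0, step_sd)))
    pert <- tremor$amplitude * sin(tremor$frequency * theta + tremor$phase) + walk
    r <- pmax(r_ideal + pert, 0)
    xy <- cbind(ctr + r * cos(theta), ctr + r * sin(theta))
    ideal <- cbind(ctr + r_ideal * cos(theta), ctr + r_ideal * sin(theta))
    dev <- mean(abs(r - r_ideal))
  } else {
    # Meander: concertina of alternating horizontal/vertical strokes whose
    # extent shrinks with each stroke pair (and further under decay).
    n_seg <- spec$segment_count
    ext0 <- 0.72 * spec$image_size
    verts <- matrix(0, n_seg + 1L, 2)
    verts[1, ] <- c(ctr - ext0 / 2, ctr - ext0 / 2)
    dir_h <- TRUE
    sgn <- 1
    for (s in seq_len(n_seg)) {
      pair <- (s - 1) %/% 2
      ext <- ext0 * (0.92 ^ pair) * tremor$micrographia_decay ^ pair
      step <- if (dir_h) c(sgn * ext, 0) else c(0, ext * 0.18)
      verts[s + 1L, ] <- verts[s, ] + step
      if (dir_h) sgn <- -sgn
      dir_h <- !dir_h
    }
    # densify uniformly along the polyline
    seg_len <- sqrt(rowSums(diff(verts)^2))
    total <- sum(seg_len)
    n <- max(256L, ceiling(6 * total))
    s_at <- seq(0, total, length.out = n)
    cum <- c(0, cumsum(seg_len))
    seg_of <- pmin(findInterval(s_at, cum, rightmost.closed = TRUE), n_seg)
    t_in <- (s_at - cum[seg_of]) / pmax(seg_len[seg_of], 1e-12)
    ideal <- verts[seg_of, , drop = FALSE] +
      (verts[seg_of + 1L, , drop = FALSE] - verts[seg_of, , drop = FALSE]) * t_in
    # perpendicular tremor along the travelled length, one "turn" per stroke pair
    tangent <- verts[seg_of + 1L, , drop = FALSE] - verts[seg_of, , drop = FALSE]
    tangent <- tangent / pmax(sqrt(rowSums(tangent^2)), 1e-12)
    normal <- cbind(-tangent[, 2], tangent[, 1])
    u <- s_at / (total / max(1, n_seg %/% 2))  # turn coordinate
    step_sd <- tremor$jitter_sd / sqrt(n / max(1, n_seg %/% 2))
    walk <- with_seed(seed, "path-walk", 0L, cumsum(rnorm(n, 0, step_sd)))
    pert <- tremor$amplitude * sin(2 * pi * tremor$frequency * u / 4 + tremor$phase) + walk
    xy <- ideal + normal * pert
    dev <- mean(abs(pert))
  }
  structure(xy, ideal = ideal, radial_dev = dev)
}

#' Render a pen path as a grayscale drawing
#'
#' Draws a dark, anti-aliased stroke of the spec's width on a white
#' background (2x supersampled disc stamping, box-downsampled). Path
#' points falling outside the canvas are clipped with a warning.
#'
#' @param path n x 2 coordinate matrix from [generate_path()].
#' @param spec the [drawing_spec()] used to generate it.
#' @return numeric matrix `image_size` x `image_size` with values in
#'   `[0, 255]` (255 = white background).
#' @export
render_drawing <- function(path, spec) {
  stopifnot(nrow(path) > 0)
  S <- spec$image_size
  ss <- 2L                                 # supersampling factor
  pts <- path * ss
  if (any(path < 0.5 | path > S + 0.5)) {
    warning("path exceeds canvas; clipping to the image bounds")
  }
  # densify so consecutive stamped points overlap at supersampled scale
  d <- sqrt(rowSums(diff(pts)^2))
  need <- pmax(1L, ceiling(d / 0.7))
  idx <- rep(seq_len(nrow(pts) - 1L), need)
  frac <- unlist(lapply(need, function(k) seq_len(k) / k), use.names = FALSE)
  dense <- rbind(pts[1, , drop = FALSE],
                 pts[idx, , drop = FALSE] +
                   (pts[idx + 1L, , drop = FALSE] - pts[idx, , drop = FALSE]) * frac)
  px <- pmin(pmax(round(dense[, 1]), 1L), S * ss)
  py <- pmin(pmax(round(dense[, 2]), 1L), S * ss)
  rad <- spec$stroke_width * ss / 2
  off <- expand.grid(dx = seq(-ceiling(rad), ceiling(rad)),
                     dy = seq(-ceiling(rad), ceiling(rad)))
  off <- off[off$dx^2 + off$dy^2 <= rad^2, , drop = FALSE]
  ink <- matrix(0, S * ss, S * ss)
  for (o in seq_len(nrow(off))) {
    rr <- pmin(pmax(py + off$dy[o], 1L), S * ss)
    cc <- pmin(pmax(px + off$dx[o], 1L), S * ss)
    ink[cbind(rr, cc)] <- 1
  }
  # 2x2 box downsample -> fractional coverage -> anti-aliased intensities
  cov <- (ink[seq(1, S * ss, 2), seq(1, S * ss, 2)] +
          ink[seq(2, S * ss, 2), seq(1, S * ss, 2)] +
          ink[seq(1, S * ss, 2), seq(2, S * ss, 2)] +
          ink[seq(2, S * ss, 2), seq(2, S * ss, 2)]) / 4
  255 * (1 - cov)
}

#' Inject Gaussian and impulse noise
#'
#' Adds seeded Gaussian noise of the spec's standard deviation, then flips
#' an `impulse_density` fraction of pixels to 0 or 255 (salt/pepper with
#' equal probability). Output is clipped to `[0, 255]`.
#'
#' @param image grayscale matrix in `[0, 255]`.
#' @param noise a [noise_spec()].
#' @return noisy image, same shape and range.
#' @export
inject_noise <- function(image, noise) {
  stopifnot(inherits(noise, "pd_noise_spec"))
  out <- image
  if (noise$gaussian_sd > 0) {
    out <- out + with_seed(noise$seed, "gauss", 0L,
                           matrix(rnorm(length(image), 0, noise$gaussian_sd),
                                  nrow(image)))
  }
  if (noise$impulse_density > 0) {
    flips <- with_seed(noise$seed, "impulse", 0L, {
      k <- round(noise$impulse_density * length(image))
      list(pos = sample.int(length(image), k),
           val = sample(c(0, 255), k, replace = TRUE))
    })
    out[flips$pos] <- flips$val
  }
  pmin(pmax(out, 0), 255)
}

#' Generate a labelled synthetic drawing dataset
#'
#' Writes `n_per_class` healthy and `n_per_class` patient drawings
#' (alternating spiral and meander patterns) to `out_dir` as PNG and
#' returns the matching manifest. Each drawing gets a seeded random tremor
#' phase and random walk so images within a class differ. The manifest
#' carries an extra `radial_dev` column with the simulator's ground-truth
#' mean radial deviation, used by the baseline comparator.
#'
#' @param n_per_class positive integer.
#' @param healthy,patient [tremor_model()]s per class; patient amplitude
#'   must exceed healthy amplitude.
#' @param specs list of [drawing_spec()]s cycled over images.
#' @param seed master integer seed.
#' @param out_dir output directory (created).
#' @param noise optional [noise_spec()] applied to every image.
#' @return a `pd_manifest` with an additional `radial_dev` column.
#' @export
generate_dataset <- function(n_per_class, healthy = healthy_tremor(),
                             patient = patient_tremor(),
                             specs = list(drawing_spec("spiral"),
                                          drawing_spec("meander")),
                             seed = 1L, out_dir = tempfile("synth"),
                             noise = NULL) {
  if (n_per_class <= 0) stop("n_per_class must be positive")
  if (patient$amplitude <= healthy$amplitude)
    stop("patient tremor amplitude must exceed healthy amplitude")
  dir.create(file.path(out_dir, "healthy"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "patient"), recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", 2L * n_per_class)
  i <- 0L
  for (label in c("healthy", "patient")) {
    base_tremor <- if (label == "healthy") healthy else patient
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      spec <- specs[[(k - 1L) %% length(specs) + 1L]]
      item_seed <- derive_seed(seed, paste0("img-", label), k)
      tr <- base_tremor
      tr$phase <- with_seed(item_seed, "phase", 0L, runif(1, 0, 2 * pi))
      path <- generate_path(spec, tr, seed = item_seed)
      img <- render_drawing(path, spec)
      if (!is.null(noise)) {
        ns <- noise
        ns$seed <- derive_seed(item_seed, "noise")
        img <- inject_noise(img, ns)
      }
      path_out <- file.path(out_dir, label, sprintf("%d-1.png", i))
      write_gray(img, path_out)
      rows[[i]] <- data.frame(
        exam_id = i, image_id = 1L, pattern = spec$pattern, label = label,
        path = path_out, provenance = "original",
        augmentation_op = NA_character_, aug_index = 0L,
        radial_dev = attr(path, "radial_dev"), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  man <- new_manifest(df[, MANIFEST_COLS])
  man$radial_dev <- df$radial_dev
  man
}
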