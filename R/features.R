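#' @section Gradient conventions:
#' Derivatives are computed by correlating the image with the 3-tap masks
#' `K_X = [-1 0 1]` (horizontal, along columns) and `K_Y = t(K_X)`
#' (vertical), with symmetric border padding. Orientation is
#' `arctan(U_Y / U_X)` (0 where both derivatives vanish) and magnitude is
#' `sqrt(U_X^2 + U_Y^2)`. For histogramming, orientations are folded to
#' the unsigned range `[0, 180)` degrees unless signed mode is requested.
#' @name gradients
NULL

# correlation with [-1 0 1] along columns (dx) / rows (dy), symmetric pad
deriv_maps <- function(image) {
  H <- nrow(image); W <- ncol(image)
  xp <- pad_sym(image, 1L)
  ux <- xp[2:(H + 1), 3:(W + 2)] - xp[2:(H + 1), 1:W]
  uy <- xp[3:(H + 2), 2:(W + 1)] - xp[1:H, 2:(W + 1)]
  list(ux = ux, uy = uy)
}

#' Image gradient field
#'
#' @param image grayscale matrix, at least 3 x 3.
#' @return list of class `pd_gradient_field` with derivative maps `ux`,
#'   `uy`, orientation `orientation` (radians, `(-pi/2, pi/2]`, 0 at flat
#'   pixels) and magnitude `magnitude`.
#' @export
compute_gradients <- function(image) {
  stopifnot(nrow(image) >= 3, ncol(image) >= 3)
  d <- deriv_maps(image)
  gradient_field(d$ux, d$uy)
}

gradient_field <- function(ux, uy) {
  o <- atan(uy / ux)
  o[ux == 0 & uy == 0] <- 0
  o[ux == 0 & uy > 0] <- pi / 2
  o[ux == 0 & uy < 0] <- -pi / 2
  structure(list(ux = ux, uy = uy, orientation = o,
                 magnitude = sqrt(ux^2 + uy^2)),
            class = "pd_gradient_field")
}

#' Shannon entropy of a probability vector
#'
#' `-sum p log_b p` with `0 log 0 := 0`. Probabilities must be
#' non-negative; vectors summing to 1 within `tol` are renormalised.
#'
#' @param probabilities non-negative numeric vector.
#' @param base logarithm base (default 2, bits).
#' @param tol tolerance on the probability sum.
#' @return entropy scalar.
#' @export
shannon_entropy <- function(probabilities, base = 2, tol = 1e-6) {
  if (any(probabilities < 0)) stop("negative probability")
  s <- sum(probabilities)
  if (abs(s - 1) > tol) stop("probabilities must sum to 1 (got ", s, ")")
  p <- probabilities / s
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

# K-bin singleton mass function over |gradient| values
gradient_mass <- function(gmap, bins) {
  v <- abs(as.numeric(gmap))
  top <- max(v)
  if (top == 0) return(NULL)
  idx <- pmin(floor(v / top * bins) + 1L, bins)
  tabulate(idx, bins) / length(v)
}

#' Improved entropy of a gradient map
#'
#' Evidential-style entropy over a singleton mass function built from a
#' `bins`-bin histogram of the gradient magnitudes (frame of discernment =
#' histogram bins, each focal element a singleton, mass = bin
#' probability). The ratio inside the numerator's logarithm divides by
#' `P log2 P`, which is negative for `P` in (0,1); its magnitude is used,
#' floored at `eps`, to keep the logarithm real, and the final value is
#' clamped to be non-negative. An all-zero gradient map returns 0 by
#' convention.
#'
#' @param gmap numeric matrix (a derivative map).
#' @param bins histogram bin count.
#' @param eps stabiliser for logarithms and the outer denominator.
#' @return finite entropy value >= 0.
#' @export
improved_entropy <- function(gmap, bins = 8L, eps = 1e-12) {
  a <- gradient_mass(gmap, bins)
  if (is.null(a)) return(0)
  improved_entropy_from_mass(a, eps)
}

# Core functional on a singleton mass vector (masses >= 0, sum 1); the
# cardinality of every focal element is 1, so 2^|M| - 1 = 1 and the
# second numerator sum vanishes (log2 1 = 0).
improved_entropy_from_mass <- function(a, eps = 1e-12) {
  stopifnot(all(a >= 0), abs(sum(a) - 1) < 1e-8)
  a <- a[a > 0]
  inner_den <- pmax(abs(a * log2(a)), eps)
  num <- -sum(a * log2((a + 1) / inner_den))
  den <- sum(a * log2(a) + 1 / (1 + exp(-log2(a))))
  if (abs(den) < eps) den <- sign(den + eps) * eps
  val <- num / den
  if (!is.finite(val)) return(0)
  max(val, 0)
}

#' Entropy pair of a gradient field
#'
#' Improved entropies of the horizontal and vertical derivative maps, the
#' mean-entropy threshold, and the selected value `IE` injected into the
#' modified gradients: the larger of the two when they differ by more than
#' `tolerance` (one axis dominates the edge information), else their mean
#' (edge information evenly distributed).
#'
#' @param field a `pd_gradient_field`.
#' @param bins histogram bin count for [improved_entropy()].
#' @param tolerance equality tolerance on the two entropies.
#' @return list with `e_x`, `e_y`, `threshold`, `ie`.
#' @export
entropy_pair <- function(field, bins = 8L, tolerance = 1e-6) {
  ex <- improved_entropy(field$ux, bins)
  ey <- improved_entropy(field$uy, bins)
  ie <- if (abs(ex - ey) > tolerance) max(ex, ey) else mean(c(ex, ey))
  list(e_x = ex, e_y = ey, threshold = mean(c(ex, ey)), ie = ie)
}

#' Entropy-augmented (modified) gradient field
#'
#' Computes the plain gradient field, derives its [entropy_pair()], and
#' adds the selected scalar `IE` uniformly to both derivative maps;
#' orientation and magnitude are recomputed from the augmented
#' derivatives. This biases the descriptor toward high-information
#' gradient structure and damps high-frequency noise.
#'
#' @param image grayscale matrix, at least 3 x 3.
#' @param bins histogram bin count for the entropies.
#' @return a `pd_gradient_field` with extra attribute `entropy` (the
#'   [entropy_pair()]).
#' @export
modified_gradients <- function(image, bins = 8L) {
  f <- compute_gradients(image)
  ep <- entropy_pair(f, bins)
  out <- gradient_field(f$ux + ep$ie, f$uy + ep$ie)
  attr(out, "entropy") <- ep
  out
}

#' Pyramid histogram of oriented gradients (PHOG)
#'
#' For pyramid level `l` in `0..levels` the image is partitioned into a
#' `2^l` x `2^l` cell grid; each cell accumulates gradient-magnitude mass
#' into `bins` orientation bins, and the per-level histograms are
#' concatenated and normalised. Applied to a [modified_gradients()] field
#' this is the modified PHOG descriptor.
#'
#' @param field a `pd_gradient_field`.
#' @param levels deepest pyramid level `L` (>= 0).
#' @param bins orientation bins per cell `K` (>= 2).
#' @param angle_mode `"unsigned"` folds orientations to `[0, 180)`
#'   degrees; `"signed"` uses `atan2` angles over `[0, 360)`.
#' @param norm `"l1"` (sum 1, default) or `"l2"` (unit norm).
#' @return numeric vector of length `bins * sum(4^(0:levels))` with
#'   attribute `unnormalized` (the raw concatenated histograms).
#' @export
phog <- function(field, levels = 2L, bins = 8L,
                 angle_mode = c("unsigned", "signed"), norm = c("l1", "l2")) {
  angle_mode <- match.arg(angle_mode)
  norm <- match.arg(norm)
  stopifnot(levels >= 0, bins >= 2)
  H <- nrow(field$magnitude); W <- ncol(field$magnitude)
  if (min(H, W) < 2^levels)
    stop("pyramid level ", levels, " needs cells of at least 1 px; image is ",
         H, " x ", W)
  if (angle_mode == "unsigned") {
    theta <- field$orientation %% pi           # [0, pi)
    span <- pi
  } else {
    theta <- atan2(field$uy, field$ux) %% (2 * pi)
    span <- 2 * pi
  }
  bin_idx <- pmin(floor(theta / span * bins) + 1L, bins)
  mag <- field$magnitude
  row_cell <- function(l) pmin(floor((seq_len(H) - 1L) / H * 2^l) + 1L, 2^l)
  col_cell <- function(l) pmin(floor((seq_len(W) - 1L) / W * 2^l) + 1L, 2^l)
  pieces <- vector("list", levels + 1L)
  for (l in 0:levels) {
    g <- 2^l
    cell <- (matrix(col_cell(l), H, W, byrow = TRUE) - 1L) * g +
      matrix(row_cell(l), H, W)
    key <- (as.numeric(cell) - 1) * bins + bin_idx
    h <- numeric(g * g * bins)
    acc <- tapply(as.numeric(mag), key, sum)
    h[as.integer(names(acc))] <- acc
    pieces[[l + 1L]] <- h
  }
  raw <- unlist(pieces, use.names = FALSE)
  total <- if (norm == "l1") sum(raw) else sqrt(sum(raw^2))
  out <- if (total > 0) raw / total else raw
  attr(out, "unnormalized") <- raw
  out
}

#' Contour shape features of a drawing
#'
#' Binarises the image (ink = foreground, via Otsu's threshold on the
#' inverted image unless `binarize_threshold` is given), keeps the largest
#' connected component, and measures: `area` (foreground pixel count),
#' `perimeter` (closed length of the oriented outer contour), `hull_area`
#' (pixels inside/on the convex hull of the contour), `hull_vertices`
#' (convex hull vertex count) and `epsilon` (the contour-approximation
#' tolerance, `epsilon_fraction * perimeter`).
#'
#' @param image grayscale matrix in `[0, 255]` (dark ink on light ground).
#' @param binarize_threshold optional ink threshold on the inverted,
#'   `[0, 1]`-scaled image; default Otsu.
#' @param epsilon_fraction fraction of the perimeter used for `epsilon`.
#' @return list of class `pd_shape_features` with fields `area`,
#'   `perimeter`, `hull_area`, `hull_vertices`, `epsilon`.
#' @export
shape_features <- function(image, binarize_threshold = NULL,
                           epsilon_fraction = 0.01) {
  inv <- pmin(pmax(1 - image / 255, 0), 1)
  th <- if (is.null(binarize_threshold)) EBImage::otsu(EBImage::Image(inv))
        else binarize_threshold
  mask <- inv > th
  if (!any(mask))
    stop("no foreground after binarisation at threshold ", signif(th, 4))
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  counts <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  biggest <- as.integer(names(counts)[which.max(counts)])
  comp <- EBImage::imageData(lab) == biggest
  area <- sum(comp)
  contour <- EBImage::ocontour(EBImage::Image(comp * 1))[[1]]
  steps <- sqrt(rowSums((contour - contour[c(2:nrow(contour), 1), ])^2))
  perimeter <- sum(steps)
  hull_idx <- chull(contour)
  hull <- contour[hull_idx, , drop = FALSE]
  hull_area <- convex_hull_pixel_area(hull, dim(comp))
  structure(list(area = area, perimeter = perimeter, hull_area = hull_area,
                 hull_vertices = nrow(hull),
                 epsilon = epsilon_fraction * perimeter),
            class = "pd_shape_features")
}

# count pixel centres inside or on a convex polygon (vertices CCW or CW)
convex_hull_pixel_area <- function(hull, dims) {
  if (nrow(hull) < 3) return(nrow(unique(hull)))
  xr <- range(hull[, 1]); yr <- range(hull[, 2])
  xs <- seq(max(1, floor(xr[1])), min(dims[1], ceiling(xr[2])))
  ys <- seq(max(1, floor(yr[1])), min(dims[2], ceiling(yr[2])))
  px <- matrix(xs, length(xs), length(ys))
  py <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  inside <- matrix(TRUE, length(xs), length(ys))
  n <- nrow(hull)
  # orientation sign of the polygon
  area2 <- sum(hull[, 1] * hull[c(2:n, 1), 2] - hull[c(2:n, 1), 1] * hull[, 2])
  s <- sign(area2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hull[j, 1] - hull[i, 1]) * (py - hull[i, 2]) -
             (hull[j, 2] - hull[i, 2]) * (px - hull[i, 1])
    inside <- inside & (s * cross >= -1e-9)
  }
  sum(inside)
}

#' Fuse feature segments into one vector set
#'
#' Concatenates per-sample segments in the fixed order
#' `[phog | shape | deep]` and standardises each dimension by training-set
#' statistics (stored in the returned layout, so test samples reuse them).
#'
#' @param phog matrix (n x p) of PHOG descriptors.
#' @param shape matrix (n x 5) of shape features
#'   (area, perimeter, hull_area, hull_vertices, epsilon).
#' @param deep optional matrix (n x d) of deep embeddings.
#' @param layout optional layout from a previous (training) call; when
#'   supplied its standardisation statistics are applied instead of being
#'   re-estimated.
#' @return list of class `pd_fused_features`: `x` (n x total standardised
#'   matrix) and `layout` (segment names, offsets, centers, scales).
#' @export
fuse_features <- function(phog, shape, deep = NULL, layout = NULL) {
  segs <- list(phog = as.matrix(phog), shape = as.matrix(shape))
  if (!is.null(deep)) segs$deep <- as.matrix(deep)
  n <- unique(vapply(segs, nrow, integer(1)))
  if (length(n) != 1) stop("segments have differing sample counts")
  for (nm in names(segs)) if (any(!is.finite(segs[[nm]])))
    stop("non-finite values in feature segment '", nm, "'")
  raw <- do.call(cbind, segs)
  lengths <- vapply(segs, ncol, integer(1))
  offsets <- cumsum(c(0L, lengths[-length(lengths)]))
  names(offsets) <- names(lengths)
  if (is.null(layout)) {
    center <- colMeans(raw)
    scale <- apply(raw, 2, sd)
    scale[scale < 1e-12] <- 1
    layout <- list(segments = names(segs), lengths = lengths,
                   offsets = offsets, center = center, scale = scale)
  } else {
    stopifnot(identical(unname(layout$lengths), unname(lengths)))
  }
  x <- sweep(sweep(raw, 2, layout$center), 2, layout$scale, "/")
  structure(list(x = x, raw = raw, layout = layout),
            class = "pd_fused_features")
}

#' Slice a fused matrix back into its segments
#'
#' @param fused a `pd_fused_features`.
#' @param standardized slice the standardised (`TRUE`) or raw matrix.
#' @return named list of per-segment matrices.
#' @export
split_segments <- function(fused, standardized = FALSE) {
  m <- if (standardized) fused$x else fused$raw
  lay <- fused$layout
  out <- list()
  for (nm in lay$segments) {
    idx <- lay$offsets[[nm]] + seq_len(lay$lengths[[nm]])
    out[[nm]] <- m[, idx, drop = FALSE]
  }
  out
}

#' Shape features as a numeric row
#'
#' @param sf a `pd_shape_features`.
#' @return numeric vector of length 5 (area, perimeter, hull_area,
#'   hull_vertices, epsilon).
#' @export
shape_vector <- function(sf) {
  c(area = sf$area, perimeter = sf$perimeter, hull_area = sf$hull_area,
    hull_vertices = sf$hull_vertices, epsilon = sf$epsilon)
}
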