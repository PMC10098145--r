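#' Image estimate over a FOV grid
#'
#' Pixel intensities over a [fov_grid()]; the unknown recovered by
#' [twist_solve()] and the container for phantom truth values.
#'
#' @param values numeric vector (or matrix for 2-D FOVs) of intensities.
#' @param fov the [fov_grid()].
#' @return an object of class `image_estimate`.
#' @export
image_estimate <- function(values, fov) {
  if (!inherits(fov, "fov_grid")) stopf("invalid-argument: `fov` must be a fov_grid")
  v <- as.numeric(values)
  if (length(v) != fov$n_pixels)
    stopf("invalid-argument: %d values for %d pixels", length(v), fov$n_pixels)
  if (any(!is.finite(v))) stopf("invalid-argument: image values must be finite")
  structure(list(values = v, fov = fov), class = "image_estimate")
}

#' @export
print.image_estimate <- function(x, ...) {
  cat(sprintf("<image_estimate> %s pixels, range [%.4g, %.4g]\n",
              paste(x$fov$dims, collapse = " x "), min(x$values), max(x$values)))
  invisible(x)
}

# image values as a matrix shaped like the FOV (2-D FOVs)
image_matrix <- function(x) {
  d <- x$fov$dims
  if (length(d) == 2) matrix(x$values, d[1], d[2]) else x$values
}

phantom_values <- function(x) {
  if (inherits(x, "phantom")) x$values$values
  else if (inherits(x, "image_estimate")) x$values
  else if (is.numeric(x)) as.numeric(x)
  else stopf("invalid-argument: expected a phantom, image_estimate, or numeric vector")
}

fov_of <- function(x) if (inherits(x, "phantom")) x$values$fov else x$fov

#' Synthetic absorber phantom
#'
#' A non-negative test object on a FOV grid plus its footprint mask (the
#' pixels its physical body covers; always a superset of the non-zero
#' support, here the support dilated by `footprint_margin` pixels). The
#' footprint drives coverage-masked boundary variants: an object touches the
#' encoder everywhere its body lies, including non-absorbing parts.
#'
#' @param values an [image_estimate()], all values >= 0.
#' @param footprint_mask logical per-pixel mask covering the support.
#' @param label phantom kind label.
#' @return an object of class `phantom`.
#' @export
phantom <- function(values, footprint_mask, label = "custom") {
  if (!inherits(values, "image_estimate")) stopf("invalid-argument: `values` must be an image_estimate")
  if (any(values$values < 0)) stopf("invalid-argument: phantom values must be >= 0")
  if (length(footprint_mask) != length(values$values))
    stopf("invalid-argument: footprint mask length mismatch")
  if (any(values$values > 0 & !footprint_mask))
    stopf("invalid-argument: footprint mask must cover the phantom support")
  structure(list(values = values, footprint_mask = as.logical(footprint_mask),
                 label = as.character(label)[1]), class = "phantom")
}

# stretch a binary motif over n pixels (nearest-neighbour)
stretch_motif <- function(motif, n) motif[pmin(length(motif), pmax(1L, ceiling(seq_len(n) * length(motif) / n)))]

dilate_mask_1d <- function(m, k) {
  out <- m
  for (s in seq_len(k)) out <- out | c(m[-seq_len(s)], rep(FALSE, s)) | c(rep(FALSE, s), m[seq_len(length(m) - s)])
  out
}

dilate_mask_2d <- function(m, k) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -k:k) for (dc in -k:k) {
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr); cs <- max(1, 1 + dc):min(nc, nc + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    out <- out | sh
  }
  out
}

#' Make a test phantom
#'
#' Binary phantoms of the named shape, centred and scaled to `scale` of the
#' FOV. On 1-D (side-view) FOVs the 2-D letter shapes degrade to fixed bar
#' motifs: C becomes `1,1,0,0,1,1` and T becomes `1,1,1,0,1,0`, stretched to
#' the active extent. `point_pair` places two mirror-symmetric pixels (the
#' symmetric-location discrimination probe); `random_sparse` is seeded
#' Bernoulli with `support_frac` expected support.
#'
#' @param kind one of `"c_shape"`, `"t_shape"`, `"point_pair"`,
#'   `"random_sparse"`.
#' @param fov a [fov_grid()] (1-D line or 2-D abstract grid).
#' @param scale fraction of the FOV the phantom spans (default 1).
#' @param seed seed for `random_sparse`.
#' @param support_frac expected support fraction for `random_sparse`
#'   (default 0.2).
#' @param footprint_margin dilation of the support into the footprint mask,
#'   in pixels, or `NULL` (default) for 0.5 mm worth of pixels (at least 2):
#'   the object's body overhangs its absorbing pattern by a fixed physical
#'   margin, independent of the calibration pitch.
#' @return a [phantom()].
#' @export
make_phantom <- function(kind = c("c_shape", "t_shape", "point_pair", "random_sparse"),
                         fov, scale = 1, seed = 1L, support_frac = 0.2,
                         footprint_margin = NULL) {
  if (is.null(footprint_margin))
    footprint_margin <- max(2L, as.integer(ceiling(0.5e-3 / fov$pitch)))
  kind <- match.arg(kind)
  if (!inherits(fov, "fov_grid")) stopf("invalid-argument: `fov` must be a fov_grid")
  check_number(scale, "scale", positive = TRUE)
  if (scale > 1) stopf("invalid-argument: `scale` must be <= 1")
  if (length(fov$dims) == 2) {
    v <- raster_phantom_2d(kind, fov$dims, scale, seed, support_frac)
  } else {
    n <- fov$n_pixels
    na <- max(1L, round(scale * n))
    lo <- floor((n - na) / 2) + 1L
    act <- lo:(lo + na - 1L)
    v <- numeric(n)
    if (kind == "c_shape") v[act] <- stretch_motif(c(1, 1, 0, 0, 1, 1), na)
    else if (kind == "t_shape") v[act] <- stretch_motif(c(1, 1, 1, 0, 1, 0), na)
    else if (kind == "point_pair") {
      k <- max(1L, round(n / 4))
      v[c(k, n + 1L - k)] <- 1
    } else v[act] <- with_local_seed(seed, as.numeric(runif(na) < support_frac))
  }
  supp <- v > 0
  fp <- if (length(fov$dims) == 2) {
    m <- matrix(supp, fov$dims[1], fov$dims[2])
    as.vector(dilate_mask_2d(m, footprint_margin))
  } else dilate_mask_1d(supp, footprint_margin)
  phantom(image_estimate(v, fov), fp, label = kind)
}

# deterministic rasterizer for 2-D letter phantoms
raster_phantom_2d <- function(kind, dims, scale, seed, support_frac) {
  nr <- dims[1]; nc <- dims[2]
  rr <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
  cc <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
  R <- matrix(rr, nr, nc); C <- matrix(cc, nr, nc, byrow = TRUE)
  v <- matrix(0, nr, nc)
  if (kind == "c_shape") {
    rad <- sqrt(R^2 + C^2); ang <- atan2(R, C)
    v[rad >= 0.45 * scale & rad <= 0.8 * scale & abs(ang) >= pi / 4] <- 1
  } else if (kind == "t_shape") {
    v[abs(R + 0.55 * scale) <= 0.15 * scale & abs(C) <= 0.6 * scale] <- 1  # top bar
    v[R > -0.55 * scale & R <= 0.8 * scale & abs(C) <= 0.15 * scale] <- 1  # stem
  } else if (kind == "point_pair") {
    k <- max(1L, round(nc / 4))
    mid <- ceiling(nr / 2)
    v[mid, c(k, nc + 1L - k)] <- 1
  } else {
    v[] <- with_local_seed(seed, as.numeric(runif(nr * nc) < support_frac))
  }
  as.vector(v)
}

#' Synthetic calibration operator (matrix mode)
#'
#' A physics-free stand-in for the calibration matrix, used to test the
#' reconstruction solver in isolation: columns are seeded Gaussian processes
#' with autocorrelation time `decorrelation_time` samples, normalized to unit
#' norm. With `n_time` samples, the expected pairwise column correlation
#' magnitude scales like `1/sqrt(n_time / decorrelation_time)`.
#'
#' @param n_time number of time samples (rows).
#' @param n_pixels number of pixels (columns); a warning is given if it
#'   exceeds `n_time` (underdetermined operator).
#' @param decorrelation_time autocorrelation time in samples.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param dt nominal sampling interval, seconds (bookkeeping only).
#' @return a [calibration_matrix()] on an abstract FOV.
#' @export
make_matrix_operator <- function(n_time, n_pixels, decorrelation_time = 4, seed = 1L,
                                 dt = 4e-9) {
  n_time <- as.integer(n_time); n_pixels <- as.integer(n_pixels)
  if (is.na(n_time) || n_time < 1 || is.na(n_pixels) || n_pixels < 1)
    stopf("invalid-argument: sizes must be positive")
  check_number(decorrelation_time, "decorrelation_time", positive = TRUE)
  if (n_time < n_pixels)
    warning("matrix operator has fewer time samples than pixels (underdetermined)")
  M <- with_local_seed(seed, {
    s <- decorrelation_time / 2
    k <- seq(-ceiling(4 * s), ceiling(4 * s))
    w <- exp(-k^2 / (2 * s^2)); w <- w / sqrt(sum(w^2))
    apply(matrix(rnorm((n_time + length(k)) * n_pixels), ncol = n_pixels), 2,
          function(z) stats::filter(z, w, sides = 2)[seq_len(n_time) + floor(length(k) / 2)])
  })
  M <- apply(M, 2, function(col) col / sqrt(sum(col^2)))
  d <- if (n_pixels >= 4 && sqrt(n_pixels) == floor(sqrt(n_pixels)))
    c(sqrt(n_pixels), sqrt(n_pixels)) else n_pixels
  calibration_matrix(M, fov_grid_abstract(d), dt = dt,
                     meta = list(method = "matrix_mode", seed = seed,
                                 decorrelation_time = decorrelation_time))
}

#' Pearson correlation between two images
#'
#' The package's quantitative recovery gate: the product-moment correlation
#' of pixel values. Errors if both images are constant (undefined).
#'
#' @param a,b [image_estimate()]s (or phantoms) on the same FOV.
#' @return a correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  va <- phantom_values(a); vb <- phantom_values(b)
  if (length(va) != length(vb)) stopf("invalid-argument: images have different sizes")
  if (sd(va) == 0 && sd(vb) == 0) stopf("undefined-value: both images are constant")
  if (sd(va) == 0 || sd(vb) == 0) stopf("undefined-value: correlation with a constant image is undefined")
  cor(va, vb)
}
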