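#' Calibration matrix (the encoding basis)
#'
#' The system matrix `K = [k_1 ... k_N]`: column `i` is the transducer's
#' recorded impulse response to a point source at FOV pixel `i`. A single-shot
#' widefield trace is modelled as the linear combination `s = sum_i k_i P_i`
#' of these columns weighted by the pixel intensities.
#'
#' @param matrix numeric matrix, time samples x pixels.
#' @param fov the [fov_grid()] the columns are indexed by.
#' @param dt,t0 time axis of the rows (s).
#' @param window the applied [time_window()], or `NULL` if unwindowed.
#' @param norm_factors per-column scaling already applied (default all 1).
#' @param meta provenance list (encoder params, variant label, seeds, ...).
#' @return an object of class `calibration_matrix`.
#' @export
calibration_matrix <- function(matrix, fov, dt, t0 = 0, window = NULL,
                               norm_factors = NULL, meta = list()) {
  if (!is.matrix(matrix) || any(!is.finite(matrix)))
    stopf("invalid-argument: calibration matrix must be finite")
  if (!inherits(fov, "fov_grid")) stopf("invalid-argument: `fov` must be a fov_grid")
  if (ncol(matrix) != fov$n_pixels)
    stopf("invalid-argument: column count (%d) != fov pixels (%d)", ncol(matrix), fov$n_pixels)
  check_number(dt, "dt", positive = TRUE)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(matrix))
  structure(list(matrix = matrix, fov = fov, dt = dt, t0 = t0, window = window,
                 norm_factors = norm_factors, meta = meta),
            class = "calibration_matrix")
}

#' @export
print.calibration_matrix <- function(x, ...) {
  cat(sprintf("<calibration_matrix> %d samples x %d pixels, dt = %.4g ns%s\n",
              nrow(x$matrix), ncol(x$matrix), x$dt * 1e9,
              if (!is.null(x$window)) sprintf(", windowed to %s", window_state(x)) else ""))
  invisible(x)
}

# band-limited, support-truncated source blob for FOV pixel i, centred one
# coupling-layer thickness below the pipe's top face (inside the encoder, so
# the launch itself is identical under every boundary variant)
pixel_blob <- function(grid, geometry, fov, i, source_width, cutoff_wavelength) {
  params <- geometry$params
  ctr <- c(geometry$pipe_center + fov$offsets[i],
           geometry$yTop - max(params$couple_layer_thickness, source_width / 2))
  b <- gaussian_blob(grid, ctr, source_width)
  b <- band_limit_source(b, grid, cutoff_wavelength)
  b <- truncate_blob(b, border = grid$pml_cells + 2L)
  b$label <- sprintf("pixel %d", i)
  b
}

check_source_width <- function(source_width, grid) {
  check_number(source_width, "source_width", positive = TRUE)
  if (source_width < 2 * grid$dx)
    stopf("invalid-argument: source_width (%g mm) must be at least 2*dx (%g mm)",
          source_width * 1e3, 2 * grid$dx * 1e3)
}

#' Pointwise (direct) calibration
#'
#' The reference calibration path: for every FOV pixel, launch a band-limited
#' Gaussian initial-pressure blob just below the pipe's top face and record
#' the transducer trace; column `i` of the result is that trace. This mirrors
#' pointwise scanning of a focused laser beam over the calibration object.
#' Deterministic given the encoder seed.
#'
#' @param grid a [sim_grid()] from [encoder_grid()].
#' @param params an [encoder_params()].
#' @param fov a [fov_grid()] from [place_fov_pixels()].
#' @param variant the [boundary_variant()] present during calibration (or
#'   `NULL` for a bare top face).
#' @param source_width blob full width at half maximum, metres (>= `2*dx`);
#'   default: the FOV pitch.
#' @param cutoff_wavelength spatial band limit passed to
#'   [band_limit_source()]; default 0.4 mm.
#' @param progress print a dot per pixel (default off).
#' @return a [calibration_matrix()] (unwindowed).
#' @export
calibrate_direct <- function(grid, params, fov, variant = NULL,
                             source_width = fov$pitch,
                             cutoff_wavelength = 0.4e-3, progress = FALSE) {
  check_source_width(source_width, grid)
  enc <- build_encoder_medium(params, grid, variant, fov)
  cols <- matrix(0, grid$nt, fov$n_pixels)
  for (i in seq_len(fov$n_pixels)) {
    b <- pixel_blob(grid, enc$geometry, fov, i, source_width, cutoff_wavelength)
    tr <- tryCatch(simulate_wave(grid, enc$medium, b, enc$sensor)[[1]],
                   error = function(e) stopf("calibration failed at pixel %d: %s", i, conditionMessage(e)))
    cols[, i] <- tr$values
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  calibration_matrix(cols, fov, dt = grid$dt, t0 = 0,
                     meta = list(params = params,
                                 variant = if (is.null(variant)) "none" else variant$label,
                                 source_width = source_width,
                                 cutoff_wavelength = cutoff_wavelength,
                                 method = "direct", seed = params$seed))
}

#' Reciprocity-based (fast) calibration
#'
#' One simulation instead of one per pixel: by acoustic reciprocity, sourcing
#' at the transducer and recording at each pixel's blob footprint yields the
#' same traces as the direct path. For heterogeneous media the discrete
#' scheme is reciprocal under compressibility weighting, so the reciprocal
#' source carries weights `kappa * m` (aperture mean weights `m`) and each
#' pixel recorder carries weights `w / kappa` (blob weights `w`), with
#' `kappa = rho c^2` evaluated per cell. Agreement with [calibrate_direct()]
#' is exact up to absorbing-layer asymmetry.
#'
#' @inheritParams calibrate_direct
#' @return a [calibration_matrix()] (unwindowed).
#' @export
calibrate_reciprocal <- function(grid, params, fov, variant = NULL,
                                 source_width = fov$pitch,
                                 cutoff_wavelength = 0.4e-3) {
  check_source_width(source_width, grid)
  enc <- build_encoder_medium(params, grid, variant, fov)
  kappa <- enc$medium$density * enc$medium$sound_speed^2
  nx <- grid$shape[1]

  # reciprocal source: kappa-weighted transducer aperture
  ap <- enc$sensor$cells
  m <- rep(1 / nrow(ap), nrow(ap))
  p0 <- matrix(0, grid$shape[1], grid$shape[2])
  p0[ap] <- kappa[ap] * m
  src <- initial_pressure(p0, label = "reciprocal@transducer")

  # one recorder per pixel: blob weights over kappa
  sensors <- vector("list", fov$n_pixels)
  for (i in seq_len(fov$n_pixels)) {
    b <- pixel_blob(grid, enc$geometry, fov, i, source_width, cutoff_wavelength)
    nz <- which(b$p0 != 0, arr.ind = TRUE)
    w <- b$p0[nz] / kappa[nz]
    sensors[[i]] <- sensor_spec(nz, weights = w)
  }
  traces <- simulate_wave(grid, enc$medium, src, sensors)
  cols <- vapply(traces, function(tr) tr$values, numeric(grid$nt))
  calibration_matrix(cols, fov, dt = grid$dt, t0 = 0,
                     meta = list(params = params,
                                 variant = if (is.null(variant)) "none" else variant$label,
                                 source_width = source_width,
                                 cutoff_wavelength = cutoff_wavelength,
                                 method = "reciprocal", seed = params$seed))
}
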