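#' Single-shot widefield measurement
#'
#' The transducer trace recorded when the whole FOV is illuminated at once,
#' plus the laser pulse energy it was acquired at (for later normalization)
#' and the label of the boundary variant present during the measurement.
#'
#' @param trace a [pressure_trace()].
#' @param pulse_energy pulse energy in arbitrary units, > 0.
#' @param variant_label free-text label of the boundary condition.
#' @return an object of class `widefield_measurement`.
#' @export
widefield_measurement <- function(trace, pulse_energy = 1, variant_label = "none") {
  if (!inherits(trace, "pressure_trace")) stopf("invalid-argument: `trace` must be a pressure_trace")
  check_number(pulse_energy, "pulse_energy", positive = TRUE)
  structure(list(trace = trace, pulse_energy = pulse_energy,
                 variant_label = as.character(variant_label)[1]),
            class = "widefield_measurement")
}

#' @export
print.widefield_measurement <- function(x, ...) {
  cat(sprintf("<widefield_measurement> %d samples, pulse energy %.4g, boundary '%s'%s\n",
              length(x$trace$values), x$pulse_energy, x$variant_label,
              if (!is.null(x$trace$meta$window)) " (windowed)" else ""))
  invisible(x)
}

#' Synthesize a single-shot widefield measurement (full physics)
#'
#' Runs one wave simulation whose initial pressure is the superposition of
#' the per-pixel calibration blobs weighted by the phantom's pixel values --
#' the in-silico analogue of flooding the object with a broad laser beam.
#' The recorded trace is scaled by the pulse energy; optional additive white
#' Gaussian noise is referenced to the RMS of the boundary-safe-windowed
#' signal. By solver linearity the result equals `K %*% P` when the boundary
#' variant matches the calibration variant; under a different variant the two
#' diverge outside the boundary-safe window.
#'
#' @inheritParams calibrate_direct
#' @param variant the [boundary_variant()] present during the measurement.
#' @param phantom a [phantom()] or [image_estimate()] on `fov`; values >= 0.
#' @param pulse_energy pulse energy scaling the trace (default 1).
#' @param noise_snr_db if not `NULL`, add white Gaussian noise at this SNR
#'   (dB) relative to the windowed signal RMS.
#' @param seed seed for the noise (required when noise is on).
#' @return a [widefield_measurement()] (unwindowed).
#' @export
synthesize_widefield <- function(grid, params, variant, phantom, fov,
                                 pulse_energy = 1, noise_snr_db = NULL,
                                 seed = NULL, source_width = fov$pitch,
                                 cutoff_wavelength = 0.4e-3) {
  check_source_width(source_width, grid)
  check_number(pulse_energy, "pulse_energy", positive = TRUE)
  P <- phantom_values(phantom)
  if (length(P) != fov$n_pixels)
    stopf("invalid-argument: phantom has %d pixels but fov has %d", length(P), fov$n_pixels)
  if (any(P < 0)) stopf("invalid-argument: phantom values must be >= 0")
  enc <- build_encoder_medium(params, grid, variant, fov)
  p0 <- matrix(0, grid$shape[1], grid$shape[2])
  for (i in which(P != 0)) {
    b <- pixel_blob(grid, enc$geometry, fov, i, source_width, cutoff_wavelength)
    p0 <- p0 + P[i] * b$p0
  }
  src <- initial_pressure(p0, label = "widefield")
  tr <- simulate_wave(grid, enc$medium, src, enc$sensor)[[1]]
  tr$values <- tr$values * pulse_energy
  if (!is.null(noise_snr_db)) {
    w <- boundary_safe_window(params)
    ref <- apply_window(tr, w)
    rms <- sqrt(mean(ref$values^2))
    sdn <- rms * 10^(-noise_snr_db / 20)
    tr$values <- tr$values + with_local_seed(seed, rnorm(length(tr$values), 0, sdn))
    tr$meta$noise_snr_db <- noise_snr_db
    tr$meta$noise_seed <- seed
  }
  tr$meta$variant <- variant_label_of(variant)
  widefield_measurement(tr, pulse_energy, variant_label_of(variant))
}

variant_label_of <- function(variant) if (is.null(variant)) "none" else variant$label

#' Project an image through the calibration basis
#'
#' The linear forward model: returns `K %*% P`, the synthetic single-shot
#' trace predicted for image `P`, carrying the same windowing state as `K`.
#'
#' @param K a [calibration_matrix()].
#' @param P an [image_estimate()] (or [phantom()]) on `K$fov`.
#' @return a [pressure_trace()].
#' @export
project_widefield <- function(K, P) {
  if (!inherits(K, "calibration_matrix")) stopf("invalid-argument: `K` must be a calibration_matrix")
  v <- phantom_values(P)
  if (length(v) != ncol(K$matrix))
    stopf("invalid-argument: image has %d pixels but K has %d columns", length(v), ncol(K$matrix))
  if (inherits(P, c("image_estimate", "phantom")) && !same_fov(fov_of(P), K$fov))
    stopf("invalid-argument: image fov does not match calibration fov")
  pressure_trace(as.numeric(K$matrix %*% v), dt = K$dt, t0 = K$t0,
                 meta = list(source = "projection", window = K$window))
}

#' Normalize a measurement by its pulse energy
#'
#' Divides the trace by the recorded pulse energy and resets the energy to 1
#' (the photodiode correction for shot-to-shot laser fluctuations);
#' idempotent.
#'
#' @param m a [widefield_measurement()].
#' @return the normalized [widefield_measurement()].
#' @export
energy_normalize <- function(m) {
  if (!inherits(m, "widefield_measurement")) stopf("invalid-argument: `m` must be a widefield_measurement")
  if (!is.finite(m$pulse_energy) || m$pulse_energy <= 0)
    stopf("invalid-argument: pulse_energy must be > 0")
  m$trace$values <- m$trace$values / m$pulse_energy
  m$pulse_energy <- 1
  m
}
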