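#' Symmetric-source discrimination experiment
#'
#' A single centred transducer in a bare homogeneous medium records (nearly)
#' identical traces from two mirror-symmetric point sources -- it cannot tell
#' them apart. The same pair launched into the encoder produces decorrelated
#' traces, because the pipe-plus-prism geometry (transducer off at the prism
#' corner, randomized rough edges) maps each position to a distinctive time
#' series. Reports the trace correlation in both settings.
#'
#' @param preset preset name for the encoder setting (see [encoder_preset()]).
#' @param pair_offset_pixels half-separation of the mirrored sources, in FOV
#'   pixels from the centre (default 4).
#' @return a tibble with columns `setting`, `trace_correlation`.
#' @export
run_symmetric_pair_test <- function(preset = "demo_2d", pair_offset_pixels = 4L) {
  ps <- encoder_preset(preset)

  # (a) bare homogeneous medium, sensor centred under the sources; an odd
  # cell count keeps the mirrored pair exactly symmetric on the lattice
  g <- build_grid(c(24.1e-3, 16e-3), dx = ps$dx, duration = 12e-6, cfl = ps$cfl,
                  c_max = 1500, pml_cells = ps$pml_cells)
  med <- uniform_medium(g, c = 1500, rho = 1000)
  ic <- (g$shape[1] + 1L) %/% 2L
  xc <- (ic - 0.5) * g$dx
  y_src <- g$shape[2] * g$dx - (g$pml_cells + 12) * g$dx
  off <- 3e-3
  sensor <- sensor_spec(cbind(ic, g$pml_cells + 10L))
  mk <- function(x) truncate_blob(band_limit_source(
    gaussian_blob(g, c(x, y_src), ps$source_width), g, ps$cutoff_wavelength),
    border = g$pml_cells + 2L)
  ta <- simulate_wave(g, med, mk(xc - off), sensor)[[1]]
  tb <- simulate_wave(g, med, mk(xc + off), sensor)[[1]]
  r_bare <- cor(ta$values, tb$values)

  # (b) the encoder, mirrored FOV pixels
  grid <- encoder_grid(ps$params, ps$duration, dx = ps$dx, cfl = ps$cfl,
                       pml_cells = ps$pml_cells)
  fov <- place_fov_pixels(ps$params, ps$fov_extent, ps$fov_pitch)
  enc <- build_encoder_medium(ps$params, grid, variant = NULL, fov = fov)
  mid <- (fov$n_pixels + 1) / 2
  i1 <- round(mid - pair_offset_pixels); i2 <- round(mid + pair_offset_pixels)
  b1 <- pixel_blob(grid, enc$geometry, fov, i1, ps$source_width, ps$cutoff_wavelength)
  b2 <- pixel_blob(grid, enc$geometry, fov, i2, ps$source_width, ps$cutoff_wavelength)
  t1 <- simulate_wave(grid, enc$medium, b1, enc$sensor)[[1]]
  t2 <- simulate_wave(grid, enc$medium, b2, enc$sensor)[[1]]
  r_enc <- cor(t1$values, t2$values)

  tibble::tibble(setting = c("bare_medium", "encoder"),
                 trace_correlation = c(r_bare, r_enc))
}

#' Changed-boundary reconstruction comparison
#'
#' The head-to-head experiment: calibrate once under `calibration_variant`
#' (a full-coverage layer, the calibration object), then acquire a
#' single-shot widefield measurement of `phantom` under
#' `measurement_variant` (a layer covering only the object footprint -- the
#' boundary condition has changed). Reconstruct twice from the same
#' measurement: from the boundary-safe window (`windowed`) and from the full
#' trace without windowing (`full_trace`, ergodic-relay style). Reports the
#' Pearson correlation of each reconstruction with the ground truth and
#' their gap.
#'
#' At the full experimental scale, full-trace reconstruction collapses when
#' the boundary changes, which is the windowing's raison d'etre. In this
#' desk-scale 2-D model the full-trace fit is far more overdetermined than
#' at full scale and typically remains serviceable; see the methods
#' vignette for the quantitative discussion.
#'
#' @param preset preset name (see [encoder_preset()]).
#' @param phantom_kind phantom passed to [make_phantom()] (default
#'   `"c_shape"`).
#' @param K optional pre-computed [calibration_matrix()] for the preset's
#'   calibration variant (skips recalibration).
#' @param cfg a [recon_config()].
#' @param phantom_scale fraction of the FOV the measured object spans
#'   (default 0.8: objects are placed inside the calibrated FOV).
#' @param matched_boundary if `TRUE`, measure under the calibration variant
#'   instead (control run: both modes should succeed).
#' @return a list of class `boundary_comparison_report`: tibble `summary`
#'   (`mode`, `pearson_r`), `gap`, the truth and both estimates, and the
#'   calibration matrix (for re-use).
#' @export
run_boundary_mismatch_experiment <- function(preset = "demo_2d",
                                             phantom_kind = "c_shape",
                                             K = NULL, cfg = recon_config(),
                                             phantom_scale = 0.8,
                                             matched_boundary = FALSE) {
  ps <- encoder_preset(preset)
  grid <- encoder_grid(ps$params, ps$duration, dx = ps$dx, cfl = ps$cfl,
                       pml_cells = ps$pml_cells)
  fov <- place_fov_pixels(ps$params, ps$fov_extent, ps$fov_pitch)
  ph <- make_phantom(phantom_kind, fov, scale = phantom_scale)
  cal_variant <- ps$cal_variant
  meas_variant <- if (matched_boundary) cal_variant
  else boundary_variant(coverage_mask = ph$footprint_mask,
                        label = sprintf("%s footprint", ph$label))
  if (is.null(K))
    K <- calibrate_direct(grid, ps$params, fov, cal_variant,
                          source_width = ps$source_width,
                          cutoff_wavelength = ps$cutoff_wavelength)
  s <- synthesize_widefield(grid, ps$params, meas_variant, ph, fov,
                            source_width = ps$source_width,
                            cutoff_wavelength = ps$cutoff_wavelength)
  fit_w <- reconstruct(K, s, cfg, window = "auto")
  fit_f <- reconstruct(K, s, cfg, window = "none")
  r_w <- pearson_r(fit_w$estimate, ph)
  r_f <- pearson_r(fit_f$estimate, ph)
  structure(list(summary = tibble::tibble(mode = c("windowed", "full_trace"),
                                          pearson_r = c(r_w, r_f)),
                 gap = r_w - r_f, phantom = ph,
                 estimate_windowed = fit_w$estimate,
                 estimate_full = fit_f$estimate,
                 calibration = K, preset = preset,
                 calibration_variant = cal_variant$label,
                 measurement_variant = meas_variant$label),
            class = "boundary_comparison_report")
}

#' @export
print.boundary_comparison_report <- function(x, ...) {
  cat(sprintf("<boundary_comparison_report> preset %s, phantom %s\n  calibration boundary: %s\n  measurement boundary: %s\n",
              x$preset, x$phantom$label, x$calibration_variant, x$measurement_variant))
  print(x$summary)
  cat(sprintf("  gap (windowed - full_trace): %.3f\n", x$gap))
  invisible(x)
}

#' @rdname run_boundary_mismatch_experiment
#' @param x a `boundary_comparison_report`.
#' @param ... unused.
#' @export
tidy.boundary_comparison_report <- function(x, ...) x$summary

#' Single-calibration recovery of multiple objects
#'
#' With one calibration matrix, measures and reconstructs several different
#' phantoms (each under its own footprint boundary variant, single shot, no
#' recalibration) and reports the recovery correlation per phantom.
#'
#' @param preset preset name.
#' @param phantom_kinds character vector of phantom kinds (default C and T).
#' @param K optional pre-computed calibration matrix for the preset.
#' @param cfg a [recon_config()].
#' @param phantom_scale fraction of the FOV each object spans (default 0.8).
#' @return a tibble with columns `phantom`, `pearson_r`, plus attributes
#'   `estimates` and `calibration`.
#' @export
run_single_calibration_recovery <- function(preset = "demo_2d",
                                            phantom_kinds = c("c_shape", "t_shape"),
                                            K = NULL, cfg = recon_config(),
                                            phantom_scale = 0.8) {
  ps <- encoder_preset(preset)
  grid <- encoder_grid(ps$params, ps$duration, dx = ps$dx, cfl = ps$cfl,
                       pml_cells = ps$pml_cells)
  fov <- place_fov_pixels(ps$params, ps$fov_extent, ps$fov_pitch)
  if (is.null(K))
    K <- calibrate_direct(grid, ps$params, fov, ps$cal_variant,
                          source_width = ps$source_width,
                          cutoff_wavelength = ps$cutoff_wavelength)
  rs <- numeric(0); ests <- list()
  for (kind in phantom_kinds) {
    ph <- make_phantom(kind, fov, scale = phantom_scale)
    mv <- boundary_variant(coverage_mask = ph$footprint_mask,
                           label = sprintf("%s footprint", kind))
    s <- synthesize_widefield(grid, ps$params, mv, ph, fov,
                              source_width = ps$source_width,
                              cutoff_wavelength = ps$cutoff_wavelength)
    fit <- reconstruct(K, s, cfg, window = "auto")
    rs <- c(rs, pearson_r(fit$estimate, ph))
    ests[[kind]] <- fit$estimate
  }
  out <- tibble::tibble(phantom = phantom_kinds, pearson_r = rs)
  attr(out, "estimates") <- ests
  attr(out, "calibration") <- K
  out
}
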