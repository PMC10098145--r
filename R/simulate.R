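#' Sensor specification
#'
#' An aperture made of grid cells whose pressures are combined into one
#' recorded sample per time step. The only reduction offered is the
#' arithmetic mean, which models a small flat transducer face in contact with
#' the medium.
#'
#' @param cells two-column integer matrix of cell indices `(i, j)` forming the
#'   aperture (1-based).
#' @param reduction how per-cell pressures combine; `"mean"`.
#' @param weights optional per-cell weights overriding the mean reduction
#'   (used internally for reciprocity-based calibration).
#' @return an object of class `sensor_spec`.
#' @export
sensor_spec <- function(cells, reduction = c("mean"), weights = NULL) {
  reduction <- match.arg(reduction)
  cells <- matrix(as.integer(cells), ncol = 2)
  if (nrow(cells) == 0) stopf("invalid-argument: sensor aperture must be non-empty")
  if (!is.null(weights) && length(weights) != nrow(cells))
    stopf("invalid-argument: sensor weights length must match cell count")
  structure(list(cells = cells, reduction = reduction, weights = weights),
            class = "sensor_spec")
}

#' Pressure time series recorded by a sensor
#'
#' @param values numeric vector, one pressure sample per time step.
#' @param dt sampling interval (s).
#' @param t0 time of the first sample (s).
#' @param meta named list of provenance (source label, geometry, seed, window).
#' @return an object of class `pressure_trace`.
#' @export
pressure_trace <- function(values, dt, t0 = 0, meta = list()) {
  if (any(!is.finite(values))) stopf("invalid-argument: trace values must be finite")
  check_number(dt, "dt", positive = TRUE)
  check_number(t0, "t0", nonneg = TRUE)
  structure(list(values = as.numeric(values), dt = dt, t0 = t0, meta = meta),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %d samples, dt = %.4g ns, t0 = %.4g us, span %.4g us%s\n",
              length(x$values), x$dt * 1e9, x$t0 * 1e6,
              (x$t0 + length(x$values) * x$dt) * 1e6,
              if (!is.null(x$meta$window)) " (windowed)" else ""))
  invisible(x)
}

#' Time axis of a trace
#' @param trace a [pressure_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) trace$t0 + (seq_along(trace$values) - 1) * trace$dt

#' Simulate acoustic wave propagation
#'
#' Runs the staggered-grid finite-difference time-domain solver for linear
#' lossless acoustics (first-order pressure/particle-velocity form) over a
#' heterogeneous medium, with a split-field perfectly matched layer absorbing
#' the outer boundary. The source is an initial pressure distribution with
#' zero initial velocity, the photoacoustic generation model. The solver is
#' exactly linear in the source and deterministic.
#'
#' @param grid a [sim_grid()]; `grid$dt` must satisfy [stable_timestep()] for
#'   the medium.
#' @param medium a [medium_map()] matching the grid shape.
#' @param source an [initial_pressure()] whose support lies strictly inside
#'   the non-PML interior.
#' @param sensors a list of [sensor_spec()] (or a single one).
#' @param record_fields_every if > 0, also return full pressure-field
#'   snapshots every that many steps (attribute `"fields"` of the result).
#' @return a list of [pressure_trace()], one per sensor, each of length
#'   `grid$nt`.
#' @export
simulate_wave <- function(grid, medium, source, sensors, record_fields_every = 0L) {
  if (!inherits(grid, "sim_grid")) stopf("invalid-argument: `grid` must be a sim_grid")
  if (!inherits(medium, "medium_map")) stopf("invalid-argument: `medium` must be a medium_map")
  if (!inherits(source, "initial_pressure")) stopf("invalid-argument: `source` must be an initial_pressure")
  check_medium_grid(medium, grid)
  check_medium_shape(source$p0, grid)
  if (inherits(sensors, "sensor_spec")) sensors <- list(sensors)
  if (length(sensors) == 0) stopf("invalid-argument: at least one sensor required")
  nx <- grid$shape[1]; ny <- grid$shape[2]; pml <- grid$pml_cells
  if (pml > 0 && any(source$p0[c(seq_len(pml), nx - seq_len(pml) + 1L), ] != 0) ||
      pml > 0 && any(source$p0[, c(seq_len(pml), ny - seq_len(pml) + 1L)] != 0))
    stopf("invalid-argument: source support must lie strictly inside the non-PML interior")
  idx <- vector("list", length(sensors)); wgt <- vector("list", length(sensors))
  for (s in seq_along(sensors)) {
    sp <- sensors[[s]]
    if (!inherits(sp, "sensor_spec")) stopf("invalid-argument: sensors must be sensor_spec objects")
    ij <- sp$cells
    if (any(ij[, 1] < 1L) || any(ij[, 1] > nx) || any(ij[, 2] < 1L) || any(ij[, 2] > ny))
      stopf("invalid-argument: sensor %d has cells outside the grid", s)
    if (pml > 0 && (any(ij[, 1] <= pml) || any(ij[, 1] > nx - pml) ||
                    any(ij[, 2] <= pml) || any(ij[, 2] > ny - pml)))
      stopf("invalid-argument: sensor %d has cells inside the PML", s)
    idx[[s]] <- (ij[, 1] - 1L) + nx * (ij[, 2] - 1L)
    wgt[[s]] <- if (is.null(sp$weights)) rep(1 / nrow(ij), nrow(ij)) else as.numeric(sp$weights)
  }
  out <- fdtd_run(medium$sound_speed, medium$density, source$p0,
                  grid$dx, grid$dt, grid$nt, pml,
                  idx, wgt, as.integer(record_fields_every))
  traces <- lapply(seq_along(sensors), function(s)
    pressure_trace(out$traces[, s], dt = grid$dt, t0 = 0,
                   meta = list(source = source$label, sensor = s)))
  if (record_fields_every > 0)
    attr(traces, "fields") <- list(fields = out$fields, steps = out$field_steps, dx = grid$dx, dt = grid$dt)
  traces
}

#' First arrival time of a trace
#'
#' Time of the first sample whose magnitude reaches `threshold_frac` of the
#' trace's peak magnitude. Returns `Inf` for an all-zero trace.
#'
#' @param trace a [pressure_trace()].
#' @param threshold_frac detection threshold as a fraction of the peak, in
#'   `(0, 1)`; default 0.05.
#' @return arrival time in seconds (or `Inf`).
#' @export
first_arrival_time <- function(trace, threshold_frac = 0.05) {
  if (!inherits(trace, "pressure_trace")) stopf("invalid-argument: `trace` must be a pressure_trace")
  check_number(threshold_frac, "threshold_frac", positive = TRUE)
  if (threshold_frac >= 1) stopf("invalid-argument: `threshold_frac` must be in (0, 1)")
  peak <- max(abs(trace$values))
  if (peak == 0) return(Inf)
  k <- which(abs(trace$values) >= threshold_frac * peak)[1]
  trace$t0 + (k - 1) * trace$dt
}
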