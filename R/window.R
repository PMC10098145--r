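#' Time window
#'
#' Half-open interval `[t_start, t_end)` in seconds applied to traces and
#' calibration matrices.
#'
#' @param t_start window start (s), >= 0.
#' @param t_end window end (s), > `t_start`.
#' @return an object of class `time_window`.
#' @export
time_window <- function(t_start, t_end) {
  check_number(t_start, "t_start", nonneg = TRUE)
  check_number(t_end, "t_end", positive = TRUE)
  if (t_start >= t_end) stopf("invalid-argument: t_start must be < t_end")
  structure(list(t_start = t_start, t_end = t_end), class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window> [%.4g, %.4g) us\n", x$t_start * 1e6, x$t_end * 1e6))
  invisible(x)
}

#' Boundary-independent time window
#'
#' The early portion of the recorded signal is independent of the boundary
#' condition on the pipe's top face: boundary-reflected energy must first
#' descend the pipe, return to the top after a reflection in the prism, and
#' descend again, i.e. traverse the pipe three times, before it can reach the
#' transducer -- any path inside the prism adds strictly positive time. The
#' window therefore ends at `3 * pipe_length / c_encoder`; its start is 0
#' (leading zeros before the first arrival are harmless to the solver).
#'
#' @param params an [encoder_params()].
#' @return a [time_window()] `[0, 3L/c)`.
#' @examples
#' p <- encoder_preset("fig3_2d")$params
#' boundary_safe_window(p)$t_end * 1e6  # ~30.51 us
#' @export
boundary_safe_window <- function(params) {
  if (!inherits(params, "encoder_params")) stopf("invalid-argument: `params` must be encoder_params")
  time_window(0, 3 * params$pipe_length / params$c_encoder)
}

window_keep_idx <- function(n, dt, t0, w) {
  if (w$t_end > t0 + n * dt + dt / 2)
    stopf("invalid-argument: window end %.4g us is beyond the recorded duration %.4g us",
          w$t_end * 1e6, (t0 + n * dt) * 1e6)
  t <- t0 + (seq_len(n) - 1) * dt
  which(t >= w$t_start - dt * 1e-6 & t < w$t_end - dt * 1e-6)
}

#' Apply a time window
#'
#' Drops samples outside `[t_start, t_end)` and records the window in the
#' object's metadata so it can be re-applied identically elsewhere; applying
#' the same window twice is a no-op. Works on pressure traces, widefield
#' measurements, and calibration matrices (column-wise).
#'
#' @param x a [pressure_trace()], [widefield_measurement()] or
#'   [calibration_matrix()].
#' @param w a [time_window()] inside the recorded duration.
#' @return the same type of object, cropped.
#' @export
apply_window <- function(x, w) UseMethod("apply_window")

#' @export
apply_window.pressure_trace <- function(x, w) {
  if (!inherits(w, "time_window")) stopf("invalid-argument: `w` must be a time_window")
  keep <- window_keep_idx(length(x$values), x$dt, x$t0, w)
  if (length(keep) == 0) stopf("invalid-argument: window retains no samples")
  x$values <- x$values[keep]
  x$t0 <- x$t0 + (keep[1] - 1) * x$dt
  x$meta$window <- w
  x
}

#' @export
apply_window.widefield_measurement <- function(x, w) {
  x$trace <- apply_window(x$trace, w)
  x
}

#' @export
apply_window.calibration_matrix <- function(x, w) {
  if (!inherits(w, "time_window")) stopf("invalid-argument: `w` must be a time_window")
  keep <- window_keep_idx(nrow(x$matrix), x$dt, x$t0, w)
  if (length(keep) == 0) stopf("invalid-argument: window retains no samples")
  x$matrix <- x$matrix[keep, , drop = FALSE]
  x$t0 <- x$t0 + (keep[1] - 1) * x$dt
  x$window <- w
  x
}

# comparable description of an object's windowing state
window_state <- function(x) {
  w <- if (inherits(x, "calibration_matrix")) x$window
  else if (inherits(x, "widefield_measurement")) x$trace$meta$window
  else x$meta$window
  if (is.null(w)) "full" else sprintf("[%.6g,%.6g)us", w$t_start * 1e6, w$t_end * 1e6)
}
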