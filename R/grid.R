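#' Simulation grid
#'
#' A regular Cartesian grid for the acoustic solver: cell counts per axis, the
#' cell edge `dx` (m), the time step `dt` (s), the number of time steps `nt`,
#' and the thickness of the absorbing boundary layer (`pml_cells`, per side).
#' All quantities are SI.
#'
#' @param shape integer vector (length 2), cells per axis.
#' @param dx cell edge length in metres.
#' @param dt time step in seconds.
#' @param nt number of time steps (>= 1).
#' @param pml_cells absorbing-layer thickness in cells per side (>= 0).
#' @return an object of class `sim_grid`.
#' @seealso [build_grid()], [stable_timestep()]
#' @export
sim_grid <- function(shape, dx, dt, nt, pml_cells = 12L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stopf("invalid-argument: `shape` must be two positive cell counts")
  check_number(dx, "dx", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  nt <- as.integer(nt)
  if (length(nt) != 1L || is.na(nt) || nt < 1L) stopf("invalid-argument: `nt` must be >= 1")
  pml_cells <- as.integer(pml_cells)
  if (length(pml_cells) != 1L || is.na(pml_cells) || pml_cells < 0L)
    stopf("invalid-argument: `pml_cells` must be >= 0")
  if (any(shape <= 2L * pml_cells))
    stopf("invalid-argument: grid of shape %s leaves no interior inside %d PML cells",
          paste(shape, collapse = "x"), pml_cells)
  structure(list(shape = shape, dx = dx, dt = dt, nt = nt, pml_cells = pml_cells),
            class = "sim_grid")
}

#' Build a simulation grid from physical extents
#'
#' Chooses the cell counts from the requested extents, and the time step from
#' the Courant-Friedrichs-Lewy (CFL) condition `dt = cfl * dx / c_max`.
#'
#' @param extent numeric vector (length 2), physical extent per axis in metres.
#'   Each extent must be an integer multiple of `dx` (to within one-cell
#'   tolerance); the cell count is `round(extent / dx)`.
#' @param dx cell edge length in metres.
#' @param duration simulated duration in seconds; `nt = ceiling(duration/dt)`.
#' @param cfl Courant number in `(0, 1]`; the staggered scheme used by
#'   [simulate_wave()] is stable in 2-D for `cfl <= 1/sqrt(2)`. Default 0.3.
#' @param c_max largest sound speed of the medium the grid will carry (m/s).
#' @param pml_cells absorbing-layer thickness per side, default 12.
#' @return a [sim_grid()].
#' @examples
#' g <- build_grid(c(10e-3, 90e-3), dx = 0.1e-3, duration = 20e-6, c_max = 5900)
#' g$shape   # 100 x 900
#' @export
build_grid <- function(extent, dx, duration, cfl = 0.3, c_max = 1500, pml_cells = 12L) {
  if (length(extent) != 2L || any(!is.finite(extent)) || any(extent <= 0))
    stopf("invalid-argument: `extent` must be two positive lengths in metres")
  check_number(dx, "dx", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  check_number(cfl, "cfl", positive = TRUE)
  if (cfl > 1) stopf("invalid-argument: `cfl` must be in (0, 1]")
  check_number(c_max, "c_max", positive = TRUE)
  shape <- round(extent / dx)
  if (any(abs(extent / dx - shape) > 1 + 1e-9))
    stopf("invalid-argument: `extent` is not divisible into whole cells of `dx`")
  dt <- cfl * dx / c_max
  nt <- as.integer(ceiling(duration / dt))
  sim_grid(shape, dx = dx, dt = dt, nt = nt, pml_cells = pml_cells)
}

#' Largest stable time step for a medium
#'
#' Returns `cfl * dx / max(sound_speed)`. At the default `cfl = 0.3` the
#' staggered-grid scheme in [simulate_wave()] is stable (the 2-D bound is
#' `1/sqrt(2)`).
#'
#' @param medium a [medium_map()].
#' @param dx cell edge in metres.
#' @param cfl Courant number in `(0, 1]`, default 0.3.
#' @return a time step in seconds.
#' @export
stable_timestep <- function(medium, dx, cfl = 0.3) {
  if (!inherits(medium, "medium_map")) stopf("invalid-argument: `medium` must be a medium_map")
  if (length(medium$sound_speed) == 0) stopf("invalid-argument: empty medium")
  check_number(dx, "dx", positive = TRUE)
  check_number(cfl, "cfl", positive = TRUE)
  if (cfl > 1) stopf("invalid-argument: `cfl` must be in (0, 1]")
  cfl * dx / max(medium$sound_speed)
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d cells, dx = %.4g mm, dt = %.4g ns, nt = %d (%.3g us), PML %d cells\n",
              x$shape[1], x$shape[2], x$dx * 1e3, x$dt * 1e9, x$nt, x$nt * x$dt * 1e6, x$pml_cells))
  invisible(x)
}

# cell-centre coordinates along one axis (metres)
axis_coords <- function(n, dx) (seq_len(n) - 0.5) * dx
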