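#' Initial pressure distribution
#'
#' The photoacoustic source model: a short laser pulse deposits heat in the
#' absorber, which launches an acoustic wave from an initial pressure field
#' `p0` (Pa) at `t = 0`, with zero initial particle velocity.
#'
#' @param p0 numeric matrix of initial pressures (finite).
#' @param label free-text provenance label.
#' @return an object of class `initial_pressure`.
#' @export
initial_pressure <- function(p0, label = "") {
  if (!is.matrix(p0) || any(!is.finite(p0)))
    stopf("invalid-argument: `p0` must be a finite numeric matrix")
  structure(list(p0 = p0, label = as.character(label)[1]), class = "initial_pressure")
}

# gaussian pressure blob; width is the full width at half maximum (metres)
gaussian_blob <- function(grid, center, width, amplitude = 1) {
  sigma <- width / (2 * sqrt(2 * log(2)))
  x <- axis_coords(grid$shape[1], grid$dx)
  y <- axis_coords(grid$shape[2], grid$dx)
  gx <- exp(-(x - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(y - center[2])^2 / (2 * sigma^2))
  initial_pressure(amplitude * outer(gx, gy), label = sprintf("blob@(%g,%g)mm", center[1] * 1e3, center[2] * 1e3))
}

#' Spatially band-limit an initial pressure field
#'
#' Applies a smooth isotropic low-pass filter in the spatial-frequency domain
#' (super-Gaussian of order 8, 1% transmission at the cutoff), suppressing
#' sub-grid spatial frequencies that the discrete scheme would propagate with
#' large dispersion error. The filter has unit DC gain, so the total of `p0`
#' over all cells is conserved.
#'
#' @param p0 an [initial_pressure()].
#' @param grid the [sim_grid()] the field lives on.
#' @param cutoff_wavelength spatial cutoff in metres; must be >= `2 * dx`
#'   (the grid Nyquist wavelength).
#' @return a band-limited [initial_pressure()].
#' @export
band_limit_source <- function(p0, grid, cutoff_wavelength) {
  if (!inherits(p0, "initial_pressure")) stopf("invalid-argument: `p0` must be an initial_pressure")
  check_medium_shape(p0$p0, grid)
  check_number(cutoff_wavelength, "cutoff_wavelength", positive = TRUE)
  if (cutoff_wavelength < 2 * grid$dx - 1e-12)
    stopf("invalid-argument: cutoff_wavelength (%g m) is below the grid Nyquist wavelength 2*dx = %g m",
          cutoff_wavelength, 2 * grid$dx)
  n <- dim(p0$p0)
  kx <- fft_freq(n[1], grid$dx)
  ky <- fft_freq(n[2], grid$dx)
  kc <- 2 * pi / cutoff_wavelength
  kk <- sqrt(outer(kx^2, ky^2, `+`))
  H <- exp(log(0.01) * (kk / kc)^4)
  sm <- Re(fft(fft(p0$p0) * H, inverse = TRUE)) / length(p0$p0)
  initial_pressure(sm, label = p0$label)
}

# angular spatial frequencies for an FFT axis (rad/m)
fft_freq <- function(n, dx) {
  i <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * i / (n * dx)
}

check_medium_shape <- function(field, grid) {
  if (!all(dim(field) == grid$shape))
    stopf("invalid-argument: field shape (%s) does not match grid shape (%s)",
          paste(dim(field), collapse = "x"), paste(grid$shape, collapse = "x"))
  invisible(TRUE)
}

# drop negligible cells (and any filter ringing within `border` cells of the
# domain edge) and renormalize so the cell total is preserved; keeps blob
# supports compact for fast weighted-sensor bookkeeping
truncate_blob <- function(p0, rel_tol = 1e-6, border = 0L) {
  m <- p0$p0
  s0 <- sum(m)
  m[abs(m) < rel_tol * max(abs(m))] <- 0
  if (border > 0) {
    n <- dim(m)
    b <- seq_len(min(border, n[1]))
    m[c(b, n[1] - b + 1L), ] <- 0
    b2 <- seq_len(min(border, n[2]))
    m[, c(b2, n[2] - b2 + 1L)] <- 0
  }
  if (s0 != 0 && sum(m) != 0) m <- m * (s0 / sum(m))
  initial_pressure(m, label = p0$label)
}
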