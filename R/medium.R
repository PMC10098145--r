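#' Acoustic medium map
#'
#' Per-cell sound speed (m/s) and mass density (kg/m^3) over a simulation grid.
#'
#' @param sound_speed numeric matrix of sound speeds, all > 0.
#' @param density numeric matrix of densities, same shape, all > 0.
#' @return an object of class `medium_map`.
#' @export
medium_map <- function(sound_speed, density) {
  if (!is.matrix(sound_speed) || !is.matrix(density))
    stopf("invalid-argument: sound_speed and density must be matrices")
  if (!all(dim(sound_speed) == dim(density)))
    stopf("invalid-argument: sound_speed and density shapes differ")
  if (length(sound_speed) == 0) stopf("invalid-argument: empty medium")
  if (any(!is.finite(sound_speed)) || any(sound_speed <= 0))
    stopf("invalid-argument: sound_speed values must be finite and > 0")
  if (any(!is.finite(density)) || any(density <= 0))
    stopf("invalid-argument: density values must be finite and > 0")
  structure(list(sound_speed = sound_speed, density = density), class = "medium_map")
}

#' Uniform medium over a grid
#'
#' @param grid a [sim_grid()].
#' @param c sound speed in m/s (default: water, 1500).
#' @param rho density in kg/m^3 (default 1000).
#' @return a [medium_map()].
#' @export
uniform_medium <- function(grid, c = 1500, rho = 1000) {
  check_number(c, "c", positive = TRUE)
  check_number(rho, "rho", positive = TRUE)
  medium_map(matrix(c, grid$shape[1], grid$shape[2]),
             matrix(rho, grid$shape[1], grid$shape[2]))
}

#' @export
print.medium_map <- function(x, ...) {
  cs <- sort(unique(as.vector(x$sound_speed)))
  cat(sprintf("<medium_map> %d x %d cells, %d distinct sound speeds (%s m/s)\n",
              nrow(x$sound_speed), ncol(x$sound_speed), length(cs),
              paste(utils::head(signif(cs, 4), 5), collapse = ", ")))
  invisible(x)
}

check_medium_grid <- function(medium, grid) {
  if (!all(dim(medium$sound_speed) == grid$shape))
    stopf("invalid-argument: medium shape (%s) does not match grid shape (%s)",
          paste(dim(medium$sound_speed), collapse = "x"),
          paste(grid$shape, collapse = "x"))
  invisible(TRUE)
}
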