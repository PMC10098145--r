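#' Spatiotemporal encoder parameters
#'
#' Geometry and material parameters of the passive acoustic encoder: a long
#' ultrasonic pipe (rectangular in this 2-D cross-section) standing on the top
#' face of a right-angle prism, surrounded by air, read out by a small
#' single-element transducer at the prism's lower corner. Two design rules are
#' enforced: the pipe must be longer than the prism edge (the early part of
#' the recorded signal is boundary-independent for the duration of a pipe
#' round trip, so a long pipe buys a long encoding window), and the pipe
#' aperture must be smaller than the prism edge (so waves entering the prism
#' can scramble before reaching the transducer).
#'
#' @param pipe_length pipe length in metres (must exceed `prism_edge`).
#' @param pipe_width pipe aperture width in metres (must be below `prism_edge`).
#' @param prism_edge right-angle edge length of the prism in metres.
#' @param c_encoder sound speed of the encoder material in m/s (fused silica,
#'   5900).
#' @param c_surround sound speed of the surrounding medium in m/s (air, 343).
#' @param rho_encoder,rho_surround densities in kg/m^3 (2200 / 1.2).
#' @param couple_layer_thickness thickness of the water-speed coupling-gel
#'   layer on the pipe's top face, metres (present identically in calibration
#'   and measurement).
#' @param couple_speed,couple_density coupling layer properties (1500, 1000).
#' @param transducer_size aperture length of the transducer along the prism
#'   face, metres.
#' @param transducer_site only `"prism_corner"` is supported.
#' @param roughness_amplitude RMS depth of the randomized groove/ridge profile
#'   ground into the prism's free edges, metres (0 = smooth, off-the-shelf
#'   prism).
#' @param roughness_feature_size correlation length of the roughness profile,
#'   metres; must be at least `nominal_wavelength` when roughness is on
#'   (features smaller than the acoustic wavelength do not reflect).
#' @param nominal_wavelength the shortest acoustic wavelength the source
#'   band-limiting admits, metres (default 0.4 mm).
#' @param seed integer seed for the roughness profile.
#' @return an object of class `encoder_params`.
#' @export
encoder_params <- function(pipe_length, pipe_width, prism_edge,
                           c_encoder = 5900, c_surround = 343,
                           rho_encoder = 2200, rho_surround = 1.2,
                           couple_layer_thickness = 0.2e-3,
                           couple_speed = 1500, couple_density = 1000,
                           transducer_size = 0.5e-3,
                           transducer_site = "prism_corner",
                           roughness_amplitude = 0,
                           roughness_feature_size = 0.8e-3,
                           nominal_wavelength = 0.4e-3,
                           seed = 1L) {
  check_number(pipe_length, "pipe_length", positive = TRUE)
  check_number(pipe_width, "pipe_width", positive = TRUE)
  check_number(prism_edge, "prism_edge", positive = TRUE)
  for (nm in c("c_encoder", "c_surround", "rho_encoder", "rho_surround",
               "couple_speed", "couple_density", "transducer_size"))
    check_number(get(nm), nm, positive = TRUE)
  check_number(couple_layer_thickness, "couple_layer_thickness", nonneg = TRUE)
  check_number(roughness_amplitude, "roughness_amplitude", nonneg = TRUE)
  check_number(roughness_feature_size, "roughness_feature_size", positive = TRUE)
  transducer_site <- match.arg(transducer_site, "prism_corner")
  if (pipe_length <= prism_edge)
    stopf("invalid-argument: design rule violated: the pipe (%g mm) must be longer than the prism edge (%g mm) so the boundary-independent round-trip window spans the prism scrambling time",
          pipe_length * 1e3, prism_edge * 1e3)
  if (pipe_width >= prism_edge)
    stopf("invalid-argument: design rule violated: the pipe aperture (%g mm) must be smaller than the prism edge (%g mm) so waves can scramble inside the prism",
          pipe_width * 1e3, prism_edge * 1e3)
  if (roughness_amplitude > 0 && roughness_feature_size < nominal_wavelength)
    stopf("invalid-argument: roughness_feature_size (%g mm) must be at least the nominal acoustic wavelength (%g mm) to reflect",
          roughness_feature_size * 1e3, nominal_wavelength * 1e3)
  structure(list(pipe_length = pipe_length, pipe_width = pipe_width,
                 prism_edge = prism_edge, c_encoder = c_encoder,
                 c_surround = c_surround, rho_encoder = rho_encoder,
                 rho_surround = rho_surround,
                 couple_layer_thickness = couple_layer_thickness,
                 couple_speed = couple_speed, couple_density = couple_density,
                 transducer_size = transducer_size,
                 transducer_site = transducer_site,
                 roughness_amplitude = roughness_amplitude,
                 roughness_feature_size = roughness_feature_size,
                 nominal_wavelength = nominal_wavelength,
                 seed = as.integer(seed)),
            class = "encoder_params")
}

#' Boundary-condition variant
#'
#' Acoustic properties of the layer sitting on top of the pipe (above the
#' coupling gel): the stand-in for "whatever object contacts the encoder".
#' Changing this layer between calibration and measurement emulates a changed
#' boundary condition. `coverage_mask = NULL` covers the whole pipe aperture;
#' a logical vector (one entry per FOV pixel) covers only the corresponding
#' pixel footprints, emulating an object of that shape.
#'
#' @param layer_speed sound speed of the layer, m/s (default 1600, rubber-like).
#' @param layer_density density, kg/m^3 (default 1100).
#' @param layer_thickness thickness in metres (>= one grid cell when applied),
#'   or `Inf` for a semi-infinite layer: the layer then extends through the
#'   top absorbing boundary, so energy transmitted into it never returns --
#'   the model of a bulk object that absorbs ultrasound (rubber attenuates
#'   strongly at these frequencies). This is the default: imaging targets in
#'   this setting are typically bulk black-rubber absorbers.
#' @param coverage_mask `NULL` (full coverage) or logical per-FOV-pixel mask.
#' @param label free-text label.
#' @return an object of class `boundary_variant`.
#' @export
boundary_variant <- function(layer_speed = 1600, layer_density = 1100,
                             layer_thickness = Inf, coverage_mask = NULL,
                             label = "rubber") {
  check_number_or_inf <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      stopf("invalid-argument: `%s` must be > 0 (or Inf)", nm)
  }
  check_number(layer_speed, "layer_speed", positive = TRUE)
  check_number(layer_density, "layer_density", positive = TRUE)
  check_number_or_inf(layer_thickness, "layer_thickness")
  if (!is.null(coverage_mask) && !is.logical(coverage_mask))
    stopf("invalid-argument: `coverage_mask` must be NULL or a logical vector")
  structure(list(layer_speed = layer_speed, layer_density = layer_density,
                 layer_thickness = layer_thickness,
                 coverage_mask = coverage_mask, label = as.character(label)[1]),
            class = "boundary_variant")
}

#' Field-of-view pixel grid on the pipe's top face
#'
#' In the 2-D (side-view) simulation mode the FOV is a line of pixels across
#' the pipe aperture; pixel positions are stored as offsets from the pipe
#' axis. Pixel index runs left to right (most negative offset first) and the
#' index-position mapping is a fixed bijection.
#'
#' @param params an [encoder_params()].
#' @param fov_extent extent of the calibrated line in metres (`0` gives a
#'   single pixel at the centre); must not exceed `pipe_width`.
#' @param pitch pixel spacing in metres.
#' @return an object of class `fov_grid` with fields `offsets`, `pitch`,
#'   `n_pixels`, `dims`, `index_order`.
#' @examples
#' p <- encoder_params(20e-3, 6e-3, 10e-3)
#' place_fov_pixels(p, 3.75e-3, 0.25e-3)$n_pixels  # 16
#' @export
place_fov_pixels <- function(params, fov_extent, pitch) {
  if (!inherits(params, "encoder_params")) stopf("invalid-argument: `params` must be encoder_params")
  check_number(fov_extent, "fov_extent", nonneg = TRUE)
  check_number(pitch, "pitch", positive = TRUE)
  if (fov_extent > params$pipe_width)
    stopf("invalid-argument: fov_extent (%g mm) exceeds the pipe aperture (%g mm)",
          fov_extent * 1e3, params$pipe_width * 1e3)
  n <- floor(fov_extent / pitch + 1e-9) + 1L
  offsets <- (seq_len(n) - (n + 1) / 2) * pitch
  structure(list(offsets = offsets, pitch = pitch, n_pixels = as.integer(n),
                 dims = as.integer(n), mode = "line",
                 index_order = "left-to-right across the pipe aperture"),
            class = "fov_grid")
}

#' Abstract rectangular FOV grid (matrix mode)
#'
#' A physics-free pixel grid used with synthetic operators from
#' [make_matrix_operator()] and 2-D phantoms; no encoder geometry attached.
#'
#' @param dims integer vector, pixels per axis (length 1 or 2).
#' @param pitch pixel spacing in metres (bookkeeping only).
#' @return an object of class `fov_grid`.
#' @export
fov_grid_abstract <- function(dims, pitch = 1e-4) {
  dims <- as.integer(dims)
  if (length(dims) < 1 || length(dims) > 2 || any(dims < 1))
    stopf("invalid-argument: `dims` must be one or two positive pixel counts")
  structure(list(offsets = NULL, pitch = pitch, n_pixels = as.integer(prod(dims)),
                 dims = dims, mode = if (length(dims) == 2) "grid" else "line",
                 index_order = "row-major from the lower-left corner"),
            class = "fov_grid")
}

#' @export
print.fov_grid <- function(x, ...) {
  cat(sprintf("<fov_grid> %s pixels (%s), pitch %.3g mm\n",
              paste(x$dims, collapse = " x "), x$mode, x$pitch * 1e3))
  invisible(x)
}

same_fov <- function(a, b) {
  identical(a$dims, b$dims) && isTRUE(all.equal(a$pitch, b$pitch)) &&
    isTRUE(all.equal(a$offsets, b$offsets))
}

# cells whose centres fall in [lo, hi); hi may be Inf (clamped to the grid)
cell_range <- function(lo, hi, n, dx) {
  i0 <- max(1L, as.integer(ceiling(lo / dx + 0.5 - 1e-9)))
  i1 <- as.integer(min(n, floor(hi / dx + 0.5 - 1e-9)))
  if (i1 < i0) integer(0) else i0:i1
}

#' Grid sized to hold an encoder
#'
#' Computes the domain extent needed for the encoder (prism + pipe + coupling
#' layer + a fixed 2 mm boundary-layer allowance so all variants share one
#' grid), with PML plus interior margins on every side, and builds the grid
#' via [build_grid()].
#'
#' @param params an [encoder_params()].
#' @param duration simulated duration in seconds.
#' @param dx cell edge in metres (default 0.1 mm).
#' @param cfl Courant number (default 0.3).
#' @param pml_cells absorbing-layer thickness (default 12).
#' @param margin_cells interior margin between the encoder (including
#'   roughness excursions) and the PML, default 8 cells (minimum 5).
#' @return a [sim_grid()].
#' @export
encoder_grid <- function(params, duration, dx = 1e-4, cfl = 0.3,
                         pml_cells = 12L, margin_cells = 8L) {
  if (!inherits(params, "encoder_params")) stopf("invalid-argument: `params` must be encoder_params")
  if (margin_cells < 5L) stopf("invalid-argument: margin_cells must be >= 5")
  extra <- ceiling(3 * params$roughness_amplitude / dx)
  pad <- (pml_cells + margin_cells + extra) * dx
  layer_allowance <- 2e-3
  ex <- params$prism_edge + 2 * pad
  ey <- params$prism_edge + params$pipe_length + params$couple_layer_thickness +
    layer_allowance + 2 * pad
  ex <- ceiling(ex / dx - 1e-9) * dx
  ey <- ceiling(ey / dx - 1e-9) * dx
  c_max <- max(params$c_encoder, params$c_surround, params$couple_speed)
  build_grid(c(ex, ey), dx = dx, duration = duration, cfl = cfl,
             c_max = c_max, pml_cells = pml_cells)
}

#' Build the encoder medium and landmarks
#'
#' Paints the pipe-on-prism encoder into a medium map over `grid`: encoder
#' cells get the encoder material, everything else the surround; a
#' water-speed coupling layer sits on the pipe's top face, and an optional
#' boundary-variant layer sits on top of that. If the parameters request
#' rough prism edges, [roughen_prism_edges()] is applied (seeded,
#' deterministic). Returns the medium plus landmarks: the transducer aperture
#' at the prism's lower corner and the FOV pixel coordinates on the top face.
#'
#' @param params an [encoder_params()].
#' @param grid a [sim_grid()] from [encoder_grid()] (or compatible).
#' @param variant a [boundary_variant()] or `NULL` (bare top face).
#' @param fov a [fov_grid()] from [place_fov_pixels()]; required when the
#'   variant carries a per-pixel coverage mask, and used to report absolute
#'   pixel coordinates.
#' @return a list of class `encoder_medium` with elements `medium`
#'   ([medium_map()]), `sensor` ([sensor_spec()]) and `geometry` (named list
#'   of landmark coordinates in metres).
#' @export
build_encoder_medium <- function(params, grid, variant = NULL, fov = NULL) {
  if (!inherits(params, "encoder_params")) stopf("invalid-argument: `params` must be encoder_params")
  if (!inherits(grid, "sim_grid")) stopf("invalid-argument: `grid` must be a sim_grid")
  if (!is.null(variant) && !inherits(variant, "boundary_variant"))
    stopf("invalid-argument: `variant` must be a boundary_variant or NULL")
  dx <- grid$dx; nx <- grid$shape[1]; ny <- grid$shape[2]
  a <- params$prism_edge
  extra <- 3 * params$roughness_amplitude
  need_pad <- (grid$pml_cells + 5L) * dx + extra
  tc <- params$couple_layer_thickness
  # centre the encoder stack in the grid so placement does not depend on the
  # roughness padding (rough and smooth variants share cell positions)
  stack <- a + params$pipe_length + tc + 2e-3
  x0 <- (nx * dx - a) / 2
  y0 <- round((ny * dx - stack) / 2 / dx) * dx
  yP <- y0 + a
  yTop <- yP + params$pipe_length
  lt <- if (is.null(variant)) 0 else variant$layer_thickness
  # a semi-infinite layer runs through the top absorbing boundary by design
  y_layer_top <- yTop + tc + (if (is.finite(lt)) lt + need_pad else 5 * dx)
  if (x0 < need_pad || y0 < need_pad || y_layer_top > ny * dx)
    stopf("invalid-argument: encoder does not fit inside the grid minus PML and margins; required extent >= %.1f x %.1f mm",
          (a + 2 * need_pad) * 1e3, (y_layer_top + 2 * need_pad) * 1e3)
  xc <- x0 + a / 2
  pipe_x <- c(xc - params$pipe_width / 2, xc + params$pipe_width / 2)

  cx <- axis_coords(nx, dx); cy <- axis_coords(ny, dx)
  X <- matrix(cx, nx, ny); Y <- matrix(cy, nx, ny, byrow = TRUE)
  prism <- X >= x0 & X <= x0 + a & Y <= yP & (Y - y0) >= (X - x0)
  pipe <- X >= pipe_x[1] & X <= pipe_x[2] & Y > yP & Y <= yTop
  solid <- prism | pipe

  cmat <- matrix(params$c_surround, nx, ny)
  rmat <- matrix(params$rho_surround, nx, ny)
  cmat[solid] <- params$c_encoder
  rmat[solid] <- params$rho_encoder
  med <- medium_map(cmat, rmat)

  geometry <- list(x0 = x0, y0 = y0, prism_edge = a, yP = yP, yTop = yTop,
                   pipe_x = pipe_x, pipe_center = xc, dx = dx,
                   couple_thickness = tc,
                   transducer_corner = c(x0, y0),
                   params = params)

  if (params$roughness_amplitude > 0)
    med <- roughen_prism_edges(med, params, geometry)

  # coupling layer on the pipe's top face
  if (tc > 0) {
    ic <- cell_range(pipe_x[1], pipe_x[2], nx, dx)
    jc <- cell_range(yTop, yTop + tc, ny, dx)
    med$sound_speed[ic, jc] <- params$couple_speed
    med$density[ic, jc] <- params$couple_density
  }

  # boundary-variant layer on top of the coupling layer
  if (!is.null(variant)) {
    jl <- cell_range(yTop + tc, yTop + tc + variant$layer_thickness, ny, dx)
    if (length(jl) < 1L)
      stopf("invalid-argument: variant layer_thickness (%g mm) is below one grid cell", variant$layer_thickness * 1e3)
    if (is.null(variant$coverage_mask)) {
      il <- cell_range(pipe_x[1], pipe_x[2], nx, dx)
      med$sound_speed[il, jl] <- variant$layer_speed
      med$density[il, jl] <- variant$layer_density
    } else {
      if (is.null(fov)) stopf("invalid-argument: a coverage-masked variant requires `fov`")
      if (length(variant$coverage_mask) != fov$n_pixels)
        stopf("invalid-argument: coverage_mask length (%d) != fov pixels (%d)",
              length(variant$coverage_mask), fov$n_pixels)
      for (i in which(variant$coverage_mask)) {
        xi <- xc + fov$offsets[i]
        il <- cell_range(xi - fov$pitch / 2, xi + fov$pitch / 2, nx, dx)
        med$sound_speed[il, jl] <- variant$layer_speed
        med$density[il, jl] <- variant$layer_density
      }
    }
  }

  # transducer aperture: cells along the prism's left face at the lower corner
  i_face <- cell_range(x0, x0 + dx, nx, dx)[1]
  ts <- max(params$transducer_size, dx)
  j_rng <- cell_range(y0, y0 + ts, ny, dx)
  cells <- cbind(i_face, j_rng)
  # keep only cells inside the prism (the corner is a 45-degree wedge)
  keep <- prism[cbind(cells[, 1], cells[, 2])]
  if (!any(keep)) { # degenerate: take the lowest interior cell on the face
    jj <- which(prism[i_face, ])[1]
    cells <- cbind(i_face, jj); keep <- TRUE
  }
  sensor <- sensor_spec(cells[keep, , drop = FALSE])
  geometry$fov_x <- if (!is.null(fov)) xc + fov$offsets else NULL
  geometry$variant_label <- if (is.null(variant)) "none" else variant$label

  structure(list(medium = med, sensor = sensor, geometry = geometry),
            class = "encoder_medium")
}

#' Roughen the prism's free edges
#'
#' Perturbs the prism boundary along its two free edges (the vertical face and
#' the hypotenuse; the top face mated to the pipe is untouched) by a seeded
#' random groove/ridge profile: Gaussian noise filtered to the requested
#' correlation length, scaled to the requested RMS depth, clamped at three
#' RMS, and quantized to grid cells. A region within `2 * transducer_size` of
#' the transducer corner is left smooth so the sensor mates flush. The same
#' seed always yields the same map.
#'
#' @param medium a [medium_map()] holding the smooth encoder.
#' @param params the [encoder_params()] (fields `roughness_amplitude`,
#'   `roughness_feature_size`, `seed`).
#' @param geometry the geometry landmarks from [build_encoder_medium()];
#'   taken from the medium construction context.
#' @return the perturbed [medium_map()].
#' @export
roughen_prism_edges <- function(medium, params, geometry) {
  amp <- params$roughness_amplitude
  if (amp == 0) return(medium)
  dx <- geometry$dx
  if (params$roughness_feature_size < 2 * dx)
    stopf("invalid-argument: roughness_feature_size (%g mm) must be at least 2*dx (%g mm)",
          params$roughness_feature_size * 1e3, 2 * dx * 1e3)
  nx <- nrow(medium$sound_speed); ny <- ncol(medium$sound_speed)
  x0 <- geometry$x0; y0 <- geometry$y0; a <- geometry$prism_edge; yP <- geometry$yP
  # keep the corner region smooth: the sensor must mate flush, and grooves
  # (up to 3*amplitude deep) must never sever the thin corner wedge
  excl <- max(2 * max(params$transducer_size, dx), 6 * amp)
  cs <- params$c_encoder; rs <- params$rho_encoder
  ca <- params$c_surround; ra <- params$rho_surround

  profile <- function(m) {
    z <- rnorm(m + 200)
    s <- params$roughness_feature_size / dx
    k <- seq(-ceiling(3 * s), ceiling(3 * s))
    w <- exp(-k^2 / (2 * s^2))
    h <- stats::filter(z, w / sum(w), sides = 2)
    h <- h[!is.na(h)][seq_len(m)]
    h <- h / max(sd(h), 1e-12) * amp
    pmin(pmax(h, -3 * amp), 3 * amp)
  }

  with_local_seed(params$seed, {
    # left vertical face, x = x0, y in [y0 + excl, yP)
    jj <- cell_range(y0 + excl, yP, ny, dx)
    i_face <- cell_range(x0, x0 + dx, nx, dx)[1]
    h <- profile(length(jj))
    for (q in seq_along(jj)) {
      k <- round(h[q] / dx)
      if (k > 0) { # ridge: extend solid outward (toward -x)
        ii <- max(1L, i_face - k):(i_face - 1L)
        medium$sound_speed[ii, jj[q]] <- cs; medium$density[ii, jj[q]] <- rs
      } else if (k < 0) { # groove: carve into the prism
        ii <- i_face:min(nx, i_face - k - 1L)
        medium$sound_speed[ii, jj[q]] <- ca; medium$density[ii, jj[q]] <- ra
      }
    }
    # hypotenuse, sampled by column, excluded near the corner
    ii <- cell_range(x0 + excl, x0 + a, nx, dx)
    h2 <- profile(length(ii))
    cyv <- axis_coords(ny, dx)
    for (q in seq_along(ii)) {
      xq <- (ii[q] - 0.5) * dx
      yh <- y0 + (xq - x0)          # smooth boundary height in this column
      v <- sqrt(2) * h2[q]          # vertical shift giving normal depth h2
      if (v > 0) { # ridge: extend solid downward below the hypotenuse
        jj2 <- cell_range(yh - v, yh, ny, dx)
        if (length(jj2)) { medium$sound_speed[ii[q], jj2] <- cs; medium$density[ii[q], jj2] <- rs }
      } else if (v < 0) { # groove: carve upward into the prism
        jj2 <- cell_range(yh, min(yh - v, yP), ny, dx)
        if (length(jj2)) { medium$sound_speed[ii[q], jj2] <- ca; medium$density[ii[q], jj2] <- ra }
      }
    }
  })
  medium
}

#' Derived timing quantities of an encoder
#'
#' One-way pipe transit `L/c`, round trip `2L/c`, and the boundary-safe window
#' end `3L/c` (see [boundary_safe_window()]), as a tibble.
#'
#' @param params an [encoder_params()] or preset name (see [encoder_preset()]).
#' @return a tibble with columns `quantity`, `value`, `unit`.
#' @examples
#' describe_encoder("fig3_2d")
#' @export
describe_encoder <- function(params) {
  if (is.character(params)) params <- encoder_preset(params)$params
  L <- params$pipe_length; c <- params$c_encoder
  tibble::tibble(
    quantity = c("pipe_transit", "pipe_round_trip", "safe_window_end",
                 "pipe_to_prism_ratio", "aperture_to_prism_ratio"),
    value = c(L / c * 1e6, 2 * L / c * 1e6, 3 * L / c * 1e6,
              L / params$prism_edge, params$pipe_width / params$prism_edge),
    unit = c("us", "us", "us", "", ""))
}

#' Encoder presets
#'
#' Two ready-made 2-D configurations:
#' \describe{
#'   \item{`fig3_2d`}{The side-view demonstration geometry: 60 mm x 10 mm
#'     fused-silica pipe (5900 m/s) on a 30 mm prism in air (343 m/s), 0.1 mm
#'     cells, smooth edges. Used to show wave propagation and first arrival.}
#'   \item{`demo_2d`}{A fast desk-scale geometry for tests and experiments:
#'     20 mm x 6 mm pipe on a 10 mm prism, rough prism edges, 16-pixel FOV at
#'     0.25 mm pitch.}
#' }
#'
#' @param name `"demo_2d"` or `"fig3_2d"`.
#' @return a list with the [encoder_params()], grid settings (`dx`, `cfl`,
#'   `pml_cells`, `duration`), FOV settings (`fov_extent`, `fov_pitch`),
#'   source settings (`source_width`, `cutoff_wavelength`) and the default
#'   calibration [boundary_variant()].
#' @export
encoder_preset <- function(name = c("demo_2d", "fig3_2d")) {
  name <- match.arg(name)
  if (name == "demo_2d") {
    params <- encoder_params(pipe_length = 20e-3, pipe_width = 6e-3,
                             prism_edge = 10e-3, transducer_size = 0.5e-3,
                             roughness_amplitude = 0.6e-3,
                             roughness_feature_size = 0.8e-3, seed = 42L)
    list(name = name, params = params, dx = 1e-4, cfl = 0.3, pml_cells = 12L,
         duration = 30e-6, fov_extent = 3.75e-3, fov_pitch = 0.25e-3,
         source_width = 0.25e-3, cutoff_wavelength = 0.4e-3,
         cal_variant = boundary_variant(label = "full-coverage rubber"))
  } else {
    params <- encoder_params(pipe_length = 60e-3, pipe_width = 10e-3,
                             prism_edge = 30e-3, transducer_size = 0.2e-3,
                             roughness_amplitude = 0, seed = 1L)
    list(name = name, params = params, dx = 1e-4, cfl = 0.3, pml_cells = 12L,
         duration = 36e-6, fov_extent = 6e-3, fov_pitch = 0.1e-3,
         source_width = 0.3e-3, cutoff_wavelength = 0.4e-3,
         cal_variant = boundary_variant(label = "full-coverage rubber"))
  }
}
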