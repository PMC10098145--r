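# grid construction, stability bounds, wave propagation physics

test_that("build_grid derives shape, dt and nt from physical settings", {
  g <- build_grid(c(10e-3, 90e-3), dx = 0.1e-3, duration = 20e-6, c_max = 5900)
  expect_identical(g$shape, c(100L, 900L))
  expect_equal(g$dt, 0.3 * 0.1e-3 / 5900, tolerance = 1e-12)  # ~5.0847e-9 s
  expect_identical(g$nt, as.integer(ceiling(20e-6 / g$dt)))
  expect_error(build_grid(c(10e-3, 10e-3), 0.1e-3, 0, c_max = 1500), "duration")
  expect_error(build_grid(c(-1e-3, 1e-3), 0.1e-3, 1e-6, c_max = 1500), "extent")
  expect_error(build_grid(c(1e-2, 1e-2), 0.1e-3, 1e-6, cfl = 1.5, c_max = 1500), "cfl")
})

test_that("stable_timestep returns cfl*dx/max(c)", {
  g <- sim_grid(c(20, 20), 0.1e-3, 1e-8, 10, pml_cells = 0)
  m <- uniform_medium(g, c = 1500)
  expect_equal(stable_timestep(m, 0.1e-3, 0.3), 2e-8, tolerance = 1e-14)
  m2 <- m; m2$sound_speed[5, 5] <- 5900
  expect_equal(stable_timestep(m2, 0.1e-3, 0.3), 0.3 * 0.1e-3 / 5900, tolerance = 1e-14)
  expect_error(stable_timestep(m, 0.1e-3, 0), "cfl")
})

test_that("first_arrival_time handles impulses, zeros and thresholds", {
  tr <- pressure_trace(c(1, rep(0, 9)), dt = 1e-8)
  expect_identical(first_arrival_time(tr, 0.05), 0)
  expect_identical(first_arrival_time(pressure_trace(rep(0, 10), dt = 1e-8)), Inf)
  tr2 <- pressure_trace(c(0, 0, 0.01, 0.5, 1), dt = 1e-8, t0 = 1e-7)
  expect_equal(first_arrival_time(tr2, 0.05), 1e-7 + 3e-8)
  expect_error(first_arrival_time(tr2, 1.2), "threshold_frac")
})

test_that("waves arrive at d/c in homogeneous media (5% threshold)", {
  g <- small_water_grid()
  med <- uniform_medium(g)
  src <- point_source(g, 30, 40, band_limit = 0.4e-3)
  # the band-limited source has finite support; its leading 5% contour, not
  # its centre, is what a 5% threshold detector first sees
  prof <- abs(src$p0[, 40])
  r05 <- (max(which(prof >= 0.05 * max(prof))) - 30) * g$dx
  tol <- 2 * g$dx / 1500
  sensors <- list(sensor_spec(cbind(80, 40)),    # d = 50 cells
                  sensor_spec(cbind(130, 40)),   # d = 100 cells
                  sensor_spec(cbind(180, 40)))   # d = 150 cells
  trs <- simulate_wave(g, med, src, sensors)
  for (q in seq_along(trs)) {
    d <- c(50, 100, 150)[q] * g$dx
    expect_lt(abs(first_arrival_time(trs[[q]], 0.05) - (d - r05) / 1500), tol)
  }
  # differential arrival between sensors removes the source-shape offset
  dt21 <- first_arrival_time(trs[[3]], 0.05) - first_arrival_time(trs[[1]], 0.05)
  expect_lt(abs(dt21 - 100 * g$dx / 1500), tol)
})

test_that("the solver is linear: superposition of sources", {
  g <- build_grid(c(10e-3, 8e-3), 0.1e-3, 6e-6, c_max = 1500, pml_cells = 10)
  med <- uniform_medium(g)
  sa <- point_source(g, 30, 30)
  sb <- point_source(g, 60, 50)
  sen <- sensor_spec(cbind(80, 40))
  ta <- simulate_wave(g, med, sa, sen)[[1]]$values
  tb <- simulate_wave(g, med, sb, sen)[[1]]$values
  joint <- initial_pressure(2.5 * sa$p0 + 0.7 * sb$p0)
  tj <- simulate_wave(g, med, joint, sen)[[1]]$values
  expect_lt(max(abs(tj - 2.5 * ta - 0.7 * tb)) / max(abs(tj)), 1e-6)
})

test_that("zero source yields identically zero traces", {
  g <- build_grid(c(6e-3, 6e-3), 0.1e-3, 3e-6, c_max = 1500, pml_cells = 8)
  med <- uniform_medium(g)
  tr <- simulate_wave(g, med, initial_pressure(matrix(0, 60, 60)),
                      sensor_spec(cbind(30, 30)))[[1]]
  expect_identical(max(abs(tr$values)), 0)
})

test_that("PML returns less than 1% of the incident amplitude", {
  g <- build_grid(c(30e-3, 10e-3), 0.1e-3, 26e-6, c_max = 1500, pml_cells = 12)
  med <- uniform_medium(g)
  src <- point_source(g, 50, 50, band_limit = 0.4e-3)
  tr <- simulate_wave(g, med, src, sensor_spec(cbind(50, 50)))[[1]]
  tt <- trace_times(tr) * 1e6
  incident <- max(abs(tr$values[tt < 4]))
  # all boundary returns (nearest edges 5 mm away) fall in this window
  returned <- max(abs(tr$values[tt > 8 & tt < 26]))
  expect_lt(returned / incident, 0.01)
})

test_that("source and receiver can be swapped in a heterogeneous medium", {
  g <- build_grid(c(12e-3, 10e-3), 0.1e-3, 8e-6, c_max = 2500, pml_cells = 10)
  cmat <- matrix(1500, g$shape[1], g$shape[2])
  rmat <- matrix(1000, g$shape[1], g$shape[2])
  cmat[, 45:65] <- 2500; rmat[, 45:65] <- 1800  # fast dense slab in between
  med <- medium_map(cmat, rmat)
  A <- c(30L, 30L); B <- c(90L, 85L)  # opposite sides of the slab, same material
  t_ab <- simulate_wave(g, med, point_source(g, A[1], A[2]),
                        sensor_spec(rbind(B)))[[1]]$values
  t_ba <- simulate_wave(g, med, point_source(g, B[1], B[2]),
                        sensor_spec(rbind(A)))[[1]]$values
  expect_lt(rel_l2(t_ab, t_ba), 1e-3)
})

test_that("an unstable time step is reported as a numerical failure", {
  g <- sim_grid(c(60, 60), 0.1e-3, 2e-7, 400, pml_cells = 8)  # far above the CFL bound
  med <- uniform_medium(g, c = 1500)
  expect_error(simulate_wave(g, med, point_source(g, 30, 30),
                             sensor_spec(cbind(40, 40))),
               "numerical-failure.*step")
})

test_that("band limiting conserves the source total and passes smooth fields", {
  g <- build_grid(c(12e-3, 12e-3), 0.1e-3, 1e-6, c_max = 1500, pml_cells = 8)
  # single-cell impulse: widened, total conserved
  imp <- point_source(g, 60, 60)
  bl <- band_limit_source(imp, g, 0.4e-3)
  expect_equal(sum(bl$p0), sum(imp$p0), tolerance = 1e-6)
  expect_gt(sum(bl$p0 > 0.01 * max(bl$p0)), 4)
  # smooth wide blob: essentially unchanged
  wide <- stencode:::gaussian_blob(g, c(6e-3, 6e-3), 2e-3)
  blw <- band_limit_source(wide, g, 0.4e-3)
  expect_lt(rel_l2(as.vector(blw$p0), as.vector(wide$p0)), 1e-3)
  expect_error(band_limit_source(imp, g, 0.1e-3), "Nyquist")
})

test_that("field snapshots are recorded on request", {
  g <- build_grid(c(6e-3, 6e-3), 0.1e-3, 2e-6, c_max = 1500, pml_cells = 8)
  med <- uniform_medium(g)
  tr <- simulate_wave(g, med, point_source(g, 30, 30),
                      sensor_spec(cbind(40, 40)), record_fields_every = 25L)
  f <- attr(tr, "fields")
  expect_false(is.null(f))
  expect_identical(f$steps[1:2], c(0L, 25L))
  expect_identical(dim(f$fields[[1]]), g$shape)
  # the first snapshot is the initial pressure itself
  expect_identical(f$fields[[1]][30, 30], 1)
})

test_that("sources and sensors must respect the absorbing boundary", {
  g <- build_grid(c(6e-3, 6e-3), 0.1e-3, 2e-6, c_max = 1500, pml_cells = 8)
  med <- uniform_medium(g)
  expect_error(simulate_wave(g, med, point_source(g, 3, 30),
                             sensor_spec(cbind(30, 30))),
               "non-PML interior")
  expect_error(simulate_wave(g, med, point_source(g, 30, 30),
                             sensor_spec(cbind(2, 2))),
               "inside the PML")
})
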