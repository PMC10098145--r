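# encoder construction, design rules, roughening, FOV placement

test_that("design rules reject bad pipe/prism proportions with the rule text", {
  expect_error(encoder_params(8e-3, 6e-3, 10e-3), "must be longer than the prism edge")
  expect_error(encoder_params(20e-3, 12e-3, 10e-3), "must be smaller than the prism edge")
  expect_error(encoder_params(20e-3, 6e-3, 10e-3, roughness_amplitude = 1e-3,
                              roughness_feature_size = 0.1e-3),
               "acoustic wavelength")
})

test_that("the stated geometry yields exactly two sound speeds when bare", {
  # pipe 6 cm on a 3 cm prism, fused silica in air, no coupling layer,
  # no roughness, no boundary layer
  p <- encoder_params(60e-3, 10e-3, 30e-3, couple_layer_thickness = 0,
                      transducer_size = 0.2e-3, roughness_amplitude = 0)
  g <- encoder_grid(p, duration = 2e-6)
  enc <- build_encoder_medium(p, g)
  cs <- sort(unique(as.vector(enc$medium$sound_speed)))
  expect_identical(cs, c(343, 5900))
  rs <- sort(unique(as.vector(enc$medium$density)))
  expect_identical(rs, c(1.2, 2200))
  # solid fraction sanity: prism area a^2/2 + pipe area L*w
  frac <- mean(enc$medium$sound_speed == 5900)
  expected <- (0.5 * 30e-3^2 + 60e-3 * 10e-3) /
    (prod(g$shape) * g$dx^2)
  expect_equal(frac, expected, tolerance = 0.02)
})

test_that("encoder construction is deterministic given the seed", {
  ps <- encoder_preset("demo_2d")
  g <- encoder_grid(ps$params, 1e-6)
  m1 <- build_encoder_medium(ps$params, g)$medium
  m2 <- build_encoder_medium(ps$params, g)$medium
  expect_identical(m1$sound_speed, m2$sound_speed)
  p2 <- ps$params; p2$seed <- 99L
  m3 <- build_encoder_medium(p2, g)$medium
  expect_false(identical(m1$sound_speed, m3$sound_speed))
})

test_that("a boundary variant changes only the layer band above the pipe top", {
  ps <- encoder_preset("demo_2d")
  g <- encoder_grid(ps$params, 1e-6)
  fov <- place_fov_pixels(ps$params, ps$fov_extent, ps$fov_pitch)
  bare <- build_encoder_medium(ps$params, g, NULL, fov)
  v <- boundary_variant(layer_thickness = 1e-3)
  cov <- build_encoder_medium(ps$params, g, v, fov)
  dmask <- bare$medium$sound_speed != cov$medium$sound_speed
  expect_gt(sum(dmask), 0)
  ys <- (which(dmask, arr.ind = TRUE)[, 2] - 0.5) * g$dx
  y_top <- bare$geometry$yTop + ps$params$couple_layer_thickness
  expect_true(all(ys >= y_top - g$dx & ys <= y_top + 1e-3 + g$dx))
})

test_that("rough and smooth encoders differ only near the free prism edges", {
  ps <- encoder_preset("demo_2d")
  g <- encoder_grid(ps$params, 1e-6)
  rough <- build_encoder_medium(ps$params, g)
  smooth_p <- ps$params; smooth_p$roughness_amplitude <- 0
  smooth <- build_encoder_medium(smooth_p, g)
  dmask <- which(rough$medium$sound_speed != smooth$medium$sound_speed, arr.ind = TRUE)
  expect_gt(nrow(dmask), 0)
  geo <- rough$geometry
  x <- (dmask[, 1] - 0.5) * g$dx; y <- (dmask[, 2] - 0.5) * g$dx
  d_face <- abs(x - geo$x0)
  d_hyp <- abs((y - geo$y0) - (x - geo$x0)) / sqrt(2)
  expect_true(all(pmin(d_face, d_hyp) <= 3 * ps$params$roughness_amplitude + 2 * g$dx))
  # no perturbation inside the pipe or above it
  expect_true(all(y <= geo$yP + g$dx))
})

test_that("roughness profile RMS matches the requested amplitude", {
  ps <- encoder_preset("demo_2d")
  p <- ps$params
  p$roughness_amplitude <- 0.5e-3; p$roughness_feature_size <- 0.8e-3
  g <- encoder_grid(p, 1e-6)
  enc <- build_encoder_medium(p, g)
  geo <- enc$geometry
  i_face <- stencode:::cell_range(geo$x0, geo$x0 + g$dx, g$shape[1], g$dx)[1]
  excl <- max(2 * p$transducer_size, 6 * p$roughness_amplitude)
  jj <- stencode:::cell_range(geo$y0 + excl, geo$yP, g$shape[2], g$dx)
  dev <- vapply(jj, function(j) {
    row <- enc$medium$sound_speed[, j] == p$c_encoder
    (i_face - which(row)[1]) * g$dx
  }, numeric(1))
  expect_lt(abs(sd(dev) - 0.5e-3), 0.3 * 0.5e-3)
  # amplitude zero leaves the medium untouched
  p0 <- p; p0$roughness_amplitude <- 0
  enc0 <- build_encoder_medium(p0, g)
  expect_identical(roughen_prism_edges(enc0$medium, p0, enc0$geometry),
                   enc0$medium)
})

test_that("FOV pixel placement counts and errors", {
  p <- encoder_params(20e-3, 6e-3, 10e-3)
  expect_identical(place_fov_pixels(p, 6e-3 - 2e-4, 0.1e-3)$n_pixels, 59L)
  f61 <- place_fov_pixels(encoder_params(70e-3, 7e-3, 30e-3), 6e-3, 0.1e-3)
  expect_identical(f61$n_pixels, 61L)  # 6 mm at 100 um pitch
  f16 <- place_fov_pixels(p, 3.75e-3, 0.25e-3)
  expect_identical(f16$n_pixels, 16L)
  expect_identical(place_fov_pixels(p, 0, 0.1e-3)$n_pixels, 1L)
  expect_equal(place_fov_pixels(p, 0, 0.1e-3)$offsets, 0)
  expect_error(place_fov_pixels(p, 12e-3, 0.1e-3), "exceeds the pipe aperture")
  # index <-> position mapping is a stable bijection
  expect_identical(f16$offsets, sort(f16$offsets))
  expect_identical(anyDuplicated(f16$offsets), 0L)
})

test_that("derived encoder timings include the round-trip window", {
  d <- describe_encoder("fig3_2d")
  expect_s3_class(d, "tbl_df")
  w_end <- d$value[d$quantity == "safe_window_end"]
  expect_equal(w_end, 3 * 60e-3 / 5900 * 1e6, tolerance = 1e-9)  # ~30.51 us
  expect_equal(d$value[d$quantity == "pipe_transit"], 60e-3 / 5900 * 1e6,
               tolerance = 1e-9)
})
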