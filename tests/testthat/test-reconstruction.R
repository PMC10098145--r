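# TwIST solver, TV operators, operator-norm estimation

test_that("operator norm estimate matches dense SVD", {
  fov4 <- fov_grid_abstract(4)
  expect_equal(estimate_operator_norm(diag(4)), 1, tolerance = 1e-8)
  D <- diag(c(3, 1)); D2 <- rbind(D, 0)
  expect_equal(estimate_operator_norm(D2), 3, tolerance = 0.01)
  expect_identical(estimate_operator_norm(matrix(0, 5, 3)), 0)
  set.seed(7)
  for (k in 1:5) {
    A <- matrix(rnorm(40 * 7), 40, 7)
    expect_equal(estimate_operator_norm(A, seed = k), max(svd(A)$d), tolerance = 0.01)
  }
})

test_that("TV seminorm: hand values, homogeneity, flat fields", {
  expect_identical(tv_seminorm(c(0, 1, 1, 0)), 2)
  expect_identical(tv_seminorm(rep(4.2, 9)), 0)
  expect_identical(tv_seminorm(matrix(1, 5, 5)), 0)
  # 2-D hand case: single bright pixel in the corner of a 2x2 image; the
  # only non-zero forward differences are gx = gy = -1 at that pixel
  m <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(tv_seminorm(m), sqrt(2))
  set.seed(1)
  v <- matrix(runif(36), 6, 6)
  expect_equal(tv_seminorm(3.5 * v), 3.5 * tv_seminorm(v))
})

test_that("TV denoise is a proximal map: identity cases and oracle objective", {
  set.seed(42)
  f <- matrix(rnorm(64), 8, 8)
  expect_identical(tv_denoise(f, 0), f)
  flat <- matrix(2, 8, 8)
  expect_equal(tv_denoise(flat, 0.7, 200), flat, tolerance = 1e-10)
  # oracle: long-run projected subgradient descent on 0.5||x-f||^2 + w TV(x)
  w <- 0.2
  obj <- function(x) 0.5 * sum((x - f)^2) + w * tv_seminorm(x)
  sub_tv <- function(x, eps = 1e-9) {
    gx <- rbind(diff(x), 0); gy <- cbind(t(diff(t(x))), 0)
    mag <- sqrt(gx^2 + gy^2 + eps)
    p <- list(x = gx / mag, y = gy / mag)
    -stencode:::tv_div(p)
  }
  x <- f
  best <- obj(x)
  for (k in 1:4000) {
    g <- (x - f) + w * sub_tv(x)
    x <- x - (0.5 / k^0.6) * g
    o <- obj(x)
    if (o < best) { best <- o; }
  }
  xd <- tv_denoise(f, w, 400)
  expect_lt(obj(xd), obj(f))             # strictly improves on the input
  expect_lt(abs(obj(xd) - best) / best, 0.01)  # within 1% of the oracle
})

test_that("twist with identity operator and lambda 0 returns the data", {
  fov <- fov_grid_abstract(6)
  K <- calibration_matrix(diag(6), fov, dt = 1e-8)
  s <- c(0.3, 1, 2, 0, 1.5, 0.2)
  fit <- twist_solve(K, s, recon_config(lambda_reg = 0))
  expect_equal(fit$estimate$values, s, tolerance = 1e-10)
})

test_that("twist with lambda 0 matches the normal-equations solution", {
  set.seed(11)
  # well-conditioned tall operator
  A <- matrix(rnorm(60 * 16), 60, 16) + 3 * diag(nrow = 60, ncol = 16)
  expect_lt(kappa(A, exact = TRUE), 10)
  fov <- fov_grid_abstract(16)
  K <- calibration_matrix(A, fov, dt = 1e-8)
  P_true <- runif(16)
  s <- as.numeric(A %*% P_true)
  fit <- twist_solve(K, s, recon_config(lambda_reg = 0, nonneg = FALSE,
                                        max_iter = 500, rel_tol = 1e-12))
  P_ls <- solve(crossprod(A), crossprod(A, s))
  expect_lt(rel_l2(fit$estimate$values, as.numeric(P_ls)), 1e-4)
  expect_gt(pearson_r(fit$estimate, image_estimate(P_true, fov)), 0.99)
})

test_that("monotone twist never increases the objective", {
  for (sd in 1:20) {
    set.seed(sd)
    A <- matrix(rnorm(40 * 12), 40, 12)
    fov <- fov_grid_abstract(12)
    K <- calibration_matrix(A, fov, dt = 1e-8)
    s <- as.numeric(A %*% pmax(rnorm(12), 0)) + 0.05 * rnorm(40)
    fit <- twist_solve(K, s, recon_config(max_iter = 60))
    expect_true(all(diff(fit$objective) <= 1e-9 * abs(fit$objective[1])))
    expect_lte(fit$objective[length(fit$objective)], fit$objective[1])
    expect_true(all(fit$estimate$values >= 0))
  }
})

test_that("large lambda drives the estimate to the best constant image", {
  set.seed(3)
  A <- matrix(rnorm(80 * 9), 80, 9)
  fov <- fov_grid_abstract(9)
  K <- calibration_matrix(A, fov, dt = 1e-8)
  s <- as.numeric(A %*% runif(9, 0.5, 1))
  lam <- 10 * max(abs(crossprod(A, s)))
  fit <- twist_solve(K, s, recon_config(lambda_reg = lam, nonneg = FALSE,
                                        max_iter = 5000, rel_tol = 1e-13,
                                        tv_inner_iters = 200))
  # restricted one-parameter oracle: best constant image
  ones <- rep(1, 9)
  c_star <- sum((A %*% ones) * s) / sum((A %*% ones)^2)
  expect_lt(max(abs(fit$estimate$values - mean(fit$estimate$values))),
            0.05 * abs(c_star))
  expect_equal(mean(fit$estimate$values), c_star, tolerance = 0.05)
})

test_that("objective value matches an explicit loop computation", {
  set.seed(5)
  A <- matrix(rnorm(30 * 8), 30, 8)
  fov <- fov_grid_abstract(8)
  K <- calibration_matrix(A, fov, dt = 1e-8)
  P <- runif(8); s <- rnorm(30); lam <- 0.3
  slow <- 0
  for (t in 1:30) {
    pred <- 0
    for (i in 1:8) pred <- pred + A[t, i] * P[i]
    slow <- slow + (s[t] - pred)^2
  }
  tv <- 0
  for (i in 1:7) tv <- tv + abs(P[i + 1] - P[i])
  slow <- slow + 2 * lam * tv
  expect_equal(objective_value(K, s, P, lam), slow, tolerance = 1e-12)
  expect_equal(objective_value(K, s, rep(0, 8), lam), sum(s^2), tolerance = 1e-12)
  expect_error(objective_value(K, s[1:10], P, lam), "dimension mismatch")
})

test_that("zero trace gives a zero image; doubling the trace doubles the image", {
  set.seed(9)
  A <- matrix(rnorm(50 * 10), 50, 10)
  fov <- fov_grid_abstract(10)
  K <- calibration_matrix(A, fov, dt = 1e-8)
  fit0 <- twist_solve(K, rep(0, 50), recon_config())
  expect_identical(fit0$estimate$values, rep(0, 10))
  s <- as.numeric(A %*% runif(10))
  f1 <- twist_solve(K, s, recon_config(lambda_reg = 0, max_iter = 300, rel_tol = 1e-12))
  f2 <- twist_solve(K, 2 * s, recon_config(lambda_reg = 0, max_iter = 300, rel_tol = 1e-12))
  expect_equal(f2$estimate$values, 2 * f1$estimate$values, tolerance = 1e-6)
})

test_that("windowing-state mismatch between K and s is rejected", {
  d <- list(dt = 1e-8)
  fov <- fov_grid_abstract(4)
  K <- calibration_matrix(matrix(rnorm(80), 20, 4), fov, dt = 1e-8)
  # same length, but the trace carries a window the matrix does not
  trw <- apply_window(pressure_trace(rnorm(80), dt = 1e-8),
                      time_window(0, 20e-8))
  expect_error(twist_solve(K, trw, recon_config()), "windowing states differ")
})

test_that("tidy and glance report the optimization path", {
  fov <- fov_grid_abstract(6)
  K <- calibration_matrix(diag(6), fov, dt = 1e-8)
  fit <- twist_solve(K, rnorm(6), recon_config(lambda_reg = 0))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "objective"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("iterations", "stop_reason", "lambda_reg") %in% names(gl)))
})
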