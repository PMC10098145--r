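#' Reconstruction configuration
#'
#' Settings for [twist_solve()]. The two-step weights `alpha`, `beta` default
#' to the standard two-step prescription for an operator scaled to unit
#' spectral norm with an assumed smallest squared singular value `xi1`:
#' `rho = (1 - sqrt(xi1)) / (1 + sqrt(xi1))`, `alpha = rho^2 + 1`,
#' `beta = 2 * alpha / (1 + xi1)`.
#'
#' @param lambda_reg regularization weight, or `"auto"` for
#'   `0.05 * max(abs(t(K) %*% s))`.
#' @param max_iter maximum iterations (default 200).
#' @param rel_tol stop when the relative objective change drops below this
#'   (default 1e-4).
#' @param alpha,beta two-step weights, or `"auto"`.
#' @param xi1 assumed lower edge of the scaled operator's squared spectrum
#'   (default 1e-4).
#' @param tv_inner_iters dual iterations inside each TV proximal step
#'   (default 10).
#' @param nonneg project each iterate onto non-negative images (default
#'   `TRUE`; absorber intensities are non-negative).
#' @param monotone enforce a non-increasing objective by falling back to a
#'   plain proximal-gradient step whenever the two-step update would increase
#'   it (default `TRUE`).
#' @param seed seed for the spectral-norm power iteration.
#' @return an object of class `recon_config`.
#' @export
recon_config <- function(lambda_reg = "auto", max_iter = 200L, rel_tol = 1e-4,
                         alpha = "auto", beta = "auto", xi1 = 1e-4,
                         tv_inner_iters = 10L, nonneg = TRUE, monotone = TRUE,
                         seed = 1L) {
  if (!identical(lambda_reg, "auto")) check_number(lambda_reg, "lambda_reg", nonneg = TRUE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stopf("invalid-argument: max_iter must be >= 1")
  check_number(rel_tol, "rel_tol", positive = TRUE)
  if (rel_tol >= 1) stopf("invalid-argument: rel_tol must be in (0, 1)")
  check_number(xi1, "xi1", positive = TRUE)
  structure(list(lambda_reg = lambda_reg, max_iter = max_iter, rel_tol = rel_tol,
                 alpha = alpha, beta = beta, xi1 = xi1,
                 tv_inner_iters = as.integer(tv_inner_iters),
                 nonneg = isTRUE(nonneg), monotone = isTRUE(monotone),
                 seed = as.integer(seed)),
            class = "recon_config")
}

#' Estimate the spectral norm of a calibration operator
#'
#' Power iteration on `t(K) %*% K`; used internally to scale the forward
#' operator to unit spectral norm before the two-step iteration. Returns 0
#' for an all-zero operator.
#'
#' @param K a [calibration_matrix()] or numeric matrix.
#' @param iters power iterations (default 60).
#' @param seed seed for the random start vector.
#' @return the largest singular value.
#' @export
estimate_operator_norm <- function(K, iters = 60L, seed = 1L) {
  A <- if (inherits(K, "calibration_matrix")) K$matrix else K
  if (!is.matrix(A) || length(A) == 0) stopf("invalid-argument: `K` must be a non-empty matrix")
  if (all(A == 0)) return(0)
  v <- with_local_seed(seed, rnorm(ncol(A)))
  v <- v / sqrt(sum(v^2))
  sig <- 0
  for (k in seq_len(iters)) {
    w <- crossprod(A, A %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- as.numeric(w / nw)
    sig <- sqrt(nw)
  }
  sig
}

#' Reconstruction objective
#'
#' The penalized least-squares objective minimized by [twist_solve()]:
#' `||s - K P||^2 + 2 * lambda * TV(P)`, with the squared L2 norm summed
#' over time samples and `TV` the isotropic total variation of the image.
#'
#' @param K a [calibration_matrix()] or matrix.
#' @param s a [widefield_measurement()], [pressure_trace()] or numeric vector.
#' @param P an [image_estimate()] or numeric vector.
#' @param lambda_reg the regularization weight.
#' @return a scalar.
#' @export
objective_value <- function(K, s, P, lambda_reg) {
  A <- if (inherits(K, "calibration_matrix")) K$matrix else K
  sv <- measurement_values(s)
  pv <- phantom_values(P)
  if (length(sv) != nrow(A) || length(pv) != ncol(A))
    stopf("invalid-argument: dimension mismatch (trace %d vs %d rows; image %d vs %d cols)",
          length(sv), nrow(A), length(pv), ncol(A))
  r <- sv - as.numeric(A %*% pv)
  Pimg <- if (inherits(P, "image_estimate")) P
  else if (inherits(K, "calibration_matrix")) image_estimate(pv, K$fov) else pv
  sum(r^2) + 2 * lambda_reg * tv_seminorm(Pimg)
}

measurement_values <- function(s) {
  if (inherits(s, "widefield_measurement")) s$trace$values
  else if (inherits(s, "pressure_trace")) s$values
  else if (is.numeric(s)) as.numeric(s)
  else stopf("invalid-argument: expected a measurement, trace, or numeric vector")
}

#' Two-step iterative shrinkage/thresholding (TwIST) with TV regularization
#'
#' Solves `argmin_P ||s - K P||^2 + 2*lambda*TV(P)` by the two-step iteration:
#' each step applies the TV proximal operator to a gradient step on the data
#' term (computed with `K` scaled to unit spectral norm), and combines the
#' result with the two previous iterates using weights `alpha`, `beta`.
#' Initialization is the deterministic back-projection `t(K) %*% s`. In
#' monotone mode an iteration that would increase the objective is replaced
#' by a plain proximal-gradient step, so the recorded objective sequence is
#' non-increasing.
#'
#' @param K a [calibration_matrix()]; must share `dt`, `t0` and windowing
#'   state with `s` when `s` carries a time axis.
#' @param s a [widefield_measurement()], [pressure_trace()], or plain numeric
#'   vector of length `nrow(K$matrix)`.
#' @param cfg a [recon_config()].
#' @return an object of class `twist_fit`: fields `estimate`
#'   ([image_estimate()]), `objective` (per-iteration values), `iterations`,
#'   `stop_reason`, `lambda_reg`, `operator_norm`, `config`.
#' @seealso [reconstruct()] for the full pipeline including energy
#'   normalization and windowing.
#' @export
twist_solve <- function(K, s, cfg = recon_config()) {
  if (!inherits(K, "calibration_matrix")) stopf("invalid-argument: `K` must be a calibration_matrix")
  if (!inherits(cfg, "recon_config")) stopf("invalid-argument: `cfg` must be a recon_config")
  sv <- measurement_values(s)
  if (length(sv) != nrow(K$matrix))
    stopf("invalid-argument: trace has %d samples but K has %d rows", length(sv), nrow(K$matrix))
  if (inherits(s, c("widefield_measurement", "pressure_trace"))) {
    ws <- window_state(s); wk <- window_state(K)
    if (!identical(ws, wk))
      stopf("invalid-argument: windowing states differ: measurement %s vs calibration %s", ws, wk)
    sdt <- if (inherits(s, "widefield_measurement")) s$trace$dt else s$dt
    if (abs(sdt - K$dt) > 1e-15)
      stopf("invalid-argument: sampling intervals differ (%g vs %g)", sdt, K$dt)
  }
  A <- K$matrix
  lam <- if (identical(cfg$lambda_reg, "auto")) 0.05 * max(abs(crossprod(A, sv))) else cfg$lambda_reg
  nrm <- estimate_operator_norm(A, seed = cfg$seed)
  dims <- K$fov$dims
  shape_img <- function(x) if (length(dims) == 2) matrix(x, dims[1], dims[2]) else x
  obj <- function(x) {
    r <- sv - as.numeric(A %*% as.numeric(x))
    sum(r^2) + 2 * lam * tv_seminorm(shape_img(as.numeric(x)))
  }
  if (nrm == 0) {
    est <- image_estimate(numeric(ncol(A)), K$fov)
    return(structure(list(estimate = est, objective = obj(est$values), iterations = 0L,
                          stop_reason = "zero-operator", lambda_reg = lam,
                          operator_norm = 0, config = cfg), class = "twist_fit"))
  }
  Ah <- A / nrm; sh <- sv / nrm; lamh <- lam / nrm^2
  Ats <- as.numeric(crossprod(Ah, sh))
  gamma <- function(x) {
    z <- x + as.numeric(crossprod(Ah, sh - as.numeric(Ah %*% x)))
    z <- as.numeric(tv_denoise(shape_img(z), lamh, cfg$tv_inner_iters))
    if (cfg$nonneg) z <- pmax(z, 0)
    z
  }
  xi1 <- cfg$xi1
  rho <- (1 - sqrt(xi1)) / (1 + sqrt(xi1))
  alpha <- if (identical(cfg$alpha, "auto")) rho^2 + 1 else cfg$alpha
  beta <- if (identical(cfg$beta, "auto")) 2 * alpha / (1 + xi1) else cfg$beta

  x_prev <- Ats
  if (cfg$nonneg) x_prev <- pmax(x_prev, 0)
  objs <- obj(x_prev)
  x <- gamma(x_prev)
  objs <- c(objs, obj(x))
  if (cfg$monotone && objs[2] > objs[1]) { x <- x_prev; objs[2] <- objs[1] }
  stop_reason <- "max_iter"
  it <- 1L
  for (t in 2:cfg$max_iter) {
    it <- t
    xg <- gamma(x)
    xn <- (1 - alpha) * x_prev + (alpha - beta) * x + beta * xg
    on <- obj(xn)
    if (cfg$monotone && on > objs[length(objs)]) {
      xn <- xg
      on <- obj(xn)
      if (on > objs[length(objs)]) { # prox too loose to improve; stop
        objs <- c(objs, objs[length(objs)])
        stop_reason <- "stalled"
        break
      }
    }
    if (!cfg$monotone && on > 10 * objs[1] + 1e-300)
      stopf("numerical-failure: objective diverged (%.3g -> %.3g) at iteration %d", objs[1], on, t)
    x_prev <- x; x <- xn
    objs <- c(objs, on)
    prev <- objs[length(objs) - 1]
    if (prev > 0 && abs(prev - on) / prev < cfg$rel_tol) { stop_reason <- "converged"; break }
    if (prev == 0 && on == 0) { stop_reason <- "converged"; break }
  }
  structure(list(estimate = image_estimate(x, K$fov), objective = objs,
                 iterations = it, stop_reason = stop_reason, lambda_reg = lam,
                 operator_norm = nrm, config = cfg),
            class = "twist_fit")
}

#' @export
print.twist_fit <- function(x, ...) {
  cat(sprintf("<twist_fit> %d iterations (%s), lambda = %.4g, objective %.6g -> %.6g\n",
              x$iterations, x$stop_reason, x$lambda_reg,
              x$objective[1], x$objective[length(x$objective)]))
  invisible(x)
}

#' @rdname twist_solve
#' @param x a `twist_fit`.
#' @param ... unused.
#' @export
tidy.twist_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective) - 1L, objective = x$objective)
}

#' @rdname twist_solve
#' @export
glance.twist_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, stop_reason = x$stop_reason,
                 lambda_reg = x$lambda_reg, operator_norm = x$operator_norm,
                 objective = x$objective[length(x$objective)])
}

#' End-to-end image reconstruction
#'
#' The full pipeline: pulse-energy normalization, time windowing, and the
#' two-step TV solver. `window = "auto"` applies the boundary-safe window
#' derived from the calibration's encoder parameters (or re-uses the window
#' already on `K`); `window = "none"` reconstructs from the full-length trace,
#' emulating ergodic-relay reconstruction without the boundary-independence
#' window (useful for comparisons; it fails when the boundary changed between
#' calibration and measurement). Matrix-mode operators carry no encoder
#' geometry and are used unwindowed.
#'
#' @param K a [calibration_matrix()].
#' @param s a [widefield_measurement()].
#' @param cfg a [recon_config()].
#' @param window `"auto"`, `"none"`, or an explicit [time_window()].
#' @return a `twist_fit` (see [twist_solve()]); the image is in
#'   `fit$estimate`.
#' @export
reconstruct <- function(K, s, cfg = recon_config(), window = "auto") {
  if (!inherits(s, "widefield_measurement")) stopf("invalid-argument: `s` must be a widefield_measurement")
  s <- energy_normalize(s)
  if (inherits(window, "time_window")) {
    if (is.null(K$window)) K <- apply_window(K, window)
    s <- apply_window(s, window)
  } else if (identical(window, "auto")) {
    w <- K$window
    if (is.null(w) && !is.null(K$meta$params)) w <- boundary_safe_window(K$meta$params)
    if (!is.null(w)) {
      if (is.null(K$window)) K <- apply_window(K, w)
      s <- apply_window(s, w)
    }
  } else if (!identical(window, "none")) {
    stopf("invalid-argument: `window` must be \"auto\", \"none\", or a time_window")
  }
  twist_solve(K, s, cfg)
}
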