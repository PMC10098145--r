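# internal helpers: argument checking, seeding, small numerics

stopf <- function(fmt, ..., class = "stencode_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("invalid-argument: `%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("invalid-argument: `%s` must be > 0", name)
  if (nonneg && x < 0) stopf("invalid-argument: `%s` must be >= 0", name)
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library randomness never leaks.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(code)
}

#' Relative L2 distance between two numeric vectors
#'
#' `||a - b|| / ||b||`, the yardstick used throughout the package for trace and
#' image comparisons. Returns `0` when both inputs are identically zero.
#'
#' @param a,b numeric vectors of equal length.
#' @return a single non-negative number.
#' @export
rel_l2 <- function(a, b) {
  if (length(a) != length(b)) stopf("invalid-argument: lengths differ (%d vs %d)", length(a), length(b))
  nb <- sqrt(sum(b^2))
  na_ <- sqrt(sum((a - b)^2))
  if (nb == 0) return(if (na_ == 0) 0 else Inf)
  na_ / nb
}
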