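# ggplot2 visualization methods

#' @rdname pressure_trace
#' @param object a [pressure_trace()].
#' @param ... unused.
#' @export
autoplot.pressure_trace <- function(object, ...) {
  df <- tibble::tibble(time_us = trace_times(object) * 1e6,
                       pressure = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_us, y = .data$pressure)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (µs)", y = "pressure (a.u.)")
}

#' @rdname image_estimate
#' @param object an [image_estimate()].
#' @param ... unused.
#' @export
autoplot.image_estimate <- function(object, ...) {
  d <- object$fov$dims
  if (length(d) == 2) {
    df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
    df$value <- object$values
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
  } else {
    df <- tibble::tibble(pixel = seq_along(object$values), value = object$values)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pixel, y = .data$value)) +
      ggplot2::geom_col(width = 0.8) +
      ggplot2::labs(x = "FOV pixel", y = "intensity (a.u.)")
  }
}

#' @rdname twist_solve
#' @param object a `twist_fit`.
#' @export
autoplot.twist_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective")
}

#' @rdname medium_map
#' @param object a [medium_map()].
#' @param ... unused.
#' @export
autoplot.medium_map <- function(object, ...) {
  d <- dim(object$sound_speed)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$sound_speed <- as.vector(object$sound_speed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$sound_speed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "cell (x)", y = "cell (y)", fill = "c (m/s)")
}

#' @importFrom ggplot2 .data
NULL
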