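# persistence: a versioned single-file container plus plain-text export

CONTAINER_VERSION <- 1L

required_fields <- function(cls) {
  switch(cls,
         calibration_matrix = c("matrix", "fov", "dt", "t0", "norm_factors"),
         widefield_measurement = c("trace", "pulse_energy", "variant_label"),
         pressure_trace = c("values", "dt", "t0"),
         image_estimate = c("values", "fov"),
         character(0))
}

#' Save / load result containers
#'
#' Persists calibration matrices, traces, measurements, images, windows and
#' configuration lists to a single versioned container file and restores
#' them bit-exactly. Loading checks the container's format version and the
#' presence of every required field of the stored class, raising a named
#' error when a field is absent or the version is unsupported.
#'
#' @param object the object to save.
#' @param path file path.
#' @return `load_container()` returns the restored object;
#'   `save_container()` returns `path` invisibly.
#' @export
save_container <- function(object, path) {
  wrapper <- list(format = "stencode-container", version = CONTAINER_VERSION,
                  class = class(object)[1], payload = object)
  saveRDS(wrapper, path, version = 3)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) {
  if (!file.exists(path)) stopf("invalid-argument: no such container: %s", path)
  wrapper <- readRDS(path)
  if (!is.list(wrapper) || !identical(wrapper$format, "stencode-container"))
    stopf("invalid-argument: %s is not a result container", path)
  if (!identical(wrapper$version, CONTAINER_VERSION))
    stopf("version-mismatch: container version %s is not supported (expected %d); re-export it with this release",
          format(wrapper$version), CONTAINER_VERSION)
  obj <- wrapper$payload
  need <- required_fields(wrapper$class)
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stopf("missing-dataset: container lacks field(s) %s for class %s",
          paste(sprintf("'%s'", missing), collapse = ", "), wrapper$class)
  obj
}

#' Plain-text matrix export
#'
#' Writes a calibration matrix (or any numeric matrix) as tab-separated text
#' with a commented header carrying the time axis, for inspection and
#' cross-checking against the binary container; `read_matrix_txt()` reads it
#' back.
#'
#' @param K a [calibration_matrix()] or numeric matrix.
#' @param path file path.
#' @param digits significant digits (default 17, round-trip exact).
#' @return the path, invisibly; `read_matrix_txt()` returns a numeric matrix
#'   with attributes `dt` and `t0` when present in the header.
#' @export
write_matrix_txt <- function(K, path, digits = 17) {
  A <- if (inherits(K, "calibration_matrix")) K$matrix else K
  hdr <- c("# stencode matrix export",
           sprintf("# ncol %d nrow %d", ncol(A), nrow(A)))
  if (inherits(K, "calibration_matrix"))
    hdr <- c(hdr, sprintf("# dt %.17g t0 %.17g", K$dt, K$t0))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(A, digits = digits, scientific = TRUE, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  if (!file.exists(path)) stopf("invalid-argument: no such file: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  A <- as.matrix(utils::read.table(text = body, sep = "\t"))
  dimnames(A) <- NULL
  tline <- grep("^# dt ", hdr, value = TRUE)
  if (length(tline)) {
    parts <- strsplit(tline[1], " ")[[1]]
    attr(A, "dt") <- as.numeric(parts[3]); attr(A, "t0") <- as.numeric(parts[5])
  }
  A
}

# ---- configuration -----------------------------------------------------

UNIT_FACTORS <- c("m" = 1, "mm" = 1e-3, "um" = 1e-6, "cm" = 1e-2,
                  "s" = 1, "ms" = 1e-3, "us" = 1e-6, "ns" = 1e-9,
                  "m/s" = 1, "mm/us" = 1e3, "km/s" = 1e3,
                  "kg/m3" = 1, "g/cm3" = 1e3)

#' Parse a physical quantity with unit suffix
#'
#' Converts strings like `"60 mm"`, `"5900 m/s"` or `"0.3 us"` to SI units;
#' bare numbers pass through unchanged.
#'
#' @param x a string (or number).
#' @return a number in SI units.
#' @examples
#' parse_quantity("60 mm")    # 0.06
#' parse_quantity("5900 m/s") # 5900
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*([A-Za-z/0-9]*)$", x))[[1]]
  if (length(m) != 3 || m[2] == "")
    stopf("invalid-argument: cannot parse quantity '%s'", x)
  val <- as.numeric(m[2])
  if (is.na(val)) stopf("invalid-argument: cannot parse number in '%s'", x)
  if (m[3] == "") return(val)
  if (!m[3] %in% names(UNIT_FACTORS))
    stopf("invalid-argument: unknown unit '%s' in '%s'", m[3], x)
  val * UNIT_FACTORS[[m[3]]]
}

CONFIG_KEYS <- list(
  top = c("preset", "geometry", "fov", "recon", "seeds", "output_dir"),
  geometry = c("pipe_length", "pipe_width", "prism_edge", "c_encoder",
               "c_surround", "couple_layer_thickness", "transducer_size",
               "roughness_amplitude", "roughness_feature_size"),
  fov = c("extent", "pitch"),
  recon = c("lambda_reg", "max_iter", "rel_tol", "tv_inner_iters",
            "nonneg", "monotone"),
  seeds = c("encoder", "noise", "recon"))

#' Load a run configuration
#'
#' Reads a YAML run configuration (preset name plus optional geometry / fov /
#' recon overrides with unit-suffixed quantities), rejects unknown keys, and
#' resolves it against the preset defaults. The resolved configuration is
#' returned as a list ready for the pipeline functions and can be persisted
#' next to outputs with [save_resolved_config()].
#'
#' @param path path to a YAML file.
#' @return a named list: `preset` (resolved preset list with overrides
#'   applied), `recon` ([recon_config()]), `seeds`, `output_dir`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stopf("invalid-argument: unknown key(s) %s in %s",
            paste(sprintf("'%s'", bad), collapse = ", "), where)
  }
  check_keys(raw, CONFIG_KEYS$top, "config")
  preset_name <- raw$preset %||% "demo_2d"
  ps <- encoder_preset(preset_name)
  if (!is.null(raw$geometry)) {
    check_keys(raw$geometry, CONFIG_KEYS$geometry, "geometry")
    geo <- lapply(raw$geometry, parse_quantity)
    pl <- as.list(ps$params)[setdiff(names(as.list(ps$params)), "transducer_site")]
    pl[names(geo)] <- geo
    ps$params <- do.call(encoder_params, pl)
  }
  if (!is.null(raw$fov)) {
    check_keys(raw$fov, CONFIG_KEYS$fov, "fov")
    if (!is.null(raw$fov$extent)) ps$fov_extent <- parse_quantity(raw$fov$extent)
    if (!is.null(raw$fov$pitch)) ps$fov_pitch <- parse_quantity(raw$fov$pitch)
  }
  rc <- raw$recon %||% list()
  check_keys(rc, CONFIG_KEYS$recon, "recon")
  cfg <- do.call(recon_config, rc)
  seeds <- raw$seeds %||% list()
  check_keys(seeds, CONFIG_KEYS$seeds, "seeds")
  list(preset = ps, recon = cfg, seeds = seeds,
       output_dir = raw$output_dir %||% ".")
}

#' @rdname load_run_config
#' @param config a resolved configuration from [load_run_config()].
#' @param path destination YAML path.
#' @export
save_resolved_config <- function(config, path) {
  p <- config$preset$params
  out <- list(
    preset = config$preset$name,
    geometry = list(pipe_length = sprintf("%g mm", p$pipe_length * 1e3),
                    pipe_width = sprintf("%g mm", p$pipe_width * 1e3),
                    prism_edge = sprintf("%g mm", p$prism_edge * 1e3),
                    c_encoder = sprintf("%g m/s", p$c_encoder),
                    c_surround = sprintf("%g m/s", p$c_surround),
                    couple_layer_thickness = sprintf("%g mm", p$couple_layer_thickness * 1e3),
                    transducer_size = sprintf("%g mm", p$transducer_size * 1e3),
                    roughness_amplitude = sprintf("%g mm", p$roughness_amplitude * 1e3),
                    roughness_feature_size = sprintf("%g mm", p$roughness_feature_size * 1e3)),
    fov = list(extent = sprintf("%g mm", config$preset$fov_extent * 1e3),
               pitch = sprintf("%g mm", config$preset$fov_pitch * 1e3)),
    recon = list(lambda_reg = if (identical(config$recon$lambda_reg, "auto")) "auto" else config$recon$lambda_reg,
                 max_iter = config$recon$max_iter, rel_tol = config$recon$rel_tol,
                 tv_inner_iters = config$recon$tv_inner_iters,
                 nonneg = config$recon$nonneg, monotone = config$recon$monotone),
    seeds = config$seeds, output_dir = config$output_dir)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
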