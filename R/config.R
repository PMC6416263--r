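.configSchema <- function() {
  list(
    d_start = 11, d_stop = 92, d_step = 3,
    degree_l = 10, order_m = 5, amplitude_a = 10,
    base_mm = 50, n_theta = 90, n_phi = 180,
    spacings = "0.68x0.68x2,0.68x0.68x0.6",
    methods = "M1,M2,M3",
    isovalue = 0.9, target_edge = 2,
    smooth_quantity = 5, smooth_iterations = 1,
    resample_grid = "1x1x1",
    volume_fractions = "0.25,0.5,0.75,1,1.25,1.5",
    volume_models = "11,47,92",
    out_dir = "spiculo_report",
    log_level = "INFO"
  )
}

#' Default run configuration
#'
#' All defaults are the study conditions of the phantom experiments:
#' harmonic degree 10, order 5, amplitude 10, the spiculatedness sweep 11
#' to 92 in steps of 3 (28 models), a 50 mm base, 0.68 mm in-plane pixel
#' size with 2 mm and 0.6 mm slice thicknesses, isovalue 0.9, remeshing
#' edge length 2, smoothing quantity 5, a 1 mm isotropic resampling grid,
#' and volume fractions 25-150%.
#'
#' @return a named list of configuration values (class `spiculoConfig`).
#' @export
defaultConfig <- function() {
  cfg <- .configSchema()
  class(cfg) <- "spiculoConfig"
  cfg
}

.validateConfig <- function(cfg) {
  schema <- .configSchema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop(
      "unknown configuration key(s): ", paste(unknown, collapse = ", "),
      "; valid keys are: ", paste(names(schema), collapse = ", ")
    )
  }
  num <- function(k) as.numeric(cfg[[k]])
  if (num("isovalue") <= 0 || num("isovalue") >= 1) {
    stop("isovalue must lie strictly between 0 and 1")
  }
  if (num("d_step") <= 0) stop("d_step must be positive")
  if (num("d_stop") < num("d_start")) stop("empty sweep: d_stop < d_start")
  if (num("amplitude_a") > 0 && num("d_start") <= num("amplitude_a")) {
    stop("d_start must exceed amplitude_a")
  }
  if (num("n_theta") < 32 || num("n_phi") < 64) {
    stop("resolution floor: n_theta >= 32 and n_phi >= 64")
  }
  if (num("base_mm") <= 0) stop("base_mm must be positive")
  if (num("target_edge") <= 0) stop("target_edge must be positive")
  if (num("smooth_quantity") < 0) stop("smooth_quantity must be >= 0")
  if (num("order_m") < 0 || num("order_m") > num("degree_l")) {
    stop("need 0 <= order_m <= degree_l")
  }
  methods <- configMethods(cfg)
  if (!all(methods %in% c("M1", "M2", "M3", "M4"))) {
    stop("methods must be a comma-separated subset of M1,M2,M3,M4")
  }
  if (!cfg$log_level %in% c("DEBUG", "INFO", "WARNING", "ERROR")) {
    stop("log_level must be one of DEBUG, INFO, WARNING, ERROR")
  }
  for (sp in configSpacings(cfg)) {
    if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0)) {
      stop("each spacing must be three positive numbers, e.g. 0.68x0.68x2")
    }
  }
  invisible(cfg)
}

#' Parse the spacing list of a configuration
#' @param cfg a `spiculoConfig`.
#' @return list of numeric length-3 spacings (mm).
#' @export
configSpacings <- function(cfg) {
  lapply(strsplit(cfg$spacings, ",")[[1L]], function(s) {
    as.numeric(strsplit(s, "x")[[1L]])
  })
}

#' Parse the meshing-method list of a configuration
#' @param cfg a `spiculoConfig`.
#' @return character vector of method names.
#' @export
configMethods <- function(cfg) trimws(strsplit(cfg$methods, ",")[[1L]])

.formatConfigValue <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
}

#' Load a run configuration from a flat key = value file
#'
#' Missing keys take their defaults (the study conditions); unknown keys
#' raise an error listing the valid keys; out-of-range values raise
#' validation errors.  An empty file therefore yields the full default
#' configuration.
#'
#' @param path configuration file; lines of the form `key = value`, blank
#'   lines and `#` comments ignored.
#' @return a validated `spiculoConfig` list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- defaultConfig()
  schema <- .configSchema()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed configuration line (expected key = value): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(schema)) {
      stop(
        "unknown configuration key: ", key, "; valid keys are: ",
        paste(names(schema), collapse = ", ")
      )
    }
    cfg[[key]] <- if (is.numeric(schema[[key]])) as.numeric(val) else val
  }
  .validateConfig(cfg)
  cfg
}

#' Save a configuration as a flat key = value file
#'
#' Numeric values are written at full double precision so that saving and
#' re-loading reproduces the configuration exactly.
#'
#' @param cfg a `spiculoConfig`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
saveConfig <- function(cfg, path) {
  .validateConfig(cfg)
  lines <- vapply(names(.configSchema()), function(k) {
    paste0(k, " = ", .formatConfigValue(cfg[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
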