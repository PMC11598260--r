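#' Default run configuration
#'
#' The shipped defaults are the reference design of the depth-sensing
#' channel: b = 10 mm / a = 8 mm diaphragm, 10 mm objective and 200 mm
#' imaging focal lengths, 785 nm laser, NA 0.75 in air, 20x magnification,
#' 5.5 um pixels on a 2048 x 1088 detector, N = 1000 strips.
#'
#' @return A nested list of class `run_config` with blocks `optics`,
#'   `aperture`, `simulation` and `noise`.
#' @export
default_run_config <- function() {
  structure(list(
    optics = list(
      f_objective_mm = 10, f_imaging_mm = 200, wavelength_nm = 785,
      na = 0.75, medium_index = 1, magnification = 20,
      beam_half_aperture_mm = 10, pixel_pitch_um = 5.5,
      detector_px = c(2048L, 1088L)
    ),
    aperture = list(b_mm = 10, a_mm = 8),
    simulation = list(n_strips = 1000L, rule = "circular_chord",
                      window_um = 5, samples = 1025L),
    noise = list(photon_scale = 2e7, read_sigma = 2, seed = 1L)
  ), class = "run_config")
}

config_schema <- function() {
  lapply(unclass(default_run_config()), names)
}

validate_run_config <- function(config) {
  schema <- config_schema()
  unknown_blocks <- setdiff(names(config), names(schema))
  if (length(unknown_blocks))
    stop(sprintf("config error: unknown block '%s'", unknown_blocks[1]))
  for (block in names(schema)) {
    if (is.null(config[[block]]))
      stop(sprintf("config error: missing block '%s'", block))
    unknown <- setdiff(names(config[[block]]), schema[[block]])
    if (length(unknown))
      stop(sprintf("config error: unknown field '%s.%s'", block, unknown[1]))
    missing <- setdiff(schema[[block]], names(config[[block]]))
    if (length(missing))
      stop(sprintf("config error: missing field '%s.%s'", block, missing[1]))
  }
  numeric_fields <- list(
    c("optics", "f_objective_mm"), c("optics", "f_imaging_mm"),
    c("optics", "wavelength_nm"), c("optics", "na"),
    c("optics", "medium_index"), c("optics", "magnification"),
    c("optics", "pixel_pitch_um"), c("aperture", "b_mm"),
    c("aperture", "a_mm"), c("simulation", "n_strips"),
    c("simulation", "window_um"), c("simulation", "samples"),
    c("noise", "photon_scale"), c("noise", "read_sigma")
  )
  for (fld in numeric_fields) {
    v <- config[[fld[1]]][[fld[2]]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("config error: field '%s.%s' must be a finite number",
                   fld[1], fld[2]))
  }
  if (!config$simulation$rule %in% c("circular_chord", "as_printed_linear"))
    stop("config error: field 'simulation.rule' must be 'circular_chord' or 'as_printed_linear'")
  if (length(config$optics$detector_px) != 2)
    stop("config error: field 'optics.detector_px' must be c(width, height)")
  structure(config[names(schema)], class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads and validates a configuration file (YAML; JSON parses as a YAML
#' subset). Unknown blocks or fields are rejected with a message naming the
#' offender; all fields of the schema must be present (start from
#' [default_run_config()] and [save_run_config()]).
#'
#' @param path file to read.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  validate_run_config(yaml::read_yaml(path))
}

#' Save a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_run_config(config)), path)
  invisible(path)
}

#' Build the optical train described by a configuration
#'
#' @param config a `run_config`.
#' @return An [optical_train()].
#' @export
as_optical_train <- function(config) {
  o <- config$optics
  optical_train(o$f_objective_mm, o$f_imaging_mm, o$wavelength_nm, o$na,
                o$medium_index, o$magnification, o$beam_half_aperture_mm,
                o$pixel_pitch_um, o$detector_px)
}

#' Build the aperture described by a configuration
#'
#' @param config a `run_config`.
#' @return An [aperture_spec()].
#' @export
as_aperture_spec <- function(config) {
  aperture_spec(config$aperture$b_mm, config$aperture$a_mm)
}

#' Write a tau sweep as CSV
#'
#' Emits the sweep with header `tau,x0_um,y0_um,snr_db`, '.' decimal
#' separator, no locale dependence; identical inputs give identical bytes.
#'
#' @param sweep a [tau_sweep()] data frame (possibly empty).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_tau_sweep_csv <- function(sweep, path) {
  cols <- c("tau", "x0_um", "y0_um", "snr_db")
  if (nrow(sweep)) sweep <- sweep[, cols] else
    sweep <- as.data.frame(setNames(rep(list(numeric(0)), 4), cols))
  write.csv(format(sweep, trim = TRUE, digits = 15, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a resolution report or depth estimate as JSON
#'
#' @param x a `resolution_report`, `depth_estimate` or any list/data frame.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a computed field grid as CSV plus JSON metadata
#'
#' Writes `<prefix>.csv` with columns `x_um,y_um,re,im` (long format) and
#' `<prefix>.json` with the grid's provenance (model, strip count, rule,
#' wavelength, focal length, normalization).
#'
#' @param field a `field_grid`.
#' @param prefix output path prefix.
#' @return The CSV path, invisibly.
#' @export
write_field_grid <- function(field, prefix) {
  df <- data.frame(
    x_um = rep(field$x_um, times = length(field$y_um)),
    y_um = rep(field$y_um, each = length(field$x_um)),
    re = as.vector(Re(field$amplitude)),
    im = as.vector(Im(field$amplitude))
  )
  csv <- paste0(prefix, ".csv")
  write.csv(df, csv, row.names = FALSE, quote = FALSE)
  meta <- field[c("model", "n_strips", "rule", "wavelength_um", "focal_um",
                  "normalization")]
  meta$aperture <- unclass(field$aperture)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(csv)
}

#' Write a detector frame as 16-bit TIFF (with optional PNG preview)
#'
#' @param image a `detector_image`.
#' @param path TIFF output path.
#' @param png_preview optional path for a contrast-normalized 8-bit PNG.
#' @param sidecar optional path for a JSON sidecar of ground-truth render
#'   parameters (`list(...)` stored as-is).
#' @param sidecar_data parameters to store in the sidecar.
#' @return `path`, invisibly.
#' @export
write_detector_image <- function(image, path, png_preview = NULL,
                                 sidecar = NULL, sidecar_data = NULL) {
  scale <- 2^image$bit_depth - 1
  # TIFF expects [row = y, col = x] in [0, 1]
  tiff::writeTIFF(t(pmin(image$pixels, scale)) / scale, path,
                  bits.per.sample = 16L, compression = "none")
  if (!is.null(png_preview)) {
    mx <- max(image$pixels)
    png::writePNG(t(image$pixels) / max(mx, 1), png_preview)
  }
  if (!is.null(sidecar))
    jsonlite::write_json(sidecar_data, sidecar, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a detector frame written by [write_detector_image()]
#'
#' @param path TIFF file.
#' @param train the [optical_train()] the frame was rendered with (supplies
#'   pitch and bit depth).
#' @return A `detector_image` (quantized counts).
#' @export
read_detector_image <- function(path, train) {
  m <- tiff::readTIFF(path)
  pixels <- t(m) * (2^16 - 1)
  new_detector_image(round(pixels), train, photon_scale = NA_real_,
                     read_sigma = NA_real_, seed = NULL, quantized = TRUE,
                     clipped = FALSE)
}
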