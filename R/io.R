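#' Write / read a recording as delimited text plus JSON sidecar
#'
#' The trace goes to a two-column tab-separated file with header
#' (`time_s`, `voltage`); sampling rate, PRF, focus and seed go to a JSON
#' sidecar at `<path>.json`.  Voltages are written with full double
#' precision so a round trip is bit-exact.
#'
#' @param rec An `ae_recording`.
#' @param path Output file path for the trace.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  tr <- resolve_trace(rec)
  df <- data.frame(time_s = sprintf("%.17g", rec$time),
                   voltage = sprintf("%.17g", tr$samples))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(fs = tr$fs, prf = attr(rec, "prf"),
               focus_x_mm = attr(rec, "focus")[1],
               focus_y_mm = attr(rec, "focus")[2],
               seed = attr(rec, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param strict Error (rather than NA) on malformed numeric fields.
#' @export
read_recording <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_input("trace file not found: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_input("missing sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("fs", "prf")) {
    if (is.null(meta[[field]])) {
      stop_input("sidecar %s is missing required field `%s`", sidecar, field)
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("time_s", "voltage") %in% names(df))) {
    stop_input("%s must have columns time_s and voltage", path)
  }
  v <- suppressWarnings(as.numeric(df$voltage))
  t_s <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(!is.finite(v) | !is.finite(t_s))
  if (length(bad) > 0 && strict) {
    stop_input("non-numeric value at data row %d of %s", bad[1], path)
  }
  focus <- c(meta$focus_x_mm %||% NA_real_, meta$focus_y_mm %||% NA_real_)
  new_ae_tibble(tibble::tibble(time = t_s, voltage = v), "ae_recording",
                fs = as.numeric(meta$fs), prf = as.numeric(meta$prf),
                focus = focus, seed = meta$seed %||% NA_integer_)
}

#' Write / read an image map as a delimited matrix plus JSON sidecar
#'
#' The matrix is written row-per-y-coordinate; coordinates and steps go to
#' `<path>.json`.
#'
#' @param img An `ae_image`.
#' @param path Output file path.
#' @return `path`, invisibly (`read_image` returns the `ae_image`).
#' @export
write_image <- function(img, path) {
  m <- image_matrix(img)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(x_coords = attr(img, "x_coords"),
               y_coords = attr(img, "y_coords"),
               x_step = attr(img, "x_step"), y_step = attr(img, "y_step"))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_input("image file not found: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_input("missing sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  if (nrow(m) != length(meta$y_coords) || ncol(m) != length(meta$x_coords)) {
    stop_input("matrix in %s is %dx%d but sidecar lists %d y and %d x coords",
               path, nrow(m), ncol(m),
               length(meta$y_coords), length(meta$x_coords))
  }
  matrix_to_image(m, meta$x_coords, meta$y_coords, meta$x_step, meta$y_step)
}

#' Read a phantom configuration from JSON
#'
#' Expects the fields of [phantom_config()], with `sources` an array of
#' `{x, y, frequency, amplitude, phase}` objects and `transducer` an
#' object of [transducer_spec()] fields; missing required fields are
#' reported by name.
#'
#' @param path JSON file path.
#' @return A `phantom_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("sources", "fs_record")) {
    if (is.null(cfg[[field]])) {
      stop_input("config %s is missing required field `%s`", path, field)
    }
  }
  src <- cfg$sources
  sources <- source_spec(src$x, src$y, src$frequency,
                         src$amplitude %||% 100, src$phase %||% 0)
  tr_args <- cfg$transducer %||% list()
  transducer <- do.call(transducer_spec, as.list(tr_args))
  args <- cfg[setdiff(names(cfg), c("sources", "transducer"))]
  do.call(phantom_config, c(list(sources = sources, transducer = transducer),
                            args))
}

#' @rdname read_config
#' @param config A `phantom_config` to serialize.
#' @export
write_config <- function(config, path) {
  out <- list(sources = config$sources,
              transducer = unclass(config$transducer),
              fs_record = config$fs_record, duration = config$duration,
              ae_constant = config$ae_constant,
              pressure_peak = config$pressure_peak,
              modulation_index = config$modulation_index,
              lf_leak_gain = config$lf_leak_gain,
              noise_sd = config$noise_sd, seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

# scenario artifacts + a manifest sufficient to re-run bit-identically
write_scenario <- function(sc, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sc$report, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(sc$config, file.path(out_dir, "config.json"))
  if (!is.null(sc$maps)) {
    for (mth in names(sc$maps)) {
      write_image(sc$maps[[mth]]$image,
                  file.path(out_dir, paste0("map_", tolower(mth), ".tsv")))
    }
  }
  manifest <- list(
    scenario = sc$name,
    seed = sc$config$seed,
    config_hash = rlang::hash(readChar(file.path(out_dir, "config.json"),
                                       1e6, useBytes = TRUE)),
    package = "abidecode",
    version = as.character(utils::packageVersion("abidecode")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
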