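# Plain-text I/O: chromatogram CSV with JSON sidecar, peak-table CSV,
# method config (YAML/JSON), calibration JSON.

#' Write / read a chromatogram as CSV plus JSON sidecar
#'
#' The trace is stored as a two-column CSV (`time_min,intensity_mau`); the
#' acquisition conditions and channel wavelength go to `<path>.meta.json`.
#'
#' @param chrom A `chromatogram`.
#' @param path CSV file path.
#' @return `write_chromatogram()` returns `path` invisibly;
#'   `read_chromatogram()` returns a `chromatogram`.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  utils::write.csv(
    data.frame(time_min = chrom$time, intensity_mau = chrom$intensity),
    path, row.names = FALSE)
  meta <- unclass(chrom$condition)
  meta$sampling_rate <- chrom$sampling_rate
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_min", "intensity_mau") %in% names(df)))
  meta_path <- paste0(path, ".meta.json")
  cond <- condition_set()
  sampling_rate <- 1 / stats::median(diff(df$time_min))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    cond <- condition_set(
      instrument_id = meta$instrument_id %||% "unknown",
      column_id = meta$column_id %||% "unknown",
      flow_rate = meta$flow_rate %||% 1,
      column_temp = meta$column_temp %||% 35,
      injection_volume = meta$injection_volume %||% 10,
      wavelength = meta$wavelength %||% 285,
      conc_level = meta$conc_level %||% 1)
    if (!is.null(meta$sampling_rate)) sampling_rate <- meta$sampling_rate
  }
  structure(
    list(time = df$time_min, intensity = df$intensity_mau,
         condition = cond, wavelength = cond$wavelength,
         sampling_rate = sampling_rate),
    class = "chromatogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a peak table CSV
#'
#' Fixed column layout `analyte,t_r_min,area,height,snr` (extra columns are
#' preserved on write and ignored on read).
#'
#' @param peaks Peak table data frame.
#' @param path CSV file path.
#' @return `write_peak_table()` returns `path` invisibly;
#'   `read_peak_table()` returns a data frame.
#' @export
write_peak_table <- function(peaks, path) {
  stopifnot(is.data.frame(peaks))
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "t_r_min", "area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a method configuration (YAML or JSON)
#'
#' A config either names a shipped preset (`preset: nonivamide` or
#' `preset: hass`) or fully specifies the method: `ir_name`, `wavelength`,
#' `ref_conc_ug_ml`, optional `rrt_tolerance` / `smd_threshold` /
#' `durability_threshold`, and an `analytes` list of
#' `{name, expected_rrt, rcf}` entries.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A `qams_method` object.
#' @export
read_method_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$preset)) {
    m <- method_preset(cfg$preset,
                       rrt_tolerance = cfg$rrt_tolerance %||% 0.05,
                       smd_threshold = cfg$smd_threshold %||% 5.0,
                       durability_threshold =
                         cfg$durability_threshold %||% 3.0)
    return(m)
  }
  an <- cfg$analytes
  if (is.data.frame(an)) {
    analytes <- an
  } else {
    analytes <- do.call(rbind, lapply(an, function(e)
      data.frame(name = e$name, expected_rrt = e$expected_rrt,
                 rcf = e$rcf %||% 1, stringsAsFactors = FALSE)))
  }
  analytes$is_ir <- analytes$name == cfg$ir_name
  if (sum(analytes$is_ir) != 1)
    stop("config must designate exactly one internal reference",
         call. = FALSE)
  structure(
    list(ir_name = cfg$ir_name,
         wavelength = cfg$wavelength %||% 285,
         analytes = analytes,
         ref_conc_ug_ml = cfg$ref_conc_ug_ml %||% NA_real_,
         rrt_tolerance = cfg$rrt_tolerance %||% 0.05,
         smd_threshold = cfg$smd_threshold %||% 5.0,
         durability_threshold = cfg$durability_threshold %||% 3.0),
    class = "qams_method")
}

#' Write calibration curves to JSON
#'
#' @param curves Named list of `calibration_curve` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curves, path) {
  out <- lapply(curves, function(cv) list(
    analyte = cv$analyte_name, slope = cv$slope, intercept = cv$intercept,
    r = cv$r, mass_range = cv$mass_range, lod = cv$lod, loq = cv$loq))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read calibration curves from JSON
#'
#' @param path JSON path written by [write_calibration()].
#' @return Named list of `calibration_curve` objects.
#' @export
read_calibration <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(cv) structure(
    list(analyte_name = cv$analyte, slope = cv$slope,
         intercept = cv$intercept, r = cv$r,
         mass_range = as.numeric(cv$mass_range),
         lod = cv$lod %||% NA_real_, loq = cv$loq %||% NA_real_,
         n = NA_integer_),
    class = "calibration_curve"))
  stats::setNames(out, names(raw))
}
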