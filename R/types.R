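#' Chromatographic condition set
#'
#' Describes the acquisition conditions of a single HPLC run: instrument,
#' column, flow rate, column temperature, injection volume, detection
#' wavelength and a relative concentration multiplier for the injected
#' solution. The defaults are the established analytical conditions of the
#' Sichuan-pepper alkylamide method (C18 column at 35 degC, 1 mL/min, 10 uL
#' injection, detection at 285 nm).
#'
#' @param instrument_id Instrument label (e.g. `"LC-20A"`).
#' @param column_id Column label (e.g. `"SuperLu-C18"`).
#' @param flow_rate Mobile-phase flow rate in mL/min; must be > 0.
#' @param column_temp Column temperature in degC.
#' @param injection_volume Injection volume in uL; must be > 0.
#' @param wavelength Detection wavelength in nm, within 190-800.
#' @param conc_level Relative concentration multiplier applied to the
#'   injected solution (dimensionless); must be > 0.
#' @return An object of class `condition_set`.
#' @examples
#' condition_set()                      # reference conditions
#' condition_set(flow_rate = 0.7, column_temp = 25)
#' @export
condition_set <- function(instrument_id = "LC-20A",
                          column_id = "SuperLu-C18",
                          flow_rate = 1.0,
                          column_temp = 35,
                          injection_volume = 10,
                          wavelength = 285,
                          conc_level = 1.0) {
  stopifnot(is.numeric(flow_rate), length(flow_rate) == 1L,
            is.numeric(injection_volume), length(injection_volume) == 1L,
            is.numeric(wavelength), length(wavelength) == 1L,
            is.numeric(conc_level), length(conc_level) == 1L)
  if (flow_rate <= 0) stop("flow_rate must be > 0", call. = FALSE)
  if (injection_volume <= 0) stop("injection_volume must be > 0", call. = FALSE)
  if (wavelength < 190 || wavelength > 800)
    stop("wavelength must lie within 190-800 nm", call. = FALSE)
  if (conc_level <= 0) stop("conc_level must be > 0", call. = FALSE)
  structure(
    list(instrument_id = as.character(instrument_id),
         column_id = as.character(column_id),
         flow_rate = flow_rate,
         column_temp = column_temp,
         injection_volume = injection_volume,
         wavelength = wavelength,
         conc_level = conc_level),
    class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf(
    "<condition_set> %s / %s | %.2g mL/min, %g degC, %g uL, %g nm, conc x%g\n",
    x$instrument_id, x$column_id, x$flow_rate, x$column_temp,
    x$injection_volume, x$wavelength, x$conc_level))
  invisible(x)
}

#' Noise model for simulated chromatograms
#'
#' @param baseline_sigma Standard deviation of white baseline noise, in the
#'   detector's area-consistent milli-absorbance units; must be >= 0. The
#'   default is calibrated so that the alpha-sanshool channel's detection
#'   limit lands at the sub-nanogram scale typical of PDA detection.
#' @param drift_slope Linear baseline drift in mAU per minute.
#' @param area_rsd Relative standard deviation of multiplicative peak-area
#'   noise applied when peak tables are generated directly (dimensionless,
#'   e.g. 0.01 for 1%).
#' @param seed Integer RNG seed; every simulation entry point is fully
#'   deterministic given its `NoiseSpec` seed.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(baseline_sigma = 0)     # noiseless traces
#' @export
noise_spec <- function(baseline_sigma = 1760,
                       drift_slope = 0,
                       area_rsd = 0.01,
                       seed = 20240101) {
  stopifnot(is.numeric(baseline_sigma), is.numeric(drift_slope),
            is.numeric(area_rsd), is.numeric(seed))
  if (baseline_sigma < 0) stop("baseline_sigma must be >= 0", call. = FALSE)
  if (area_rsd < 0) stop("area_rsd must be >= 0", call. = FALSE)
  structure(
    list(baseline_sigma = baseline_sigma,
         drift_slope = drift_slope,
         area_rsd = area_rsd,
         seed = as.integer(seed)),
    class = "noise_spec")
}

#' Peak shape specification for simulation
#'
#' An exponentially modified Gaussian (EMG) peak; `tau = 0` degenerates to a
#' pure Gaussian. Areas are expressed in mAU*s, times in minutes.
#'
#' @param analyte_name Analyte label carried into the ground-truth manifest.
#' @param t_r Retention time in minutes; must be > 0.
#' @param area True peak area in mAU*s; must be >= 0.
#' @param sigma Gaussian width in minutes; must be > 0.
#' @param tau Exponential tailing constant in minutes; 0 means no tailing.
#' @return An object of class `peak_shape_spec`.
#' @export
peak_shape_spec <- function(analyte_name, t_r, area, sigma = 0.15, tau = 0) {
  stopifnot(is.numeric(t_r), is.numeric(area), is.numeric(sigma),
            is.numeric(tau))
  if (t_r <= 0) stop("t_r must be > 0", call. = FALSE)
  if (area < 0) stop("area must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  structure(
    list(analyte_name = as.character(analyte_name),
         t_r = t_r, area = area, sigma = sigma, tau = tau),
    class = "peak_shape_spec")
}

#' Detector response model for one analyte
#'
#' Linear area-versus-mass response: `area = slope * mass + intercept` at the
#' reference wavelength, multiplied by a per-wavelength relative response
#' factor. Mass is on-column mass in micrograms.
#'
#' @param analyte_name Analyte label.
#' @param slope Response slope in mAU*s per ug on column; must be > 0.
#' @param intercept Response intercept in mAU*s.
#' @param wavelength_factor Named numeric vector mapping wavelength (nm, as
#'   names) to a relative response multiplier; all values must be > 0.
#'   Wavelengths absent from the map default to a factor of 1.
#' @param t_r Default retention time (minutes) used when this model drives a
#'   simulated peak.
#' @param sigma Default Gaussian peak width (minutes).
#' @param tau Default exponential tailing constant (minutes).
#' @return An object of class `response_model`.
#' @export
response_model <- function(analyte_name, slope, intercept = 0,
                           wavelength_factor = c("285" = 1),
                           t_r = NULL, sigma = 0.15, tau = 0) {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (any(wavelength_factor <= 0))
    stop("wavelength_factor values must be > 0", call. = FALSE)
  structure(
    list(analyte_name = as.character(analyte_name),
         slope = slope, intercept = intercept,
         wavelength_factor = wavelength_factor,
         t_r = t_r, sigma = sigma, tau = tau),
    class = "response_model")
}

#' Look up the relative response factor of a response model at a wavelength
#'
#' @param model A [response_model()].
#' @param wavelength Wavelength in nm.
#' @return Numeric multiplier (1 when the wavelength is not in the map).
#' @export
wavelength_factor_at <- function(model, wavelength) {
  wf <- model$wavelength_factor
  key <- as.character(wavelength)
  if (!is.null(wf) && key %in% names(wf)) unname(wf[[key]]) else 1
}

# internal: condition -> stable single-string key for grids/maps
condition_key <- function(cond) {
  paste(cond$instrument_id, cond$column_id,
        format(cond$flow_rate), format(cond$column_temp),
        format(cond$injection_volume), format(cond$wavelength),
        format(cond$conc_level), sep = "|")
}
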