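# Linear calibration (area vs on-column mass) and external-standard
# quantitation.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area against on-column mass
#' (`Y = slope * X + intercept`), with the Pearson correlation coefficient
#' of the points. A `1/x` weighted fit is available for heteroscedastic
#' series.
#'
#' @param points Data frame with columns `mass` (ug on column; see Details)
#'   and `area` (mAU*s), one row per calibration injection.
#' @param analyte_name Label stored on the curve.
#' @param weighted `FALSE` (default, ordinary least squares), `"1/x"`
#'   (or `TRUE`) for `1/mass` weights, or `"1/x2"` for `1/mass^2` weights.
#'   `1/x2` is the variance-matched choice when area noise is relative
#'   (constant RSD), which otherwise inflates the intercept variance and
#'   biases back-calculation at the low end of the range.
#' @param lod,loq Optional detection/quantitation limits (same unit as
#'   `mass`) carried on the curve.
#' @details The abscissa is the reference-standard mass on column, i.e.
#'   injected concentration times injection volume. Any consistent unit
#'   works; quantitation reports back in the unit the curve was fitted in.
#' @return Object of class `calibration_curve`: list with `analyte_name`,
#'   `slope`, `intercept`, `r`, `mass_range`, `lod`, `loq`, `n`.
#' @examples
#' pts <- data.frame(mass = 0:5, area = 2e5 * (0:5) + 40)
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, analyte_name = "unknown",
                            weighted = FALSE, lod = NA_real_,
                            loq = NA_real_) {
  stopifnot(is.data.frame(points), all(c("mass", "area") %in% names(points)))
  x <- points$mass
  y <- points$area
  if (length(x) < 3) stop("need >= 3 calibration points", call. = FALSE)
  if (any(x < 0)) stop("masses must be >= 0", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("all masses equal: calibration design is rank-deficient",
         call. = FALSE)
  w <- if (isFALSE(weighted)) rep(1, length(x))
  else if (isTRUE(weighted) || identical(weighted, "1/x"))
    1 / pmax(x, .Machine$double.eps)
  else if (identical(weighted, "1/x2")) 1 / pmax(x, .Machine$double.eps)^2
  else stop("weighted must be FALSE, TRUE, \"1/x\" or \"1/x2\"",
            call. = FALSE)
  fit <- stats::lm(y ~ x, weights = w)
  structure(
    list(analyte_name = analyte_name,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = stats::cor(x, y),
         mass_range = range(x),
         lod = lod, loq = loq, n = length(x)),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: Y = %.6g X %+.6g, r = %.6f, range [%.4g, %.4g]\n",
    x$analyte_name, x$slope, x$intercept, x$r,
    x$mass_range[1], x$mass_range[2]))
  invisible(x)
}

#' External-standard quantitation of one peak area
#'
#' Back-calculates on-column mass through a calibration curve and converts
#' to the injected concentration.
#'
#' @param area Peak area in mAU*s.
#' @param curve A [fit_calibration()] curve (mass abscissa in ug).
#' @param injection_volume Injection volume in uL (default 10).
#' @return List with `mass_ug`, `conc_ug_ml` and `flags` (character vector;
#'   possible flags: `below_range`, `above_range`, `below_lod`,
#'   `below_loq`). Negative back-calculated masses are reported as 0 with a
#'   `below_range` flag.
#' @examples
#' cv <- fit_calibration(data.frame(mass = 0:5, area = 1e5 * (0:5)))
#' quantify_esm(2.5e5, cv)
#' @export
quantify_esm <- function(area, curve, injection_volume = 10) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (injection_volume <= 0) stop("injection_volume must be > 0",
                                  call. = FALSE)
  mass <- (area - curve$intercept) / curve$slope
  flags <- character(0)
  if (mass < 0) {
    mass <- 0
    flags <- c(flags, "below_range")
  } else {
    if (mass < curve$mass_range[1]) flags <- c(flags, "below_range")
    if (mass > curve$mass_range[2]) flags <- c(flags, "above_range")
  }
  if (!is.na(curve$lod) && mass < curve$lod) flags <- c(flags, "below_lod")
  if (!is.na(curve$loq) && mass < curve$loq) flags <- c(flags, "below_loq")
  if (any(c("below_range", "above_range") %in% flags))
    warning(sprintf("%s: back-calculated mass %.4g ug outside the calibrated range",
                    curve$analyte_name, mass), call. = FALSE)
  list(mass_ug = mass,
       conc_ug_ml = mass / (injection_volume * 1e-3),
       flags = flags)
}

#' Check calibration linearity against a correlation threshold
#'
#' @param curve A `calibration_curve`.
#' @param r_threshold Minimum acceptable Pearson r (default 0.9990).
#' @return List with `pass` (logical), `r`, `r_threshold`, `mass_range`.
#' @examples
#' cv <- fit_calibration(data.frame(mass = 0:5, area = 1e5 * (0:5)))
#' check_linearity(cv)$pass
#' @export
check_linearity <- function(curve, r_threshold = 0.9990) {
  stopifnot(inherits(curve, "calibration_curve"))
  list(pass = curve$r >= r_threshold,
       r = curve$r,
       r_threshold = r_threshold,
       mass_range = curve$mass_range)
}

#' Published calibration curves of the five alkylamides
#'
#' Convenience constructor returning the published regression lines as
#' `calibration_curve` objects on the on-column-mass abscissa (ug), with the
#' published LOD/LOQ converted from ng.
#'
#' @return Named list of `calibration_curve` objects keyed by analyte.
#' @export
reference_curves <- function() {
  tab <- alkylamide_table()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    structure(
      list(analyte_name = tab$analyte[i],
           slope = tab$slope[i] / (REF_INJECTION_UL * 1e-3),
           intercept = tab$intercept[i],
           r = tab$r[i],
           mass_range = c(tab$range_lo_ug_ml[i], tab$range_hi_ug_ml[i]) *
             REF_INJECTION_UL * 1e-3,
           lod = tab$lod_ng[i] * 1e-3,
           loq = tab$loq_ng[i] * 1e-3,
           n = NA_integer_),
      class = "calibration_curve")
  })
  stats::setNames(out, tab$analyte)
}
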