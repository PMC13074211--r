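# Synthetic chromatogram generator. Traces are exponentially modified
# Gaussian (EMG) peaks on a drifting noisy baseline; all randomness is
# seeded through a noise_spec so every run is reproducible.

# erfc via the normal CDF (avoids an extra dependency)
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)

# EMG profile in mAU at times t (minutes). `area` is in mAU*s; the profile
# integrates (over minutes) to area/60.
emg_profile <- function(t, t_r, area, sigma, tau) {
  a_min <- area / 60
  if (tau <= .Machine$double.eps) {
    a_min * stats::dnorm(t, mean = t_r, sd = sigma)
  } else {
    z <- (sigma / tau - (t - t_r) / sigma) / sqrt(2)
    a_min / (2 * tau) *
      exp(sigma^2 / (2 * tau^2) - (t - t_r) / tau) * erfc(z)
  }
}

#' Simulate a chromatogram trace
#'
#' Builds a sampled detector trace as the sum of EMG peaks, a linear
#' baseline drift and seeded white noise. The numerically integrated area of
#' an isolated noiseless peak matches its specified area to well within
#' 0.5%.
#'
#' @param peaks List of [peak_shape_spec()] objects.
#' @param duration Run length in minutes (default 50, the reference gradient
#'   window).
#' @param sampling_rate Sampling rate in points per minute; must be >= 10.
#' @param noise A [noise_spec()].
#' @param condition A [condition_set()] recorded as metadata.
#' @return An object of class `chromatogram`: list with `time` (min),
#'   `intensity` (mAU), `condition`, `wavelength`, `sampling_rate`.
#' @examples
#' pk <- peak_shape_spec("HaSS", t_r = 26, area = 1e5, sigma = 0.15)
#' ch <- simulate_chromatogram(list(pk), noise = noise_spec(baseline_sigma = 0))
#' @export
simulate_chromatogram <- function(peaks,
                                  duration = 50,
                                  sampling_rate = 20,
                                  noise = noise_spec(),
                                  condition = condition_set()) {
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (sampling_rate < 10)
    stop("sampling_rate must be >= 10 points/min", call. = FALSE)
  stopifnot(inherits(noise, "noise_spec"), inherits(condition, "condition_set"))
  for (p in peaks) {
    if (!inherits(p, "peak_shape_spec"))
      stop("peaks must be peak_shape_spec objects", call. = FALSE)
    if (p$t_r > duration)
      stop(sprintf("peak '%s' at %g min lies outside the %g min run",
                   p$analyte_name, p$t_r, duration), call. = FALSE)
  }
  # resolution check between neighbouring peaks
  if (length(peaks) > 1) {
    trs <- vapply(peaks, `[[`, numeric(1), "t_r")
    ord <- order(trs)
    for (k in seq_len(length(peaks) - 1)) {
      i <- ord[k]; j <- ord[k + 1]
      if (abs(peaks[[j]]$t_r - peaks[[i]]$t_r) <
          3 * (peaks[[i]]$sigma + peaks[[j]]$sigma))
        warning(sprintf("peaks '%s' and '%s' are poorly resolved",
                        peaks[[i]]$analyte_name, peaks[[j]]$analyte_name),
                call. = FALSE)
    }
  }
  t <- seq(0, duration, by = 1 / sampling_rate)
  signal <- noise$drift_slope * t
  for (p in peaks) {
    if (p$area > 0)
      signal <- signal + emg_profile(t, p$t_r, p$area, p$sigma, p$tau)
  }
  if (noise$baseline_sigma > 0) {
    old <- local_seed(noise$seed)
    on.exit(restore_seed(old), add = TRUE)
    signal <- signal + stats::rnorm(length(t), 0, noise$baseline_sigma)
  }
  structure(
    list(time = t, intensity = signal, condition = condition,
         wavelength = condition$wavelength, sampling_rate = sampling_rate),
    class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d points over %.4g min at %g nm\n",
              length(x$time), max(x$time), x$wavelength))
  invisible(x)
}

# Seed handling: set a temporary seed, restore global state afterwards so
# simulation calls do not perturb the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# True peak area for a response model at on-column mass (ug) under a
# condition: affine response at the reference channel scaled by the
# channel's relative response factor. Mass <= 0 yields no peak.
true_area <- function(model, mass_ug, condition) {
  if (mass_ug <= 0) return(0)
  wf <- wavelength_factor_at(model, condition$wavelength)
  max((model$slope * mass_ug + model$intercept) * wf, 0)
}

peak_from_model <- function(model, area, condition,
                            base_condition = condition_set()) {
  # retention scales with inverse flow and shifts linearly with temperature
  t_r <- model$t_r * base_condition$flow_rate / condition$flow_rate -
    0.05 * (condition$column_temp - base_condition$column_temp)
  peak_shape_spec(model$analyte_name, t_r = t_r, area = area,
                  sigma = model$sigma, tau = model$tau)
}

#' Simulate a calibration standard series
#'
#' Generates one chromatogram per calibration level, with every analyte's
#' true peak area following its response model (`area = slope * mass +
#' intercept`, scaled by the channel factor at the condition's wavelength),
#' plus a ground-truth manifest. On-column mass is taken as the level mass
#' scaled by `injection_volume` relative to the 10 uL reference, so doubling
#' the injection doubles the mass and (up to the intercept) the area.
#'
#' @param responses Named list of [response_model()] objects.
#' @param levels List of named numeric vectors, one per standard injection,
#'   mapping analyte name to on-column mass (ug) at the reference
#'   injection. See [standard_levels()] for a convenience builder.
#' @param condition A [condition_set()].
#' @param noise A [noise_spec()]; each level uses `seed + level index`.
#' @param mass_range Optional named list of `c(lo, hi)` mass bounds (ug);
#'   masses outside get `out_of_range` flags in the manifest.
#' @param return_traces If `FALSE`, skip trace synthesis and return peak
#'   tables with multiplicative `area_rsd` noise instead (fast path).
#' @return List with `chromatograms` (or `peak_tables`) and `manifest`
#'   (data.frame `level`, `analyte`, `mass_ug`, `conc_ug_ml`, `area`,
#'   `flag`).
#' @export
simulate_standard_series <- function(responses, levels,
                                     condition = condition_set(),
                                     noise = noise_spec(),
                                     mass_range = NULL,
                                     return_traces = TRUE) {
  stopifnot(is.list(responses), is.list(levels))
  chroms <- list()
  tables <- list()
  man <- list()
  for (k in seq_along(levels)) {
    lv <- levels[[k]]
    stopifnot(!is.null(names(lv)))
    specs <- list()
    rows <- list()
    lvl_noise <- noise_spec(noise$baseline_sigma, noise$drift_slope,
                            noise$area_rsd, noise$seed + k)
    old <- local_seed(lvl_noise$seed + 500000L)
    for (a in names(lv)) {
      model <- responses[[a]]
      if (is.null(model))
        stop(sprintf("no response model for analyte '%s'", a), call. = FALSE)
      mass <- lv[[a]] * condition$injection_volume / REF_INJECTION_UL *
        condition$conc_level
      area <- true_area(model, mass, condition)
      flag <- ""
      if (!is.null(mass_range) && !is.null(mass_range[[a]])) {
        if (mass < mass_range[[a]][1] || mass > mass_range[[a]][2])
          flag <- "out_of_range"
      }
      if (area > 0) {
        obs_area <- area
        if (!return_traces && noise$area_rsd > 0)
          obs_area <- area * (1 + stats::rnorm(1, 0, noise$area_rsd))
        specs[[length(specs) + 1L]] <-
          peak_from_model(model, obs_area, condition)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        level = k, analyte = a, mass_ug = mass,
        conc_ug_ml = mass / (condition$injection_volume * 1e-3),
        area = area, flag = flag, stringsAsFactors = FALSE)
    }
    restore_seed(old)
    if (return_traces) {
      chroms[[k]] <- simulate_chromatogram(
        specs, noise = lvl_noise, condition = condition)
    } else {
      tables[[k]] <- peak_table_from_specs(specs, lvl_noise)
    }
    man[[k]] <- do.call(rbind, rows)
  }
  manifest <- do.call(rbind, man)
  attr(manifest, "condition") <- condition
  attr(manifest, "seed") <- noise$seed
  if (return_traces) list(chromatograms = chroms, manifest = manifest)
  else list(peak_tables = tables, manifest = manifest)
}

#' Build per-analyte standard level masses spanning the linear ranges
#'
#' @param responses Named list of [response_model()] objects.
#' @param n Number of levels.
#' @param ranges Named list of `c(lo, hi)` on-column mass ranges (ug);
#'   defaults to the published linear concentration ranges converted at the
#'   10 uL reference injection.
#' @return List of `n` named vectors (analyte -> mass ug), geometric between
#'   each analyte's range endpoints.
#' @export
standard_levels <- function(responses, n = 6, ranges = NULL) {
  if (is.null(ranges)) {
    tab <- alkylamide_table()
    ranges <- stats::setNames(lapply(seq_len(nrow(tab)), function(i)
      c(tab$range_lo_ug_ml[i], tab$range_hi_ug_ml[i]) *
        REF_INJECTION_UL * 1e-3), tab$analyte)
  }
  keep <- intersect(names(responses), names(ranges))
  lapply(seq_len(n), function(k) {
    vapply(keep, function(a) {
      r <- ranges[[a]]
      exp(log(r[1]) + (log(r[2]) - log(r[1])) * (k - 1) / (n - 1))
    }, numeric(1))
  })
}

# peak table row builder shared by the fast (traceless) paths
peak_table_from_specs <- function(specs, noise) {
  if (!length(specs)) {
    return(data.frame(analyte = character(), t_r_min = numeric(),
                      area = numeric(), height = numeric(), snr = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(specs, function(p) {
    height <- p$area / 60 / (p$sigma * sqrt(2 * pi))
    data.frame(analyte = p$analyte_name, t_r_min = p$t_r, area = p$area,
               height = height,
               snr = if (noise$baseline_sigma > 0)
                 height / noise$baseline_sigma else Inf,
               stringsAsFactors = FALSE)
  }))
  df[order(df$t_r_min), , drop = FALSE]
}

#' Simulate replicate sample injections from known contents
#'
#' Inverts the content equation `W_i = C_i * V * K / M_m` to derive the
#' extract concentration implied by each true content, drives peak areas
#' through the response models, and emits replicates plus a ground-truth
#' manifest.
#'
#' @param true_contents Named numeric vector, analyte -> content in mg per g
#'   of sample.
#' @param sample_mass Weighed sample mass in g (default 0.025).
#' @param extract_volume Final extract volume in mL (default 25).
#' @param dilution_k Dilution factor K (default 1).
#' @param n_replicates Number of replicate injections (default 3).
#' @param condition A [condition_set()].
#' @param noise A [noise_spec()]; replicate r uses `seed + r`.
#' @param responses Named list of [response_model()] objects (defaults to
#'   the published models).
#' @param return_traces If `FALSE` (default), return noisy peak tables
#'   directly (multiplicative `area_rsd` noise on each true area); if
#'   `TRUE`, synthesize full traces.
#' @return List with `peak_tables` (or `chromatograms`) of length
#'   `n_replicates` and `manifest` (analyte, true content mg/g, extract
#'   concentration ug/mL, on-column mass ug).
#' @examples
#' out <- simulate_sample_batch(c(HaSS = 45), noise = noise_spec(seed = 1))
#' out$manifest
#' @export
simulate_sample_batch <- function(true_contents,
                                  sample_mass = 0.025,
                                  extract_volume = 25,
                                  dilution_k = 1,
                                  n_replicates = 3,
                                  condition = condition_set(),
                                  noise = noise_spec(),
                                  responses = response_models(),
                                  return_traces = FALSE) {
  if (sample_mass <= 0) stop("sample_mass must be > 0", call. = FALSE)
  if (extract_volume <= 0) stop("extract_volume must be > 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  stopifnot(!is.null(names(true_contents)))
  missing_models <- setdiff(names(true_contents), names(responses))
  if (length(missing_models))
    stop("no response model for analyte(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)

  # C_i [mg/mL] = W_i * M_m / (V * K); reported in ug/mL
  conc_ug_ml <- true_contents * sample_mass / (extract_volume * dilution_k) *
    1000
  mass_ug <- conc_ug_ml * condition$injection_volume * 1e-3 *
    condition$conc_level
  manifest <- data.frame(
    analyte = names(true_contents),
    content_mg_g = unname(true_contents),
    conc_ug_ml = unname(conc_ug_ml),
    mass_ug = unname(mass_ug),
    stringsAsFactors = FALSE)
  attr(manifest, "condition") <- condition
  attr(manifest, "seed") <- noise$seed
  attr(manifest, "sample_mass_g") <- sample_mass
  attr(manifest, "extract_volume_ml") <- extract_volume
  attr(manifest, "dilution_k") <- dilution_k

  reps <- lapply(seq_len(n_replicates), function(r) {
    rep_seed <- noise$seed + r
    old <- local_seed(rep_seed + 900000L)
    specs <- list()
    for (i in seq_along(manifest$analyte)) {
      a <- manifest$analyte[i]
      area <- true_area(responses[[a]], manifest$mass_ug[i], condition)
      if (area <= 0) next
      if (noise$area_rsd > 0)
        area <- area * (1 + stats::rnorm(1, 0, noise$area_rsd))
      specs[[length(specs) + 1L]] <-
        peak_from_model(responses[[a]], area, condition)
    }
    restore_seed(old)
    if (return_traces) {
      simulate_chromatogram(
        specs,
        noise = noise_spec(noise$baseline_sigma, noise$drift_slope,
                           noise$area_rsd, rep_seed),
        condition = condition)
    } else {
      peak_table_from_specs(
        specs, noise_spec(noise$baseline_sigma, noise$drift_slope,
                          noise$area_rsd, rep_seed))
    }
  })
  if (return_traces) list(chromatograms = reps, manifest = manifest)
  else list(peak_tables = reps, manifest = manifest)
}

#' Transform peak specifications between condition sets
#'
#' Applies the parametric condition model used throughout the simulator:
#' retention times scale with inverse flow rate and shift linearly with
#' column temperature; areas scale with injection volume and with the
#' channel response-factor ratio; instrument or column swaps apply a
#' configured multiplicative retention factor and a shared area gain. The
#' shared gain is what keeps area ratios between co-injected analytes -- and
#' hence RCFs -- durable across the grid.
#'
#' @param base_peaks List of [peak_shape_spec()] under `base`.
#' @param base,new [condition_set()] objects.
#' @param responses Optional named list of [response_model()] used to
#'   resolve per-analyte channel factors when the wavelength changes.
#' @param tr_factor Multiplicative retention-time factor for instrument or
#'   column swaps (default 1).
#' @param area_gain Multiplicative area gain shared by all peaks of the run
#'   (default 1).
#' @param temp_coef Retention shift per degC (min/degC, default -0.05).
#' @return List of transformed [peak_shape_spec()] objects.
#' @examples
#' pk <- peak_shape_spec("HaSS", 26, 1e5)
#' slow <- condition_set(flow_rate = 0.5)
#' apply_condition_perturbation(list(pk), condition_set(), slow)[[1]]$t_r
#' @export
apply_condition_perturbation <- function(base_peaks, base, new,
                                         responses = NULL,
                                         tr_factor = 1,
                                         area_gain = 1,
                                         temp_coef = -0.05) {
  stopifnot(inherits(base, "condition_set"), inherits(new, "condition_set"))
  if (new$flow_rate <= 0) stop("new flow_rate must be > 0", call. = FALSE)
  lapply(base_peaks, function(p) {
    t_r <- p$t_r * base$flow_rate / new$flow_rate * tr_factor +
      temp_coef * (new$column_temp - base$column_temp)
    gain <- new$injection_volume / base$injection_volume * area_gain *
      new$conc_level / base$conc_level
    if (!is.null(responses) && !is.null(responses[[p$analyte_name]])) {
      m <- responses[[p$analyte_name]]
      gain <- gain * wavelength_factor_at(m, new$wavelength) /
        wavelength_factor_at(m, base$wavelength)
    }
    peak_shape_spec(p$analyte_name, t_r = t_r, area = p$area * gain,
                    sigma = p$sigma, tau = p$tau)
  })
}
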