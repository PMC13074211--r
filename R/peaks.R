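# Baseline estimation, peak detection and integration for sampled traces.

#' Estimate the baseline and noise level of a chromatogram
#'
#' Fits a piecewise-linear baseline through low-quantile anchor points of
#' windowed segments of the trace and estimates the noise standard
#' deviation robustly (scaled median absolute deviation) from residuals in
#' peak-free regions.
#'
#' @param chrom A `chromatogram`.
#' @param peak_free_fraction Fraction of each window treated as peak-free
#'   signal when picking the anchor quantile (default 0.2).
#' @param n_windows Number of windows for the piecewise fit (default 25).
#' @return Object of class `baseline_estimate`: list with `baseline`
#'   (numeric, one value per sample point) and `noise_sigma` (mAU).
#' @export
estimate_baseline <- function(chrom, peak_free_fraction = 0.2,
                              n_windows = 25) {
  stopifnot(inherits(chrom, "chromatogram"))
  y <- chrom$intensity
  t <- chrom$time
  n <- length(y)
  if (n < 100) stop("trace must have >= 100 points", call. = FALSE)
  if (peak_free_fraction <= 0 || peak_free_fraction > 1)
    stop("peak_free_fraction must be in (0, 1]", call. = FALSE)

  if (stats::sd(y) == 0) {
    return(structure(list(baseline = rep(y[1], n), noise_sigma = 0),
                     class = "baseline_estimate"))
  }
  # anchor = low quantile of each window, robust to peaks sticking up
  breaks <- floor(seq(1, n + 1, length.out = n_windows + 1))
  anchor_t <- anchor_y <- numeric(0)
  for (w in seq_len(n_windows)) {
    idx <- breaks[w]:(breaks[w + 1] - 1)
    q <- stats::quantile(y[idx], probs = peak_free_fraction / 2,
                         names = FALSE, type = 7)
    # use the median of the sub-quantile points as the anchor value
    low <- y[idx][y[idx] <= q]
    if (!length(low)) low <- min(y[idx])
    anchor_t <- c(anchor_t, mean(t[idx]))
    anchor_y <- c(anchor_y, stats::median(low))
  }
  # anchors whose whole window sits on a peak (peaks wider than a window)
  # stick up above the interpolation of their neighbours: drop them
  eps <- 1e-6 * diff(range(y))
  for (pass in 1:5) {
    if (length(anchor_t) <= 2) break
    sig <- stats::mad(y - stats::approx(anchor_t, anchor_y, xout = t,
                                        rule = 2)$y)
    excess <- vapply(seq_along(anchor_t), function(i) {
      if (i == 1 || i == length(anchor_t)) return(0)
      anchor_y[i] - stats::approx(anchor_t[-i], anchor_y[-i],
                                  xout = anchor_t[i], rule = 2)$y
    }, numeric(1))
    bad <- excess > 3 * sig + eps
    if (!any(bad)) break
    anchor_t <- anchor_t[!bad]
    anchor_y <- anchor_y[!bad]
  }
  baseline <- stats::approx(anchor_t, anchor_y, xout = t, rule = 2)$y
  resid <- y - baseline
  # peak-free residuals: exclude points far above the baseline
  sigma0 <- stats::mad(resid)
  free <- resid < 3 * max(sigma0, .Machine$double.eps)
  noise_sigma <- stats::mad(resid[free])
  # white noise pulls the low-quantile anchors below the true baseline;
  # re-center the baseline so peak-free residuals have zero median
  offset <- stats::median(resid[free])
  baseline <- baseline + offset
  structure(list(baseline = baseline, noise_sigma = noise_sigma),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> noise_sigma = %.4g mAU over %d points\n",
              x$noise_sigma, length(x$baseline)))
  invisible(x)
}

#' Detect chromatographic peaks
#'
#' Finds local maxima of the baseline-corrected trace exceeding
#' `min_snr * noise_sigma`, delimits each peak where the corrected signal
#' re-crosses 0.1% of the peak height (or at a valley between fused peaks),
#' and integrates each peak.
#'
#' @param chrom A `chromatogram`.
#' @param baseline A `baseline_estimate` (computed if missing).
#' @param min_snr Minimum height-to-noise ratio (default 10).
#' @param min_width Minimum peak width in minutes (default 0.1).
#' @return Data frame sorted by retention time with columns `analyte`
#'   (`"unassigned"`), `t_r_min`, `area` (mAU*s), `height` (mAU),
#'   `left_min`, `right_min`, `snr`.
#' @export
detect_peaks <- function(chrom, baseline = NULL, min_snr = 10,
                         min_width = 0.1) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (min_snr <= 0) stop("min_snr must be > 0", call. = FALSE)
  if (is.null(baseline)) baseline <- estimate_baseline(chrom)
  y <- chrom$intensity - baseline$baseline
  t <- chrom$time
  n <- length(y)
  sigma <- baseline$noise_sigma
  thr <- if (sigma > 0) min_snr * sigma else
    max(1e-12, 1e-9 * max(abs(y)))

  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y > thr)
  if (!length(cand)) return(empty_peak_table())

  # merge plateau/shoulder maxima closer than min_width: keep the taller
  cand <- cand[order(t[cand])]
  keep <- logical(length(cand))
  i <- 1
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) && t[cand[j + 1]] - t[cand[j]] < min_width) j <- j + 1
    grp <- cand[i:j]
    keep[i:j] <- FALSE
    keep[i + which.max(y[grp]) - 1] <- TRUE
    i <- j + 1
  }
  apex <- cand[keep]

  rows <- lapply(apex, function(k) {
    h <- y[k]
    floor_lvl <- max(1e-3 * h, if (sigma > 0) 0.5 * sigma else 0)
    # walk outward until the corrected signal re-crosses the floor level or
    # a valley (rise after the tail has fallen below 20% of the apex)
    l <- k
    while (l > 1) {
      if (y[l - 1] <= floor_lvl) break
      if (y[l - 1] >= y[l] && y[l] < 0.2 * h) break
      l <- l - 1
    }
    r <- k
    while (r < n) {
      if (y[r + 1] <= floor_lvl) break
      if (y[r + 1] >= y[r] && y[r] < 0.2 * h) break
      r <- r + 1
    }
    area <- trapz_area(t[l:r], y[l:r])
    data.frame(analyte = "unassigned", t_r_min = t[k], area = area,
               height = h, left_min = t[l], right_min = t[r],
               snr = if (sigma > 0) h / sigma else Inf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$right_min - out$left_min >= min_width & out$area > 0, ,
             drop = FALSE]
  rownames(out) <- NULL
  out[order(out$t_r_min), , drop = FALSE]
}

empty_peak_table <- function() {
  data.frame(analyte = character(), t_r_min = numeric(), area = numeric(),
             height = numeric(), left_min = numeric(), right_min = numeric(),
             snr = numeric(), stringsAsFactors = FALSE)
}

# trapezoidal integral over minutes, reported in mAU*s
trapz_area <- function(t, y) {
  if (length(t) < 2) return(0)
  max(sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) * 60, 0)
}

#' Integrate a chromatogram over given bounds
#'
#' Trapezoidal integral of the baseline-corrected signal between two times,
#' clamped at zero, in mAU*s.
#'
#' @param chrom A `chromatogram`.
#' @param baseline A `baseline_estimate` (computed if missing).
#' @param bounds Numeric `c(left, right)` in minutes, inside the trace.
#' @return Area in mAU*s (>= 0).
#' @export
integrate_peak <- function(chrom, baseline = NULL, bounds) {
  stopifnot(inherits(chrom, "chromatogram"), length(bounds) == 2)
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy left < right",
                                   call. = FALSE)
  if (bounds[1] < min(chrom$time) || bounds[2] > max(chrom$time))
    stop("bounds outside the trace", call. = FALSE)
  if (is.null(baseline)) baseline <- estimate_baseline(chrom)
  idx <- chrom$time >= bounds[1] & chrom$time <= bounds[2]
  trapz_area(chrom$time[idx],
             chrom$intensity[idx] - baseline$baseline[idx])
}

#' Detection and quantitation limits from noise and sensitivity
#'
#' Applies the pharmacopoeial signal-to-noise convention: the limit of
#' detection is the on-column mass whose peak height equals 3x the baseline
#' noise and the limit of quantitation the mass at 10x, so LOQ/LOD = 10/3
#' exactly.
#'
#' @param noise_sigma Baseline noise standard deviation (mAU).
#' @param height_per_mass Peak height per on-column mass (mAU/ug); must be
#'   > 0.
#' @return List with `lod_ug` and `loq_ug`.
#' @examples
#' estimate_lod_loq(noise_sigma = 1, height_per_mass = 30)
#' @export
estimate_lod_loq <- function(noise_sigma, height_per_mass) {
  if (height_per_mass <= 0) stop("height_per_mass must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  list(lod_ug = 3 * noise_sigma / height_per_mass,
       loq_ug = 10 * noise_sigma / height_per_mass)
}
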