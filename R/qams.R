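# Core single-marker method: relative correction factors, durability over
# condition grids, relative retention times, peak assignment, single-marker
# quantitation and content calculation.

#' Relative correction factor of an analyte against the internal reference
#'
#' `f = (A_s * C_i) / (A_i * C_s)`: the ratio of the internal reference's
#' response-per-concentration to the analyte's. An analyte ratioed against
#' itself gives exactly 1.
#'
#' @param c_s Internal-reference concentration (ug/mL); > 0.
#' @param a_s Internal-reference peak area (mAU*s); > 0.
#' @param c_i Analyte concentration (ug/mL); > 0.
#' @param a_i Analyte peak area (mAU*s); > 0.
#' @return The dimensionless RCF.
#' @examples
#' compute_rcf(c_s = 2, a_s = 10, c_i = 1, a_i = 10)  # 0.5
#' @export
compute_rcf <- function(c_s, a_s, c_i, a_i) {
  if (any(c(c_s, a_s, c_i, a_i) <= 0))
    stop("all concentrations and areas must be > 0", call. = FALSE)
  (a_s * c_i) / (a_i * c_s)
}

#' Single-marker (QAMS) quantitation of one analyte
#'
#' `C_i = f * C_s * A_i / A_s` -- the algebraic inverse of the RCF
#' definition, so quantifying with an RCF computed from the same run
#' recovers the known concentration exactly.
#'
#' @param a_i Analyte peak area (mAU*s); >= 0.
#' @param a_s Internal-reference peak area (mAU*s); > 0.
#' @param c_s Internal-reference concentration (ug/mL); > 0.
#' @param f Relative correction factor; > 0.
#' @return Analyte concentration in the units of `c_s`.
#' @examples
#' f <- compute_rcf(c_s = 10, a_s = 500, c_i = 2, a_i = 800)
#' quantify_qams(a_i = 800, a_s = 500, c_s = 10, f = f)  # 2
#' @export
quantify_qams <- function(a_i, a_s, c_s, f) {
  if (a_s <= 0) stop("internal-reference peak area must be > 0",
                     call. = FALSE)
  if (c_s <= 0 || f <= 0) stop("c_s and f must be > 0", call. = FALSE)
  if (a_i < 0) stop("a_i must be >= 0", call. = FALSE)
  f * c_s * a_i / a_s
}

#' Relative retention time
#'
#' Ratio of the analyte's retention time to the internal reference's.
#' Invariant under any common rescaling of both times (e.g. a flow-rate
#' change), which is what makes it usable for peak identification across
#' instruments and columns.
#'
#' @param t_r_x Analyte retention time (min); > 0.
#' @param t_r_s Internal-reference retention time (min); > 0.
#' @return Dimensionless RRT.
#' @examples
#' compute_rrt(26, 38)
#' @export
compute_rrt <- function(t_r_x, t_r_s) {
  if (t_r_x <= 0 || t_r_s <= 0)
    stop("retention times must be > 0", call. = FALSE)
  t_r_x / t_r_s
}

#' Assign detected peaks to analytes by relative retention time
#'
#' Locates the internal-reference peak with the configured strategy,
#' computes every peak's RRT against it, and matches each analyte to the
#' unassigned peak whose RRT is nearest its expected value within the
#' tolerance. Competing claims are resolved globally by smallest
#' |RRT - expected|; analytes with no admissible peak are reported missing.
#'
#' @param peaks Peak table (data frame with `t_r_min`, `area`, optionally
#'   `analyte` labels); must be non-empty.
#' @param analytes Data frame with `name`, `expected_rrt` and `is_ir`
#'   (exactly one `TRUE`), e.g. `method_preset("nonivamide")$analytes`.
#' @param rrt_tolerance Relative tolerance on |RRT - expected| (default
#'   0.05).
#' @param ir_locator One of `"nearest-time"` (peak closest to `ir_time`),
#'   `"tallest-peak"`, `"labeled"` (peak table carries the IR label), or
#'   `"external-time"` (the IR was injected separately; use `ir_time`
#'   directly as the reference retention time without requiring an IR peak
#'   in this run).
#' @param ir_time Expected IR retention time in minutes (required by the
#'   `nearest-time` and `external-time` strategies).
#' @return List with `assignments` (data frame `analyte`, `t_r_min`, `area`,
#'   `rrt`, `peak_index`), `missing` (character vector) and `ir_time`.
#' @export
assign_peaks <- function(peaks, analytes, rrt_tolerance = 0.05,
                         ir_locator = c("nearest-time", "tallest-peak",
                                        "labeled", "external-time"),
                         ir_time = NULL) {
  ir_locator <- match.arg(ir_locator)
  stopifnot(is.data.frame(peaks), is.data.frame(analytes))
  if (!nrow(peaks)) stop("peak table is empty", call. = FALSE)
  if (sum(analytes$is_ir) != 1)
    stop("exactly one analyte must be the internal reference", call. = FALSE)
  ir_name <- analytes$name[analytes$is_ir]

  t_s <- switch(ir_locator,
    "nearest-time" = {
      if (is.null(ir_time))
        stop("ir_time is required for the nearest-time strategy",
             call. = FALSE)
      peaks$t_r_min[which.min(abs(peaks$t_r_min - ir_time))]
    },
    "tallest-peak" = peaks$t_r_min[which.max(peaks$height)],
    "labeled" = {
      hit <- which(peaks$analyte == ir_name)
      if (!length(hit))
        stop(sprintf("internal reference '%s' not found in labeled peak table",
                     ir_name), call. = FALSE)
      peaks$t_r_min[hit[1]]
    },
    "external-time" = {
      if (is.null(ir_time))
        stop("ir_time is required for the external-time strategy",
             call. = FALSE)
      ir_time
    })
  if (is.null(t_s) || !is.finite(t_s) || t_s <= 0)
    stop("internal reference could not be located", call. = FALSE)

  rrt <- peaks$t_r_min / t_s
  targets <- analytes[!analytes$is_ir | ir_locator != "external-time", ,
                      drop = FALSE]
  # all admissible (analyte, peak) pairs ranked by |RRT - expected|
  cand <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    d <- abs(rrt - targets$expected_rrt[i])
    ok <- d <= rrt_tolerance * targets$expected_rrt[i]
    if (!any(ok)) return(NULL)
    data.frame(analyte = targets$name[i], peak = which(ok), dist = d[ok],
               stringsAsFactors = FALSE)
  }))
  assigned <- data.frame(analyte = character(), t_r_min = numeric(),
                         area = numeric(), rrt = numeric(),
                         peak_index = integer(), stringsAsFactors = FALSE)
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), , drop = FALSE]
    used_pk <- integer(0)
    used_an <- character(0)
    for (k in seq_len(nrow(cand))) {
      if (cand$peak[k] %in% used_pk || cand$analyte[k] %in% used_an) next
      p <- cand$peak[k]
      assigned <- rbind(assigned, data.frame(
        analyte = cand$analyte[k], t_r_min = peaks$t_r_min[p],
        area = peaks$area[p], rrt = rrt[p], peak_index = p,
        stringsAsFactors = FALSE))
      used_pk <- c(used_pk, p)
      used_an <- c(used_an, cand$analyte[k])
    }
  }
  missing <- setdiff(targets$name, assigned$analyte)
  list(assignments = assigned[order(assigned$t_r_min), , drop = FALSE],
       missing = missing, ir_time = t_s)
}

#' Assess RCF durability over a grid of instrument conditions
#'
#' Computes the relative correction factor of every analyte under each run
#' of a condition grid and summarizes its mean and relative standard
#' deviation. A common per-run gain (detector sensitivity, injection
#' deviation) cancels in the area ratio, which is the mechanism that makes
#' RCFs durable; analytes whose RSD exceeds the durability threshold are
#' flagged.
#'
#' @param runs List of runs, each a list with `condition` (a
#'   [condition_set()]), `peaks` (data frame with `analyte` and `area`) and
#'   `conc` (named vector of known concentrations, ug/mL).
#' @param ir_name Internal-reference analyte label; must be present with a
#'   positive area in every run.
#' @param durability_threshold Flagging bound in % RSD (default 3).
#' @return Object of class `rcf_estimate`: data frame with one row per
#'   analyte (`analyte`, `ir_name`, `mean_f`, `rsd_percent`, `n_conditions`,
#'   `durable`), with the per-condition factor matrix in
#'   `attr(, "per_condition")`.
#' @export
assess_rcf_durability <- function(runs, ir_name,
                                  durability_threshold = 3.0) {
  stopifnot(is.list(runs), length(runs) >= 1)
  per <- list()
  for (k in seq_along(runs)) {
    run <- runs[[k]]
    pk <- run$peaks
    conc <- run$conc
    hit <- which(pk$analyte == ir_name)
    if (!length(hit) || is.na(conc[ir_name]))
      stop(sprintf("internal reference '%s' missing from run %d",
                   ir_name, k), call. = FALSE)
    a_s <- pk$area[hit[1]]
    c_s <- unname(conc[ir_name])
    others <- setdiff(intersect(pk$analyte, names(conc)), ir_name)
    f <- vapply(others, function(a) {
      compute_rcf(c_s = c_s, a_s = a_s, c_i = unname(conc[a]),
                  a_i = pk$area[which(pk$analyte == a)[1]])
    }, numeric(1))
    per[[k]] <- f
  }
  analyte_names <- sort(unique(unlist(lapply(per, names))))
  mat <- do.call(rbind, lapply(per, function(f) f[analyte_names]))
  colnames(mat) <- analyte_names
  rownames(mat) <- vapply(runs, function(r) condition_key(r$condition),
                          character(1))
  summ <- data.frame(
    analyte = analyte_names,
    ir_name = ir_name,
    mean_f = colMeans(mat, na.rm = TRUE),
    rsd_percent = apply(mat, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else 100 * stats::sd(v) / mean(v)
    }),
    n_conditions = apply(mat, 2, function(v) sum(!is.na(v))),
    stringsAsFactors = FALSE)
  summ$durable <- summ$rsd_percent <= durability_threshold
  rownames(summ) <- NULL
  structure(summ, per_condition = mat, class = c("rcf_estimate",
                                                 "data.frame"))
}

#' @export
print.rcf_estimate <- function(x, ...) {
  cat(sprintf("<rcf_estimate> IR = %s over %d condition(s)\n",
              x$ir_name[1], max(x$n_conditions)))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Mass content of an analyte in the original sample
#'
#' `W_i = C_i * V * K / M_m`, the dilution-and-mass back-calculation from
#' extract concentration to content per gram of sample.
#'
#' @param c_i Extract concentration in mg/mL; >= 0.
#' @param v Extract volume in mL; > 0.
#' @param k Dilution factor; >= 1 (default 1).
#' @param m_m Sample mass in g; > 0.
#' @return Content in mg per g of sample.
#' @examples
#' compute_content(c_i = 0.045, v = 25, k = 1, m_m = 0.025)  # 45 mg/g
#' @export
compute_content <- function(c_i, v, k = 1, m_m) {
  if (m_m <= 0) stop("sample mass must be > 0", call. = FALSE)
  if (v <= 0) stop("extract volume must be > 0", call. = FALSE)
  if (k < 1) stop("dilution factor must be >= 1", call. = FALSE)
  if (c_i < 0) stop("concentration must be >= 0", call. = FALSE)
  c_i * v * k / m_m
}
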