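# Method-equivalence statistics (SMD) and validation summaries.

#' Standardized mean difference between two content determinations
#'
#' `SMD% = |w_ref - w_alt| / w_ref * 100`. The denominator is the first
#' argument, so the statistic is deliberately not symmetric in its
#' arguments: the reference method defines the scale.
#'
#' @param w_ref Reference-method content (mg/g); > 0.
#' @param w_alt Alternative-method content (mg/g); >= 0.
#' @return SMD in percent (>= 0).
#' @examples
#' compute_smd(20, 19)  # 5
#' @export
compute_smd <- function(w_ref, w_alt) {
  if (any(w_ref <= 0))
    stop("reference content must be > 0 (undefined denominator)",
         call. = FALSE)
  if (any(w_alt < 0)) stop("alternative content must be >= 0", call. = FALSE)
  abs(w_ref - w_alt) / w_ref * 100
}

#' Compare two sets of quantitation results by SMD
#'
#' Joins two result tables on sample x analyte keys, averages replicates
#' within each key, and computes the per-key SMD with the first set as
#' reference. Per-replicate SMDs and the SMD of the summed (total
#' alkylamide) content per sample are also reported.
#'
#' @param results_a,results_b Data frames with columns `sample`, `analyte`,
#'   `w_i` (mg/g) and optionally `replicate`; `results_a` is the reference
#'   method.
#' @param threshold Acceptance bound in % (strictly less than; default 5).
#' @return Object of class `comparison_report`: list with `per_analyte`
#'   (data frame `sample`, `analyte`, `w_ref`, `w_alt`, `smd`, `pass`),
#'   `per_replicate` (same keys plus `replicate`, when both inputs carry
#'   replicates), `total` (per-sample summed contents), `overall_pass`,
#'   `max_smd`, `threshold`.
#' @export
compare_methods <- function(results_a, results_b, threshold = 5.0) {
  check_results_df(results_a, "results_a")
  check_results_df(results_b, "results_b")
  ka <- paste(results_a$sample, results_a$analyte, sep = "\r")
  kb <- paste(results_b$sample, results_b$analyte, sep = "\r")
  only_a <- setdiff(unique(ka), unique(kb))
  only_b <- setdiff(unique(kb), unique(ka))
  if (length(only_a) || length(only_b))
    stop("unmatched sample/analyte keys: ",
         paste(gsub("\r", "/", c(only_a, only_b)), collapse = ", "),
         call. = FALSE)

  mean_a <- stats::aggregate(w_i ~ sample + analyte, results_a, mean)
  mean_b <- stats::aggregate(w_i ~ sample + analyte, results_b, mean)
  per <- merge(mean_a, mean_b, by = c("sample", "analyte"),
               suffixes = c("_ref", "_alt"))
  names(per)[names(per) == "w_i_ref"] <- "w_ref"
  names(per)[names(per) == "w_i_alt"] <- "w_alt"
  per$smd <- compute_smd(per$w_ref, per$w_alt)
  per$pass <- per$smd < threshold
  per <- per[order(per$sample, per$analyte), , drop = FALSE]
  rownames(per) <- NULL

  per_rep <- NULL
  if ("replicate" %in% names(results_a) && "replicate" %in% names(results_b)) {
    rep_ab <- merge(results_a[c("sample", "analyte", "replicate", "w_i")],
                    results_b[c("sample", "analyte", "replicate", "w_i")],
                    by = c("sample", "analyte", "replicate"),
                    suffixes = c("_ref", "_alt"))
    if (nrow(rep_ab)) {
      rep_ab$smd <- compute_smd(rep_ab$w_i_ref, rep_ab$w_i_alt)
      per_rep <- rep_ab
    }
  }

  tot_a <- stats::aggregate(w_i ~ sample, mean_a, sum)
  tot_b <- stats::aggregate(w_i ~ sample, mean_b, sum)
  total <- merge(tot_a, tot_b, by = "sample", suffixes = c("_ref", "_alt"))
  names(total)[names(total) == "w_i_ref"] <- "w_ref"
  names(total)[names(total) == "w_i_alt"] <- "w_alt"
  total$smd <- compute_smd(total$w_ref, total$w_alt)
  total$pass <- total$smd < threshold

  structure(
    list(per_analyte = per, per_replicate = per_rep, total = total,
         overall_pass = all(per$pass), max_smd = max(per$smd),
         threshold = threshold),
    class = "comparison_report")
}

check_results_df <- function(df, what) {
  if (!is.data.frame(df) || !nrow(df))
    stop(what, " must be a non-empty data frame", call. = FALSE)
  need <- c("sample", "analyte", "w_i")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %d sample x analyte entries, max SMD = %.3f%% (threshold %.1f%%): %s\n",
    nrow(x$per_analyte), x$max_smd, x$threshold,
    if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Precision / stability / repeatability / recovery summary
#'
#' Computes the relative standard deviation of replicate determinations per
#' group, and spike recoveries when spiked results and added amounts are
#' supplied.
#'
#' @param replicate_results Named list of numeric vectors (>= 2 values
#'   each): replicate determinations per group (e.g. per analyte).
#' @param spiked Optional named list per group:
#'   `list(base = , spiked = , added = )` -- mean unspiked result, replicate
#'   spiked results, and the amount added (all in the same unit).
#' @return Object of class `validation_summary`: data frame with `group`,
#'   `n`, `mean`, `rsd_percent`, and when spikes are given
#'   `recovery_percent`, `recovery_rsd_percent`.
#' @examples
#' summarize_validation(list(HaSS = c(44.8, 45.1, 45.3)))
#' @export
summarize_validation <- function(replicate_results, spiked = NULL) {
  stopifnot(is.list(replicate_results), length(replicate_results) >= 1)
  rows <- lapply(names(replicate_results), function(g) {
    v <- replicate_results[[g]]
    if (length(v) < 2)
      stop(sprintf("group '%s' has fewer than 2 replicates", g),
           call. = FALSE)
    out <- data.frame(group = g, n = length(v), mean = mean(v),
                      rsd_percent = 100 * stats::sd(v) / mean(v),
                      stringsAsFactors = FALSE)
    if (!is.null(spiked) && !is.null(spiked[[g]])) {
      sp <- spiked[[g]]
      rec <- 100 * (sp$spiked - sp$base) / sp$added
      out$recovery_percent <- mean(rec)
      out$recovery_rsd_percent <- if (length(rec) > 1)
        100 * stats::sd(rec) / mean(rec) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("validation_summary", "data.frame"))
}

#' Batch summary of quantitation results
#'
#' Long-format roll-up of a batch: per analyte and method, the range and
#' mean of per-sample contents, with the per-sample replicate standard
#' deviation.
#'
#' @param results Data frame with `sample`, `analyte`, `w_i`, and optionally
#'   `method` and `replicate`.
#' @return List with `per_sample` (sample x analyte x method means +/- sd
#'   across replicates) and `summary` (per analyte x method: `min`, `max`,
#'   `mean`, `sd` across samples).
#' @export
batch_report <- function(results) {
  check_results_df(results, "results")
  if (!"method" %in% names(results)) results$method <- "unspecified"
  agg <- stats::aggregate(w_i ~ sample + analyte + method, results, mean)
  names(agg)[names(agg) == "w_i"] <- "w_mean"
  sdv <- stats::aggregate(w_i ~ sample + analyte + method, results,
                          function(v) if (length(v) > 1) stats::sd(v) else 0)
  names(sdv)[names(sdv) == "w_i"] <- "w_sd"
  per_sample <- merge(agg, sdv, by = c("sample", "analyte", "method"))
  per_sample <- per_sample[order(per_sample$method, per_sample$analyte,
                                 per_sample$sample), , drop = FALSE]
  rownames(per_sample) <- NULL
  summ <- do.call(rbind, lapply(
    split(per_sample, per_sample[c("analyte", "method")], drop = TRUE),
    function(d) data.frame(
      analyte = d$analyte[1], method = d$method[1],
      n_samples = nrow(d), min = min(d$w_mean), max = max(d$w_mean),
      mean = mean(d$w_mean), sd = if (nrow(d) > 1) stats::sd(d$w_mean) else 0,
      stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(per_sample = per_sample, summary = summ)
}
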