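# Single-marker core: RCF, RRT, peak assignment, quantitation, content.

test_that("RCF and single-marker quantitation are exact inverses", {
  set.seed(314)
  for (k in 1:1000) {
    v <- exp(runif(4, -4, 4))  # c_s, a_s, c_i, a_i, all positive
    f <- compute_rcf(v[1], v[2], v[3], v[4])
    expect_equal(quantify_qams(a_i = v[4], a_s = v[2], c_s = v[1], f = f),
                 v[3], tolerance = 1e-12)
  }
})

test_that("RCF arithmetic matches hand-computed cases", {
  expect_equal(compute_rcf(c_s = 1, a_s = 10, c_i = 1, a_i = 10), 1)
  expect_equal(compute_rcf(c_s = 2, a_s = 10, c_i = 1, a_i = 10), 0.5)
  # equal-mass areas proportional to the calibration slopes
  expect_equal(compute_rcf(1, 1.78e7, 1, 1.09e7), 1.78 / 1.09)
  expect_error(compute_rcf(0, 1, 1, 1), "> 0")
})

test_that("single-marker quantitation follows C_i = f C_s A_i / A_s", {
  expect_equal(quantify_qams(a_i = 500, a_s = 500, c_s = 7, f = 1), 7)
  expect_equal(quantify_qams(a_i = 2, a_s = 1, c_s = 10, f = 0.0513),
               1.026)
  expect_error(quantify_qams(a_i = 1, a_s = 0, c_s = 1, f = 1),
               "reference peak")
})

test_that("relative retention times are plain ratios, invariant to flow", {
  expect_equal(compute_rrt(38, 38), 1)
  expect_equal(compute_rrt(26, 38), 26 / 38)
  expect_equal(compute_rrt(26 * 1.43, 38 * 1.43), 26 / 38)
  expect_error(compute_rrt(-1, 38), "> 0")
})

test_that("all four sanshools are assigned from the five-peak standard", {
  method <- method_preset("nonivamide")
  peaks <- data.frame(
    analyte = "unassigned",
    t_r_min = c(24, 26, 28, 38, 42),
    area = c(2e6, 8e6, 1e6, 2e6, 1.5e6),
    height = c(9e4, 4e5, 5e4, 8e4, 6e4))
  asg <- assign_peaks(peaks, method$analytes, ir_locator = "nearest-time",
                      ir_time = 38)
  got <- setNames(asg$assignments$t_r_min, asg$assignments$analyte)
  expect_equal(got[["HeSS"]], 24)
  expect_equal(got[["HaSS"]], 26)
  expect_equal(got[["HbSS"]], 28)
  expect_equal(got[["Nonivamide"]], 38)
  expect_equal(got[["HgSS"]], 42)
  expect_length(asg$missing, 0)
})

test_that("a missing analyte is reported missing, not an error", {
  method <- method_preset("nonivamide")
  peaks <- data.frame(analyte = "unassigned",
                      t_r_min = c(24, 26, 28, 38),
                      area = c(2e6, 8e6, 1e6, 2e6),
                      height = c(9e4, 4e5, 5e4, 8e4))
  asg <- assign_peaks(peaks, method$analytes, ir_time = 38)
  expect_equal(asg$missing, "HgSS")
  expect_equal(nrow(asg$assignments), 4)
})

test_that("assignment is invariant under a common retention-time scaling", {
  method <- method_preset("nonivamide")
  base <- data.frame(analyte = "unassigned",
                     t_r_min = c(24, 26, 28, 38, 42),
                     area = 1:5 * 1e6, height = 1:5 * 1e4)
  scaled <- transform(base, t_r_min = t_r_min * 1 / 0.7)
  a1 <- assign_peaks(base, method$analytes, ir_time = 38)
  a2 <- assign_peaks(scaled, method$analytes, ir_time = 38 / 0.7)
  expect_equal(a1$assignments$analyte[order(a1$assignments$peak_index)],
               a2$assignments$analyte[order(a2$assignments$peak_index)])
})

test_that("competing claims go to the closer analyte; the loser is missing", {
  analytes <- data.frame(name = c("IR", "A", "B"),
                         expected_rrt = c(1, 0.50, 0.52),
                         rcf = c(1, 1, 1),
                         is_ir = c(TRUE, FALSE, FALSE))
  peaks <- data.frame(analyte = "unassigned", t_r_min = c(5.05, 10),
                      area = c(1, 1), height = c(1, 2))
  asg <- assign_peaks(peaks, analytes, rrt_tolerance = 0.05,
                      ir_locator = "tallest-peak")
  expect_equal(asg$assignments$analyte[asg$assignments$t_r_min == 5.05], "A")
  expect_true("B" %in% asg$missing)
})

test_that("durability: a shared per-run gain cancels exactly in the RCF", {
  conc <- c(Nonivamide = 24.18, HaSS = 9.67, HbSS = 0.54)
  base_areas <- c(Nonivamide = 1e6, HaSS = 3.3e7, HbSS = 4.1e5)
  runs <- lapply(1:8, function(k) {
    gain <- exp(0.4 * sin(k))  # arbitrary but shared within the run
    list(condition = condition_set(flow_rate = 0.7 + 0.1 * k),
         peaks = data.frame(analyte = names(base_areas),
                            area = unname(base_areas) * gain),
         conc = conc)
  })
  est <- assess_rcf_durability(runs, "Nonivamide")
  expect_equal(est$rsd_percent, c(0, 0), tolerance = 1e-10)
  expect_true(all(est$durable))
})

test_that("1% independent area noise propagates to ~1.4% RCF RSD", {
  conc <- c(Nonivamide = 24.18, HaSS = 9.67, HbSS = 0.54, HeSS = 0.27)
  base_areas <- c(Nonivamide = 1e6, HaSS = 3.3e7, HbSS = 4.1e5,
                  HeSS = 1.7e5)
  set.seed(88)
  mean_rsds <- replicate(8, {
    runs <- lapply(1:20, function(k) list(
      condition = condition_set(column_temp = 20 + k),
      peaks = data.frame(
        analyte = names(base_areas),
        area = unname(base_areas) * (1 + rnorm(4, 0, 0.01))),
      conc = conc))
    mean(assess_rcf_durability(runs, "Nonivamide")$rsd_percent)
  })
  expect_gt(mean(mean_rsds), sqrt(2) - 0.5)
  expect_lt(mean(mean_rsds), sqrt(2) + 0.5)
})

test_that("a single condition gives zero RSD and that run's factor", {
  runs <- list(list(condition = condition_set(),
                    peaks = data.frame(analyte = c("S", "A"),
                                       area = c(100, 400)),
                    conc = c(S = 2, A = 4)))
  est <- assess_rcf_durability(runs, "S")
  expect_equal(est$rsd_percent, 0)
  expect_equal(est$mean_f, compute_rcf(2, 100, 4, 400))
  expect_error(assess_rcf_durability(runs, "Missing"), "missing from run 1")
})

test_that("content back-calculation follows W = C V K / M", {
  expect_equal(compute_content(c_i = 0.045, v = 25, k = 1, m_m = 0.025), 45)
  expect_equal(compute_content(0, 25, 1, 0.025), 0)
  expect_equal(compute_content(0.045, 25, 2, 0.025),
               2 * compute_content(0.045, 25, 1, 0.025))
  expect_error(compute_content(0.045, 25, 1, 0), "mass")
})
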