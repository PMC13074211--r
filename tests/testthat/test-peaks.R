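# Baseline estimation, detection, integration and detection limits.

test_that("robust noise estimate recovers the true sigma on a pure-noise trace", {
  ch <- simulate_chromatogram(list(), duration = 49.95, sampling_rate = 20,
                              noise = noise_spec(baseline_sigma = 1,
                                                 area_rsd = 0, seed = 3))
  expect_equal(length(ch$time), 1000)
  bl <- estimate_baseline(ch)
  expect_gt(bl$noise_sigma, 0.8)
  expect_lt(bl$noise_sigma, 1.2)
})

test_that("a constant trace yields that constant baseline and zero noise", {
  ch <- structure(list(time = seq(0, 50, by = 0.05),
                       intensity = rep(5, 1001),
                       condition = condition_set(), wavelength = 285,
                       sampling_rate = 20), class = "chromatogram")
  bl <- estimate_baseline(ch)
  expect_equal(bl$baseline, rep(5, 1001))
  expect_equal(bl$noise_sigma, 0)
})

test_that("the baseline stays near zero underneath an isolated peak", {
  ch <- gaussian_trace(area = 1e5, sigma = 0.3, sampling_rate = 20,
                       baseline_sigma = 10, seed = 11)
  bl <- estimate_baseline(ch)
  under <- abs(ch$time - 25) < 3 * 0.3
  expect_lt(max(abs(bl$baseline[under])), 3 * bl$noise_sigma)
})

test_that("the five-compound standard yields exactly five peaks at the nominal times", {
  resp <- response_models()
  ser <- simulate_standard_series(resp, standard_levels(resp)[4],
                                  noise = noise_spec(seed = 21))
  pk <- detect_peaks(ser$chromatograms[[1]])
  expect_equal(nrow(pk), 5)
  expect_equal(pk$t_r_min, c(24, 26, 28, 38, 42), tolerance = 0.1 / 24)
})

test_that("a blank trace yields an empty peak table", {
  ch <- simulate_chromatogram(list(), noise = noise_spec(seed = 4))
  pk <- detect_peaks(ch)
  expect_equal(nrow(pk), 0)
})

test_that("peaks below the S/N threshold are not reported", {
  sigma_n <- 10
  tall <- peak_shape_spec("tall", 20, 50 * sigma_n * 0.3 * sqrt(2 * pi) * 60,
                          0.3)
  short <- peak_shape_spec("short", 35, 5 * sigma_n * 0.3 * sqrt(2 * pi) * 60,
                           0.3)
  ch <- simulate_chromatogram(list(tall, short),
                              noise = noise_spec(baseline_sigma = sigma_n,
                                                 seed = 8))
  pk <- detect_peaks(ch, min_snr = 10)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$t_r_min, 20, tolerance = 0.01)
})

test_that("raising min_snr never increases the number of detected peaks", {
  resp <- response_models()
  ser <- simulate_standard_series(resp, standard_levels(resp)[2],
                                  noise = noise_spec(seed = 13))
  ch <- ser$chromatograms[[1]]
  bl <- estimate_baseline(ch)
  counts <- vapply(c(3, 10, 30, 100, 1000),
                   function(s) nrow(detect_peaks(ch, bl, min_snr = s)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("integration recovers spec areas and Gaussian half-window fractions", {
  ch <- gaussian_trace(area = 100, sigma = 1.0, sampling_rate = 200)
  bl <- estimate_baseline(ch)
  full <- integrate_peak(ch, bl, c(25 - 5, 25 + 5))
  expect_rel_equal(full, 100, 0.005)

  # central +/- 0.6745 sigma holds 50% of a Gaussian's area
  half <- integrate_peak(ch, bl, c(25 - 0.6745, 25 + 0.6745))
  expect_rel_equal(half, 100 * (2 * pnorm(0.6745) - 1), 0.01)

  flat <- integrate_peak(ch, bl, c(5, 10))
  expect_lt(abs(flat), 1e-6)

  expect_error(integrate_peak(ch, bl, c(30, 20)), "left < right")
  expect_error(integrate_peak(ch, bl, c(-5, 10)), "outside")
})

test_that("detection plus integration round-trips noiseless peak areas within 1%", {
  resp <- response_models()
  ser <- simulate_standard_series(resp, standard_levels(resp)[4],
                                  noise = quiet_noise())
  pk <- detect_peaks(ser$chromatograms[[1]])
  man <- ser$manifest[order(match(ser$manifest$analyte,
                                  c("HeSS", "HaSS", "HbSS", "Nonivamide",
                                    "HgSS"))), ]
  expect_equal(nrow(pk), 5)
  expect_true(all(abs(pk$area - man$area) / man$area < 0.01))
})

test_that("detection limits follow the 3:1 and 10:1 signal-to-noise rules", {
  lims <- estimate_lod_loq(noise_sigma = 1, height_per_mass = 30)
  expect_equal(lims$lod_ug, 0.1)
  expect_equal(lims$loq_ug, 1 / 3)
  expect_equal(lims$loq_ug / lims$lod_ug, 10 / 3)

  zero <- estimate_lod_loq(noise_sigma = 0, height_per_mass = 30)
  expect_equal(zero$lod_ug, 0)
  expect_equal(zero$loq_ug, 0)
  expect_error(estimate_lod_loq(1, 0), "height_per_mass")
})

test_that("the default noise floor puts the alpha-sanshool LOD at the sub-ng scale", {
  m <- response_models()$HaSS
  height_per_mass <- m$slope / 60 / (m$sigma * sqrt(2 * pi))
  lims <- estimate_lod_loq(noise_spec()$baseline_sigma, height_per_mass)
  expect_rel_equal(lims$lod_ug * 1e3, 0.068, 0.2)
})
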