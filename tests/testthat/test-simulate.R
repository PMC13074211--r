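# Synthetic chromatogram generator: area conservation, determinism,
# response-model scaling, condition transforms.

test_that("noiseless Gaussian peak conserves its specified area", {
  ch <- gaussian_trace(area = 100, sigma = 0.5, sampling_rate = 200)
  idx <- abs(ch$time - 25) <= 5 * 0.5
  area <- sum(diff(ch$time[idx]) *
                (head(ch$intensity[idx], -1) + tail(ch$intensity[idx], -1)) /
                2) * 60
  expect_rel_equal(area, 100, 0.005)
})

test_that("tailed (EMG) peaks also conserve area and shift the apex late", {
  ch_g <- gaussian_trace(area = 500, sigma = 0.3, sampling_rate = 200)
  ch_e <- simulate_chromatogram(
    list(peak_shape_spec("X", t_r = 25, area = 500, sigma = 0.3,
                         tau = 0.2)),
    duration = 50, sampling_rate = 200, noise = quiet_noise())
  a <- function(ch) sum(diff(ch$time) * (head(ch$intensity, -1) +
                                           tail(ch$intensity, -1)) / 2) * 60
  expect_rel_equal(a(ch_e), 500, 0.005)
  expect_gt(ch_e$time[which.max(ch_e$intensity)],
            ch_g$time[which.max(ch_g$intensity)])
})

test_that("the five-compound standard produces maxima at the nominal times", {
  resp <- response_models()
  ser <- simulate_standard_series(resp, standard_levels(resp)[5],
                                  noise = quiet_noise())
  ch <- ser$chromatograms[[1]]
  y <- ch$intensity
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  apex <- ch$time[is_max & y > 0.01 * max(y)]
  expect_length(apex, 5)
  step <- 1 / ch$sampling_rate
  for (tr in c(24, 26, 28, 38, 42))
    expect_true(any(abs(apex - tr) <= step + 1e-9))
})

test_that("identical spec and seed reproduce bit-identical traces", {
  ns <- noise_spec(baseline_sigma = 50, seed = 99)
  pk <- list(peak_shape_spec("X", 10, 1e4, 0.2))
  ch1 <- simulate_chromatogram(pk, noise = ns)
  ch2 <- simulate_chromatogram(pk, noise = ns)
  expect_identical(ch1$intensity, ch2$intensity)
  ch3 <- simulate_chromatogram(pk, noise = noise_spec(baseline_sigma = 50,
                                                      seed = 100))
  expect_false(identical(ch1$intensity, ch3$intensity))
})

test_that("overlapping peaks warn and out-of-window peaks error", {
  close_pair <- list(peak_shape_spec("A", 10, 1e3, 0.3),
                     peak_shape_spec("B", 10.5, 1e3, 0.3))
  expect_warning(simulate_chromatogram(close_pair, noise = quiet_noise()),
                 "poorly resolved")
  expect_error(simulate_chromatogram(
    list(peak_shape_spec("A", 60, 1e3, 0.3)), duration = 50,
    noise = quiet_noise()), "outside")
  expect_error(simulate_chromatogram(list(), duration = -1,
                                     noise = quiet_noise()), "duration")
})

test_that("standard series areas follow the affine response model", {
  m <- response_model("HaSS", slope = 1.78e7, intercept = -8686.99,
                      wavelength_factor = c("285" = 1), t_r = 26)
  ser <- simulate_standard_series(list(HaSS = m), list(c(HaSS = 1.0)),
                                  noise = quiet_noise(),
                                  return_traces = FALSE)
  expect_equal(ser$manifest$area, 1.78e7 * 1.0 - 8686.99)

  # doubling the injection doubles on-column mass and area up to intercept
  cond20 <- condition_set(injection_volume = 20)
  ser20 <- simulate_standard_series(list(HaSS = m), list(c(HaSS = 1.0)),
                                    condition = cond20,
                                    noise = quiet_noise(),
                                    return_traces = FALSE)
  expect_equal(ser20$manifest$mass_ug, 2.0)
  expect_equal(ser20$manifest$area, 1.78e7 * 2.0 - 8686.99)

  # zero mass: no peak, clamped area
  ser0 <- simulate_standard_series(list(HaSS = m), list(c(HaSS = 0)),
                                   noise = quiet_noise(),
                                   return_traces = FALSE)
  expect_equal(nrow(ser0$peak_tables[[1]]), 0)
  expect_equal(ser0$manifest$area, 0)
})

test_that("sample batch inverts the content equation into concentrations", {
  out <- simulate_sample_batch(c(HaSS = 45.0), sample_mass = 0.025,
                               extract_volume = 25, dilution_k = 1,
                               noise = quiet_noise(),
                               responses = proportional_models())
  # 45 mg/g * 0.025 g / 25 mL = 0.045 mg/mL = 45 ug/mL
  expect_equal(out$manifest$conc_ug_ml, 45.0)
  expect_equal(out$manifest$mass_ug, 0.45)

  expect_error(simulate_sample_batch(c(Unknown = 1), noise = quiet_noise()),
               "no response model")

  # blank sample: no peaks in any replicate
  blank <- simulate_sample_batch(c(HaSS = 0), noise = quiet_noise(),
                                 responses = proportional_models())
  expect_equal(nrow(blank$peak_tables[[1]]), 0)
})

test_that("replicates differ in noise but share one manifest truth", {
  out <- simulate_sample_batch(c(HaSS = 30), n_replicates = 3,
                               noise = noise_spec(area_rsd = 0.05,
                                                  seed = 7),
                               responses = proportional_models())
  areas <- vapply(out$peak_tables, function(t) t$area[1], numeric(1))
  expect_length(unique(areas), 3)
  expect_equal(nrow(out$manifest), 1)
})

test_that("condition perturbations transform retention and area as configured", {
  pks <- list(peak_shape_spec("A", 26, 1000, 0.15),
              peak_shape_spec("B", 38, 500, 0.18))
  base <- condition_set()

  halved <- apply_condition_perturbation(
    pks, base, condition_set(flow_rate = 0.5))
  expect_equal(vapply(halved, `[[`, numeric(1), "t_r"), c(52, 76))

  doubled <- apply_condition_perturbation(
    pks, base, condition_set(injection_volume = 20))
  areas <- vapply(doubled, `[[`, numeric(1), "area")
  expect_equal(areas, c(2000, 1000))
  expect_equal(areas[1] / areas[2], 1000 / 500)  # ratio preserved

  ident <- apply_condition_perturbation(pks, base, base)
  expect_equal(vapply(ident, `[[`, numeric(1), "t_r"), c(26, 38))
  expect_equal(vapply(ident, `[[`, numeric(1), "area"), c(1000, 500))

  bad <- base
  bad$flow_rate <- -1
  expect_error(apply_condition_perturbation(pks, base, bad), "flow_rate")
})
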