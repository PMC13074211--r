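# Shared fixtures: noiseless specs, reference models, small worlds.

quiet_noise <- function(seed = 1) {
  noise_spec(baseline_sigma = 0, drift_slope = 0, area_rsd = 0, seed = seed)
}

# a single isolated Gaussian peak trace on a zero baseline
gaussian_trace <- function(area = 100, t_r = 25, sigma = 0.5,
                           sampling_rate = 200, duration = 50,
                           baseline_sigma = 0, seed = 1) {
  simulate_chromatogram(
    list(peak_shape_spec("X", t_r = t_r, area = area, sigma = sigma)),
    duration = duration, sampling_rate = sampling_rate,
    noise = noise_spec(baseline_sigma = baseline_sigma, area_rsd = 0,
                       seed = seed))
}

# tiny proportional-response world: zero intercepts, unit channel factors
proportional_models <- function() {
  tab <- alkylamide_table()
  out <- lapply(seq_len(nrow(tab)), function(i)
    response_model(tab$analyte[i],
                   slope = tab$slope[i] / 0.01, intercept = 0,
                   wavelength_factor = c("270" = 1, "285" = 1),
                   t_r = tab$t_r_min[i],
                   sigma = 0.10 + 0.002 * tab$t_r_min[i]))
  stats::setNames(out, tab$analyte)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / abs(expected), rel_tol)
}
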