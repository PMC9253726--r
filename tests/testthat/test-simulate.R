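test_that("noiseless trace has cosine peaks at the programmed spacing", {
  tr <- clean_trace(tau_h = 24, offset = 2)
  expect_equal(tr$ll_start_h, 39)
  # signal maxima occur where theta is a multiple of 2 pi
  exp_peaks <- analytic_peaks(24, 2)
  expect_equal(exp_peaks[1], 2)
  expect_equal(diff(exp_peaks), rep(24, length(exp_peaks) - 1))
  # sampled maxima sit on the analytic grid (grid resolution 1/3 h)
  pk <- detect_peaks(tr)
  expect_equal(pk$time_h, exp_peaks, tolerance = 0.05)
})

test_that("same spec and seed give bitwise-identical traces", {
  a <- simulate_luminescence(tau_h = 25.3, noise_sd = 8, seed = 11)
  b <- simulate_luminescence(tau_h = 25.3, noise_sd = 8, seed = 11)
  expect_identical(a$signal, b$signal)
  c <- simulate_luminescence(tau_h = 25.3, noise_sd = 8, seed = 12)
  expect_false(identical(a$signal, c$signal))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_luminescence(noise_sd = 5, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("longer free-running period delays the first LL peak", {
  t26 <- clean_trace(tau_h = 26)
  t22 <- clean_trace(tau_h = 22)
  p26 <- min(analytic_peaks(26)[analytic_peaks(26) >= t26$ll_start_h])
  p22 <- min(analytic_peaks(22)[analytic_peaks(22) >= t22$ll_start_h])
  expect_gt(p26, p22)
  # and the detector agrees
  f26 <- first_peak_in_ll(detect_peaks(t26), t26)
  f22 <- first_peak_in_ll(detect_peaks(t22), t22)
  expect_gt(f26, f22)
})

test_that("generator rejects invalid parameters", {
  expect_error(simulate_luminescence(tau_h = -1))
  expect_error(simulate_luminescence(noise_sd = -1))
  expect_error(simulate_luminescence(tau_h = NaN))
  expect_error(simulate_luminescence(ll_duration_h = -5))
})

test_that("flowering probability is fmax/2 at the programmed CDL", {
  # law of large numbers at the ramp midpoint
  fa <- simulate_flowering_assay(true_cdl_h = 12.5, fmax_pct = 100,
                                 transition_width_h = 1,
                                 day_lengths = 12.5,
                                 n_fronds_per_well = 1e5,
                                 n_replicates = 1, seed = 5)
  expect_equal(100 * fa$n_flowering / fa$n_total, 50, tolerance = 0.02)
})

test_that("a transition entirely below the tested grid gives no flowering", {
  fa <- simulate_flowering_assay(true_cdl_h = 5, transition_width_h = 1,
                                 day_lengths = c(9, 12, 15),
                                 n_fronds_per_well = 50, seed = 2)
  expect_true(all(fa$n_flowering == 0))
})

test_that("flowering assay is seed-reproducible", {
  a <- simulate_flowering_assay(12.5, seed = 7)
  b <- simulate_flowering_assay(12.5, seed = 7)
  expect_identical(a, b)
})

test_that("panel with zero slope and zero noise has constant true CDL", {
  pan <- simulate_strain_panel(n_strains = 10, cdl_slope_per_h = 0,
                               cdl_noise_sd_h = 0, cdl_intercept_h = 13,
                               seed = 1)
  expect_equal(pan$truth$true_cdl_h, rep(13, 10))
})

test_that("noiseless linear panel has sample correlation exactly -1", {
  pan <- simulate_strain_panel(n_strains = 20, cdl_slope_per_h = -0.5,
                               cdl_noise_sd_h = 0, seed = 2)
  expect_equal(cor(pan$truth$tau_h, pan$truth$true_cdl_h), -1)
})

test_that("programmed slope reproduces the population correlation", {
  # r_pop = b sigma_tau / sqrt(b^2 sigma_tau^2 + sigma_eps^2)
  r_pop <- -0.5 * 1 / sqrt(0.25 + 0.09)
  rs <- vapply(1:200, function(i) {
    pan <- simulate_strain_panel(n_strains = 72, tau_sd_h = 1,
                                 cdl_slope_per_h = -0.5,
                                 cdl_noise_sd_h = 0.3, seed = 400 + i)
    cor(pan$truth$tau_h, pan$truth$true_cdl_h)
  }, numeric(1))
  expect_lt(abs(mean(rs) - r_pop), 3 / sqrt(72))
})

test_that("panel generator enforces its preconditions", {
  expect_error(simulate_strain_panel(n_strains = 1))
  expect_error(simulate_strain_panel(tau_sd_h = -1))
})
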