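test_that("periodogram seeding localizes single and double spectral lines", {
  t <- seq(0, 72 - 1 / 3, by = 1 / 3)
  s1 <- periodogram_seeds(cos(2 * pi * t / 24), 1 / 3, k = 1)
  expect_equal(s1$tau_h, 24, tolerance = 0.5)
  y2 <- cos(2 * pi * t / 24) + 0.5 * cos(2 * pi * t / 12)
  s2 <- periodogram_seeds(y2, 1 / 3, k = 2)
  expect_equal(sort(s2$tau_h), c(12, 24), tolerance = 0.5)
  expect_gt(s2$amplitude[1], s2$amplitude[2])
})

test_that("seeding white noise returns k finite seeds", {
  set.seed(4)
  s <- periodogram_seeds(rnorm(216), 1 / 3, k = 4)
  expect_identical(nrow(s), 4L)
  expect_true(all(is.finite(unlist(s))))
})

test_that("all-zero input is rejected", {
  expect_error(periodogram_seeds(rep(0, 100), 1 / 3), "all-zero")
})

test_that("exact-model parameters are recovered to stated precision", {
  t <- seq(60, 132, by = 1 / 3)
  y <- 3 + 2 * cos(2 * pi * (t - 5) / 25)
  fit <- fit_multicomponent_cosine(t, y)
  expect_identical(fit$n_components, 1L)
  expect_equal(fit$c0, 3, tolerance = 1e-3)
  expect_equal(fit$components$tau_h, 25, tolerance = 1e-3)
  expect_equal(fit$components$amplitude, 2, tolerance = 1e-3)
  expect_equal(fit$components$phase_h, 5, tolerance = 0.01)
  expect_lt(rae(fit, 1), 1e-6)
})

test_that("two noiseless components are both recovered", {
  t <- seq(60, 132, by = 1 / 3)
  y <- 2 * cos(2 * pi * t / 24.5) + 0.8 * cos(2 * pi * t / 12.25)
  fit <- fit_multicomponent_cosine(t, y)
  expect_gte(fit$n_components, 2L)
  taus <- sort(fit$components$tau_h[order(fit$components$amplitude,
                                          decreasing = TRUE)][1:2])
  expect_equal(taus, c(12.25, 24.5), tolerance = 0.01)
})

test_that("a constant series yields zero components and c0 = constant", {
  t <- seq(60, 132, by = 1 / 3)
  fit <- fit_multicomponent_cosine(t, rep(4.2, length(t)))
  expect_identical(fit$n_components, 0L)
  expect_equal(fit$c0, 4.2)
})

test_that("RSS does not increase when the component budget grows", {
  t <- seq(60, 132, by = 1 / 3)
  set.seed(10)
  y <- 2 * cos(2 * pi * t / 24.5) + 0.8 * cos(2 * pi * t / 12.25) +
    rnorm(length(t), 0, 0.3)
  rss <- vapply(1:3, function(m) {
    fit_multicomponent_cosine(t, y, rhythm_config(max_components = m))$rss
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("RAE is the capped ratio of amplitude CI half-width to amplitude", {
  fake <- structure(list(n_components = 1L,
                         components = data.frame(
                           tau_h = 24, amplitude = 1, phase_h = 0,
                           amplitude_se = 1,
                           amplitude_ci_halfwidth = 2.5)),
                    class = "rhythm_fit")
  expect_identical(rae(fake, 1), 1)  # interval wider than amplitude: cap
  fake$components$amplitude_ci_halfwidth <- 0.3
  expect_equal(rae(fake, 1), 0.3)
  fake$components$amplitude_ci_halfwidth <- NA_real_
  expect_warning(expect_identical(rae(fake, 1), 1), "singular")
})

test_that("clean rhythms at SNR 5 pass the RAE filter", {
  raes <- vapply(1:20, function(i) {
    tr <- simulate_luminescence(tau_h = 24.5, amplitude = 50, noise_sd = 10,
                                seed = 300 + i)
    estimate_frp(preprocess_trace(tr))$rae
  }, numeric(1))
  expect_gte(mean(raes < 0.1), 0.95)
})

test_that("simulated period is recovered through the full pipeline", {
  est <- vapply(1:20, function(i) {
    tr <- simulate_luminescence(tau_h = 25, amplitude = 50, noise_sd = 10,
                                seed = 700 + i)
    estimate_frp(preprocess_trace(tr))$tau_h
  }, numeric(1))
  expect_lt(sqrt(mean((est - 25)^2)), 0.2)
})

test_that("harmonic-rich traces report the circadian, not the harmonic", {
  t <- seq(60, 132, by = 1 / 3)
  y <- cos(2 * pi * t / 24) + 0.9 * cos(2 * pi * t / 12)
  tr <- lum_trace("s", "r", seq(0, 156, by = 1 / 3),
                  3 + cos(2 * pi * seq(0, 156, by = 1 / 3) / 24) +
                    0.9 * cos(2 * pi * seq(0, 156, by = 1 / 3) / 12),
                  ll_start_h = 39)
  tr$stage <- "normalized"  # already dimensionless
  fit <- estimate_frp(tr)
  expect_gte(fit$tau_h, 15)
  expect_lte(fit$tau_h, 35)
  expect_equal(fit$tau_h, 24, tolerance = 0.1)
})

test_that("estimated period is invariant to affine input transforms", {
  tr <- simulate_luminescence(tau_h = 26, noise_sd = 5, seed = 77)
  scaled <- lum_trace(tr$strain_id, tr$replicate_id, tr$time_h,
                      3 * tr$signal + 50, tr$ll_start_h,
                      tr$entrain_photoperiod_h)
  f1 <- estimate_frp(preprocess_trace(tr))
  f2 <- estimate_frp(preprocess_trace(scaled))
  expect_equal(f1$tau_h, f2$tau_h, tolerance = 1e-6)
})

test_that("a trace not covering the analysis window is rejected", {
  t <- seq(0, 90, by = 1 / 3)
  tr <- lum_trace("s", "r", t, cos(2 * pi * t / 24) + 2, ll_start_h = 39,
                  stage = "normalized")
  expect_error(estimate_frp(tr), "analysis window")
})

test_that("replicate aggregation applies means, SDs and thresholds", {
  d <- data.frame(tau_h = c(24.0, 24.2, 24.4), rae = c(0.03, 0.04, 0.05))
  a <- aggregate_replicates(d, strain_id = "ok")
  expect_equal(a$mean_frp_h, 24.2)
  expect_equal(a$sd_frp_h, 0.2)
  expect_equal(a$mean_rae, 0.04)
  expect_false(a$excluded)

  b <- aggregate_replicates(
    data.frame(tau_h = c(22.0, 25.5, 24.0), rae = c(0.05, 0.05, 0.05)),
    strain_id = "wobbly")
  expect_equal(b$sd_frp_h, sd(c(22, 25.5, 24)))
  expect_gt(b$sd_frp_h, 1.5)
  expect_true(b$excluded)
  expect_identical(b$reason, "sd_frp")

  c3 <- aggregate_replicates(
    data.frame(tau_h = c(24, 24.1, 24.2), rae = c(0.12, 0.11, 0.13)),
    strain_id = "noisy")
  expect_true(c3$excluded)
  expect_identical(c3$reason, "rae")
})

test_that("the SD-only exclusion switch ignores the RAE threshold", {
  d <- data.frame(tau_h = c(24, 24.1, 24.2), rae = c(0.12, 0.11, 0.13))
  a <- aggregate_replicates(d, rhythm_config(exclusion_rule = "sd_only"),
                            strain_id = "s")
  expect_false(a$excluded)
})

test_that("a replicate without a circadian component excludes the strain", {
  d <- data.frame(tau_h = c(24, NA), rae = c(0.05, 1))
  a <- aggregate_replicates(d, strain_id = "s")
  expect_true(a$excluded)
  expect_match(a$reason, "no_circadian_component")
})
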