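test_that("Pearson test matches the t-distribution closed form", {
  x <- 1:10
  perfect <- pearson_test(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)

  sym <- pearson_test(c(-1, 0, 1), c(1, 0.5, 1))
  expect_equal(sym$r, 0)
  expect_equal(sym$p, 1)

  # hand-computable case: r = 0.8, t = 0.8 sqrt(3 / 0.36) on 3 df
  ct <- pearson_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(ct$r, 0.8, tolerance = 1e-12)
  t_stat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(ct$p, 2 * pt(-t_stat, 3), tolerance = 1e-12)
  expect_identical(ct$n, 5L)
})

test_that("Pearson preconditions are enforced", {
  expect_error(pearson_test(1:2, 1:2), "at least 3")
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
})

test_that("Deming regression recovers a perfect line and swap symmetry", {
  x <- c(1, 2, 4, 7, 9)
  fit <- deming_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)

  set.seed(5)
  xs <- rnorm(40)
  ys <- 0.7 * xs + rnorm(40, 0, 0.5)
  s_xy <- deming_fit(xs, ys)$slope
  s_yx <- deming_fit(ys, xs)$slope
  expect_equal(s_xy * s_yx, 1, tolerance = 1e-10)  # orthogonal identity
  # equivariance under common rescaling of both axes
  s_scaled <- deming_fit(3 * xs, 3 * ys)$slope
  expect_equal(s_scaled, s_xy, tolerance = 1e-10)
})

test_that("Deming beats OLS under equal errors in both variables", {
  dem_bias <- ols_bias <- numeric(100)
  for (r in 1:100) {
    set.seed(1200 + r)
    xt <- rnorm(72, 24, 1)
    yt <- 25 - 0.5 * xt
    x <- xt + rnorm(72, 0, 0.3)
    y <- yt + rnorm(72, 0, 0.3)
    dem_bias[r] <- deming_fit(x, y)$slope + 0.5
    ols_bias[r] <- unname(coef(lm(y ~ x))[2]) + 0.5
  }
  expect_lt(abs(mean(dem_bias)), abs(mean(ols_bias)))
})

test_that("exact Wilcoxon p values match the enumeration arithmetic", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 2 / 20)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 2 / 6)
  expect_identical(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5)), 1)
})

test_that("exact path agrees with the reference test for all small sizes", {
  set.seed(21)
  for (na in 1:5) {
    for (nb in 1:(10 - na)) {
      vals <- sample(seq_len(60), na + nb)  # distinct, no ties
      a <- vals[seq_len(na)]
      b <- vals[-seq_len(na)]
      p_pkg <- wilcoxon_rank_sum(a, b)
      p_ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-12,
                   label = sprintf("n_a=%d n_b=%d", na, nb))
    }
  }
})

test_that("large or tied samples use the corrected normal approximation", {
  set.seed(22)
  a <- rnorm(10)
  b <- rnorm(12, 0.8)
  p_pkg <- wilcoxon_rank_sum(a, b)
  p_ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)

  a2 <- c(1, 2, 2, 3)
  b2 <- c(2, 3, 3, 4)
  p_tied <- wilcoxon_rank_sum(a2, b2)
  p_tied_ref <- stats::wilcox.test(a2, b2, exact = FALSE,
                                   correct = TRUE)$p.value
  expect_equal(p_tied, p_tied_ref, tolerance = 1e-10)
})

test_that("Holm adjustment matches the step-down closed form", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.2)), c(0.03, 0.04, 0.2),
               tolerance = 1e-15)
  expect_equal(holm_adjust(0.37), 0.37)
  expect_equal(holm_adjust(c(0.04, 0.04)), c(0.08, 0.08),
               tolerance = 1e-15)
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p), tolerance = 1e-15)
    expect_true(all(adj >= p))                       # never smaller than raw
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone step-down
  }
})

test_that("compact letters handle the canonical configurations", {
  all_sig <- matrix(0.001, 3, 3); diag(all_sig) <- NA
  expect_identical(unname(compact_letters(all_sig, 0.05)),
                   c("a", "b", "c"))
  none_sig <- matrix(0.9, 3, 3); diag(none_sig) <- NA
  expect_identical(unname(compact_letters(none_sig, 0.05)),
                   c("a", "a", "a"))
  chain <- matrix(c(NA, 0.5, 0.01, 0.5, NA, 0.5, 0.01, 0.5, NA), 3, 3)
  lets <- unname(compact_letters(chain, 0.05))
  expect_identical(lets, c("a", "ab", "b"))
  # minimality: one letter cannot separate the significant pair (1,3)
  expect_identical(length(unique(unlist(strsplit(lets, "")))), 2L)
})

test_that("letter displays satisfy the share-letter biconditional", {
  set.seed(41)
  for (i in 1:100) {
    k <- sample(3:6, 1)
    p <- random_p_matrix(k)
    lets <- compact_letters(p, 0.05)
    expect_true(letters_consistent(lets, p, 0.05))
  }
})

test_that("pairwise Wilcoxon bundles matrices and letters coherently", {
  set.seed(51)
  vals <- c(rnorm(8, 0), rnorm(8, 0), rnorm(8, 6))
  grp <- rep(c("g1", "g2", "g3"), each = 8)
  pw <- pairwise_wilcoxon(vals, grp)
  expect_true(all(pw$p_adj >= pw$p_raw, na.rm = TRUE))
  expect_true(isSymmetric(pw$p_adj))
  expect_true(letters_consistent(unname(pw$letters), pw$p_adj, pw$alpha))
  expect_identical(unname(pw$letters), c("a", "a", "b"))
})

test_that("panel association drops excluded and censored strains", {
  tau <- c(23, 24, 25, 26, 27)
  rec <- data.frame(strain_id = paste0("s", 1:5),
                    mean_frp_h = tau,
                    first_peak_h = tau + 2,
                    cdl_h = 25 - 0.5 * tau,
                    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                    cdl_censored = FALSE)
  pa <- panel_association(rec)
  expect_identical(pa$frp_cdl$n, 4L)          # excluded strain dropped
  expect_equal(pa$frp_cdl$pearson$r, -1)
  expect_equal(pa$frp_cdl$deming$slope, -0.5, tolerance = 1e-12)
  expect_equal(pa$frp_peak$pearson$r, 1)

  rec$cdl_censored <- c(TRUE, rep(FALSE, 4))
  pa2 <- panel_association(rec)
  expect_identical(pa2$frp_cdl$n, 3L)         # censored CDL also dropped
})

test_that("a null panel rarely reports a significant correlation", {
  sig <- vapply(1:60, function(i) {
    pan <- simulate_strain_panel(n_strains = 30, cdl_slope_per_h = 0,
                                 cdl_noise_sd_h = 0.5, seed = 6000 + i)
    pearson_test(pan$truth$tau_h, pan$truth$true_cdl_h)$p < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.1)
})
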