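# Shared fixtures and independent oracles for the test suite.

# Noiseless, trend-free trace: analytic peak times are known exactly.
clean_trace <- function(tau_h = 24, offset = 2, ...) {
  simulate_luminescence(tau_h = tau_h, entrained_peak_offset_h = offset,
                        noise_sd = 0, growth_rate_per_h = 0,
                        damping_per_h = 0, ...)
}

# Analytic peak times of the phase-continuity signal model over [0, t_max]:
# entrained peaks at offset + 24 k before LL onset, free-running peaks
# afterwards by solving theta(t) = 2 pi k.
analytic_peaks <- function(tau_h, offset = 2, photoperiod = 15,
                           entrain_days = 2, t_max = 180) {
  ll <- 24 * (entrain_days - 1) + photoperiod
  ent <- offset + 24 * (0:floor((ll - offset) / 24))
  ent <- ent[ent < ll]
  theta_ll <- (ll - offset) / 24            # cycles at release
  k <- seq(ceiling(theta_ll), floor(theta_ll + (t_max - ll) / tau_h))
  free <- ll + (k - theta_ll) * tau_h
  c(ent, free[free <= t_max])
}

# Independent moving-window oracle: direct evaluation at one interior time.
window_stat_oracle <- function(y, times, t0, window_h, dt, stat) {
  k <- floor(window_h / (2 * dt) + 1e-9)
  i0 <- which.min(abs(times - t0))
  w <- y[(i0 - k):(i0 + k)]
  if (stat == "mean") mean(w) else sqrt(mean(w^2) - mean(w)^2)
}

# Closed-form Holm adjustment, written from the definition.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Letter display must satisfy: share a letter <=> not significantly
# different (adjusted p >= alpha).
letters_consistent <- function(letters_vec, p_adj, alpha) {
  k <- length(letters_vec)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      share <- length(intersect(strsplit(letters_vec[i], "")[[1]],
                                strsplit(letters_vec[j], "")[[1]])) > 0
      sig <- !is.na(p_adj[i, j]) && p_adj[i, j] < alpha
      if (share == sig) return(FALSE)
    }
  }
  TRUE
}

random_p_matrix <- function(k) {
  p <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      p[i, j] <- p[j, i] <- stats::runif(1)
    }
  }
  p
}
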