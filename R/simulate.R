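#' Simulate a luminescence reporter trace
#'
#' Generates one replicate of a circadian bioluminescence reporter time
#' series under the standard entrainment-then-release protocol: a number of
#' light/dark cycles (default two days of 15 h light / 9 h dark) followed by
#' constant light (LL). The deterministic signal is
#' \deqn{y(t) = e^{g t}\,[M + A\,D(t)\cos\theta(t)] + \varepsilon_t}
#' where the phase \eqn{\theta(t)} is continuous, advancing at rate
#' \eqn{2\pi/24} per hour during entrainment (anchored so that a cosine peak
#' falls `entrained_peak_offset_h` hours after each lights-on) and at
#' \eqn{2\pi/\tau} per hour after release into LL. `D(t)` is 1 during
#' entrainment and decays exponentially at rate `damping_per_h` in LL; the
#' multiplicative envelope \eqn{e^{gt}} models reporter signal from an
#' exponentially growing frond population. Noise is additive i.i.d.
#' Gaussian.
#'
#' Release into LL happens at the end of the final photoperiod, i.e. at
#' `ll_start_h = 24 * (entrain_days - 1) + entrain_photoperiod_h` (the dark
#' period that never comes); the sampling grid runs from 0 to
#' `24 * entrain_days + ll_duration_h`.
#'
#' @param tau_h Free-running period in LL, hours.
#' @param entrain_photoperiod_h Light hours per 24-h entrainment cycle.
#' @param entrain_days Number of entrainment days.
#' @param ll_duration_h Hours of recording beyond the nominal entrainment
#'   block (grid ends at `24 * entrain_days + ll_duration_h`).
#' @param sampling_interval_h Sampling interval in hours (default 1/3,
#'   i.e. 20 min).
#' @param entrained_peak_offset_h Peak time after lights-on during
#'   entrainment, hours.
#' @param amplitude,mesor Oscillation amplitude and midline, signal units.
#' @param growth_rate_per_h Exponential trend coefficient per hour.
#' @param damping_per_h Amplitude decay rate in LL, per hour.
#' @param noise_sd Additive Gaussian noise SD, signal units.
#' @param strain_id,replicate_id Labels carried on the trace.
#' @param seed Optional integer; when given the trace is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A [lum_trace] object.
#' @examples
#' tr <- simulate_luminescence(tau_h = 25, noise_sd = 0)
#' tr
#' @export
simulate_luminescence <- function(tau_h = 24,
                                  entrain_photoperiod_h = 15,
                                  entrain_days = 2,
                                  ll_duration_h = 132,
                                  sampling_interval_h = 1 / 3,
                                  entrained_peak_offset_h = 2,
                                  amplitude = 50,
                                  mesor = 100,
                                  growth_rate_per_h = 0.005,
                                  damping_per_h = 0.005,
                                  noise_sd = 10,
                                  strain_id = "sim",
                                  replicate_id = "r1",
                                  seed = NULL) {
  stopifnot(is.finite(tau_h), tau_h > 0,
            is.finite(sampling_interval_h), sampling_interval_h > 0,
            is.finite(amplitude), amplitude >= 0,
            is.finite(noise_sd), noise_sd >= 0,
            is.finite(mesor), is.finite(growth_rate_per_h),
            is.finite(damping_per_h), damping_per_h >= 0,
            entrain_days >= 1, ll_duration_h > 0,
            entrain_photoperiod_h > 0, entrain_photoperiod_h < 24)

  total_h <- 24 * entrain_days + ll_duration_h
  ll_start_h <- 24 * (entrain_days - 1) + entrain_photoperiod_h
  t <- seq(0, total_h, by = sampling_interval_h)

  # phase continuous across release: entrained rate 2*pi/24, free-run 2*pi/tau
  theta <- ifelse(t < ll_start_h,
                  2 * pi * (t - entrained_peak_offset_h) / 24,
                  2 * pi * (ll_start_h - entrained_peak_offset_h) / 24 +
                    2 * pi * (t - ll_start_h) / tau_h)
  damp <- ifelse(t < ll_start_h, 1, exp(-damping_per_h * (t - ll_start_h)))
  y <- exp(growth_rate_per_h * t) * (mesor + amplitude * damp * cos(theta))
  if (noise_sd > 0) {
    y <- y + local_rnorm(length(y), sd = noise_sd, seed = seed)
  }

  lum_trace(strain_id = strain_id, replicate_id = replicate_id,
            time_h = t, signal = y, ll_start_h = ll_start_h,
            entrain_photoperiod_h = entrain_photoperiod_h)
}

#' Simulate a photoperiodic flowering assay
#'
#' Draws flowering/total frond counts over a grid of day lengths for a
#' strain with a known (programmed) critical day length. The flowering
#' probability is a symmetric linear ramp centred on `true_cdl_h`:
#' \eqn{p(DL) = (F_{max}/100)\cdot r(DL)} with \eqn{r = 1} for
#' \eqn{DL \le CDL - w/2}, \eqn{r = 0} for \eqn{DL \ge CDL + w/2} and
#' linear in between, so that the 50-percent-of-maximum point equals the
#' programmed CDL exactly. Counts are binomial per replicate well.
#'
#' @param true_cdl_h Programmed critical day length, hours.
#' @param fmax_pct Maximum flowering rate, percent (0, 100].
#' @param transition_width_h Width `w` of the linear ramp, hours.
#' @param day_lengths Tested day lengths, hours; the default is the
#'   standard 10-point grid with 0.5-h resolution near the transition.
#' @param n_fronds_per_well Fronds counted per replicate well.
#' @param n_replicates Replicate wells per day length.
#' @param strain_id Label carried on the assay.
#' @param seed Optional integer for reproducibility.
#' @return A data frame of class `flowering_assay` with columns
#'   `strain_id`, `day_length_h`, `replicate_id`, `n_flowering`, `n_total`.
#' @examples
#' fa <- simulate_flowering_assay(true_cdl_h = 12.5, seed = 1)
#' head(fa)
#' @export
simulate_flowering_assay <- function(true_cdl_h,
                                     fmax_pct = 80,
                                     transition_width_h = 1,
                                     day_lengths = c(9, 11, 11.5, 12, 12.5,
                                                     13, 13.5, 14, 14.5, 15),
                                     n_fronds_per_well = 20,
                                     n_replicates = 2,
                                     strain_id = "sim",
                                     seed = NULL) {
  stopifnot(is.finite(true_cdl_h),
            fmax_pct > 0, fmax_pct <= 100,
            transition_width_h > 0,
            length(day_lengths) >= 1,
            n_fronds_per_well >= 1, n_replicates >= 1)

  p <- (fmax_pct / 100) * flowering_ramp(day_lengths, true_cdl_h,
                                         transition_width_h)
  grid <- expand.grid(replicate_id = paste0("r", seq_len(n_replicates)),
                      day_length_h = day_lengths,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$p <- rep(p, each = n_replicates)
  grid$n_flowering <- local_rbinom(nrow(grid), n_fronds_per_well, grid$p,
                                   seed = seed)
  out <- data.frame(strain_id = strain_id,
                    day_length_h = grid$day_length_h,
                    replicate_id = grid$replicate_id,
                    n_flowering = grid$n_flowering,
                    n_total = n_fronds_per_well,
                    stringsAsFactors = FALSE)
  out <- out[order(out$day_length_h, out$replicate_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flowering_assay", "data.frame")
  out
}

# linear ramp: 1 below cdl - w/2, 0 above cdl + w/2
flowering_ramp <- function(day_length_h, cdl_h, width_h) {
  pmin(1, pmax(0, (cdl_h + width_h / 2 - day_length_h) / width_h))
}

#' Simulate a strain panel with a programmed period--CDL relationship
#'
#' Draws per-strain free-running periods \eqn{\tau_i \sim N(\mu_\tau,
#' \sigma_\tau^2)} and true critical day lengths
#' \eqn{CDL_i = a + b\,\tau_i + N(0, \sigma_\epsilon^2)}, returning the
#' ground-truth table together with per-strain simulation parameters so
#' that recovery of the programmed relationship can be scored downstream.
#'
#' @param n_strains Number of strains (>= 2).
#' @param tau_mean_h,tau_sd_h Mean and SD of the period distribution, hours.
#' @param cdl_intercept_h Intercept `a` of the true CDL line, hours.
#' @param cdl_slope_per_h Slope `b`: change in true CDL per hour of period.
#' @param cdl_noise_sd_h SD of the CDL process noise around the line, hours.
#' @param latitude_range Length-2 numeric; strain latitudes are drawn
#'   uniformly over this range (panel metadata only).
#' @param n_populations Number of population labels to spread strains over.
#' @param seed Optional integer for reproducibility.
#' @return A list of class `strain_panel` with elements `truth` (data frame
#'   of strain_id, population_id, latitude_deg, tau_h, true_cdl_h) and
#'   `trace_specs` / `assay_specs` (per-strain parameter lists consumable by
#'   [simulate_luminescence()] and [simulate_flowering_assay()]).
#' @examples
#' pan <- simulate_strain_panel(n_strains = 12, seed = 1)
#' head(pan$truth)
#' @export
simulate_strain_panel <- function(n_strains = 72,
                                  tau_mean_h = 24,
                                  tau_sd_h = 1,
                                  cdl_intercept_h = 25,
                                  cdl_slope_per_h = -0.5,
                                  cdl_noise_sd_h = 0.3,
                                  latitude_range = c(31.5, 43.8),
                                  n_populations = 4,
                                  seed = NULL) {
  stopifnot(n_strains >= 2, tau_sd_h >= 0, cdl_noise_sd_h >= 0,
            is.finite(cdl_intercept_h), is.finite(cdl_slope_per_h),
            length(latitude_range) == 2)

  draw <- function() {
    tau <- stats::rnorm(n_strains, tau_mean_h, tau_sd_h)
    cdl <- cdl_intercept_h + cdl_slope_per_h * tau +
      stats::rnorm(n_strains, 0, cdl_noise_sd_h)
    lat <- stats::runif(n_strains, min(latitude_range), max(latitude_range))
    list(tau = tau, cdl = cdl, lat = lat)
  }
  d <- with_local_seed(seed, draw())

  ids <- sprintf("S%03d", seq_len(n_strains))
  pops <- paste0("P", rep_len(seq_len(n_populations), n_strains))
  truth <- data.frame(strain_id = ids, population_id = pops,
                      latitude_deg = d$lat, tau_h = d$tau,
                      true_cdl_h = d$cdl, stringsAsFactors = FALSE)

  trace_specs <- lapply(seq_len(n_strains), function(i) {
    list(strain_id = ids[i], tau_h = d$tau[i])
  })
  assay_specs <- lapply(seq_len(n_strains), function(i) {
    list(strain_id = ids[i], true_cdl_h = d$cdl[i])
  })
  structure(list(truth = truth, trace_specs = trace_specs,
                 assay_specs = assay_specs),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat("Simulated strain panel:", nrow(x$truth), "strains\n")
  cat(sprintf("  tau range: %.2f-%.2f h; true CDL range: %.2f-%.2f h\n",
              min(x$truth$tau_h), max(x$truth$tau_h),
              min(x$truth$true_cdl_h), max(x$truth$true_cdl_h)))
  invisible(x)
}

# Run expr with a locally seeded RNG, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

local_rnorm <- function(n, sd, seed = NULL) {
  with_local_seed(seed, stats::rnorm(n, 0, sd))
}

local_rbinom <- function(n, size, prob, seed = NULL) {
  with_local_seed(seed, stats::rbinom(n, size, prob))
}
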