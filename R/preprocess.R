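#' Moving-average detrending of a luminescence trace
#'
#' Subtracts a centred 24-h moving average from the signal, removing the
#' growth trend before period analysis. The window spans
#' `[t - window_h/2, t + window_h/2]` inclusive (73 samples at 20-min
#' sampling); output is defined only where the full window fits, so
#' `(window points - 1)` samples are trimmed from the edges. No padding is
#' used: the analyses downstream work on an interior window, so edge
#' behaviour never matters and trimming is the least surprising choice.
#'
#' @param trace A [lum_trace].
#' @param window_h Window width in hours (default 24, one full cycle).
#' @return A [lum_trace] with `stage = "detrended"` and trimmed time range.
#' @export
moving_average_detrend <- function(trace, window_h = 24) {
  stopifnot(inherits(trace, "lum_trace"))
  w <- window_points(window_h, sampling_interval(trace))
  if (length(trace$signal) < w) {
    stop("trace shorter than one ", window_h, "-h window (", w, " points)")
  }
  mu <- moving_mean(trace$signal, w)
  keep <- !is.na(mu)
  lum_trace(trace$strain_id, trace$replicate_id,
            trace$time_h[keep], trace$signal[keep] - mu[keep],
            ll_start_h = trace$ll_start_h,
            entrain_photoperiod_h = trace$entrain_photoperiod_h,
            stage = "detrended")
}

#' Moving-SD amplitude normalization
#'
#' Divides a detrended trace by its centred 24-h moving standard deviation,
#' putting all traces on a common dimensionless amplitude scale before the
#' cosine fit. The SD uses the population (divide-by-N) form: it is a
#' normalization constant, not an inferential estimate. A second edge trim
#' of `(window points - 1)` samples is applied.
#'
#' @inheritParams moving_average_detrend
#' @return A [lum_trace] with `stage = "normalized"`.
#' @export
moving_sd_normalize <- function(trace, window_h = 24) {
  stopifnot(inherits(trace, "lum_trace"))
  w <- window_points(window_h, sampling_interval(trace))
  if (length(trace$signal) < w) {
    stop("trace shorter than one ", window_h, "-h window (", w, " points)")
  }
  s <- moving_popsd(trace$signal, w)
  keep <- !is.na(s)
  tol <- 1e-12 * max(abs(trace$signal), 1)
  if (any(s[keep] <= tol)) {
    bad <- trace$time_h[keep][which(s[keep] <= tol)[1]]
    stop(sprintf(
      "zero moving SD at t = %.4g h (constant segment); cannot normalize",
      bad))
  }
  lum_trace(trace$strain_id, trace$replicate_id,
            trace$time_h[keep], trace$signal[keep] / s[keep],
            ll_start_h = trace$ll_start_h,
            entrain_photoperiod_h = trace$entrain_photoperiod_h,
            stage = "normalized")
}

#' Detrend and normalize in one step
#'
#' Convenience wrapper applying [moving_average_detrend()] then
#' [moving_sd_normalize()] with the same window.
#'
#' @inheritParams moving_average_detrend
#' @return A [lum_trace] with `stage = "normalized"`.
#' @export
preprocess_trace <- function(trace, window_h = 24) {
  moving_sd_normalize(moving_average_detrend(trace, window_h), window_h)
}

# Odd number of samples spanning <= window_h, centred (73 at dt = 1/3 h).
window_points <- function(window_h, dt) {
  if (window_h <= 0) stop("window_h must be positive")
  2L * as.integer(floor(window_h / (2 * dt) + 1e-9)) + 1L
}

# Centred moving mean; NA where the full window does not fit.
moving_mean <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

# Centred moving population SD (divide by N).
moving_popsd <- function(x, w) {
  m1 <- moving_mean(x, w)
  m2 <- moving_mean(x * x, w)
  v <- pmax(m2 - m1 * m1, 0)
  sqrt(v)
}
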