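#' Detect peaks by local quadratic curve fitting
#'
#' Finds candidate peaks as local maxima of a lightly smoothed copy of the
#' trace, then refines each by ordinary least squares of a quadratic on the
#' raw samples within `fit_halfwidth_h` hours of the candidate; the peak
#' time is the parabola vertex. A fitted candidate is kept only when the
#' quadratic opens downwards and its vertex lies inside the fitted window.
#' Peaks closer together than `min_separation_h` are resolved by keeping
#' the one with the higher fitted height (ties: the earlier peak).
#'
#' The defaults (2-h smoothing, +/-2-h fit window) make the quadratic span
#' about one sixth of a circadian cycle, where a cosine is locally
#' near-quadratic and the vertex bias is below 0.05 h.
#'
#' @param trace A [lum_trace] (any processing stage).
#' @param smooth_window_h Moving-average window used only for candidate
#'   detection, hours.
#' @param fit_halfwidth_h Half-width of the quadratic fit window, hours.
#' @param min_separation_h Minimum separation between reported peaks, hours.
#' @return A data frame of class `peak_estimates` with columns `time_h`,
#'   `height`, `curvature`; empty (zero rows) when no peak is found.
#' @examples
#' tr <- simulate_luminescence(tau_h = 24, noise_sd = 0,
#'                             growth_rate_per_h = 0, damping_per_h = 0)
#' detect_peaks(tr)
#' @export
detect_peaks <- function(trace, smooth_window_h = 2, fit_halfwidth_h = 2,
                         min_separation_h = 12) {
  stopifnot(inherits(trace, "lum_trace"))
  t <- trace$time_h
  y <- trace$signal
  dt <- sampling_interval(trace)
  k <- max(1L, as.integer(round(fit_halfwidth_h / dt)))
  if (length(y) < 2L * k + 1L) stop("trace shorter than the fit window")

  w <- window_points(smooth_window_h, dt)
  s <- if (w >= 3) moving_mean(y, w) else y

  n <- length(s)
  idx <- which(!is.na(s))
  cand <- integer(0)
  for (i in idx) {
    if (i > 1 && i < n && !is.na(s[i - 1]) && !is.na(s[i + 1]) &&
        s[i] > s[i - 1] && s[i] >= s[i + 1]) {
      cand <- c(cand, i)
    }
  }

  peaks <- data.frame(time_h = numeric(0), height = numeric(0),
                      curvature = numeric(0))
  for (i in cand) {
    lo <- i - k
    hi <- i + k
    if (lo < 1 || hi > length(y)) next
    tw <- t[lo:hi]
    yw <- y[lo:hi]
    tc <- tw - t[i]  # centre for conditioning
    fit <- stats::lm.fit(cbind(1, tc, tc^2), yw)
    a <- fit$coefficients[3]
    b <- fit$coefficients[2]
    if (!is.finite(a) || a >= 0) next
    vertex <- -b / (2 * a)
    if (vertex < tc[1] || vertex > tc[length(tc)]) next
    time_h <- t[i] + vertex
    height <- fit$coefficients[1] + b * vertex + a * vertex^2
    peaks <- rbind(peaks, data.frame(time_h = time_h, height = height,
                                     curvature = a))
  }

  if (nrow(peaks) > 1) {
    peaks <- peaks[order(peaks$time_h), , drop = FALSE]
    keep <- rep(TRUE, nrow(peaks))
    repeat {
      ok <- which(keep)
      if (length(ok) < 2) break
      gaps <- diff(peaks$time_h[ok])
      close <- which(gaps < min_separation_h)
      if (length(close) == 0) break
      j <- close[1]
      i1 <- ok[j]; i2 <- ok[j + 1]
      # keep the higher fitted height; ties -> earlier time
      drop <- if (peaks$height[i2] > peaks$height[i1]) i1 else i2
      keep[drop] <- FALSE
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  attr(peaks, "fit_halfwidth_h") <- fit_halfwidth_h
  class(peaks) <- c("peak_estimates", "data.frame")
  peaks
}

#' Timing of the first peak in constant light
#'
#' Returns the time of the earliest detected peak at or after release into
#' constant light, expressed as hours since the final lights-on preceding
#' the release (the dawn of the last entrained day). This is the phase
#' phenotype that carries the entrained clock state into free run: under
#' phase continuity, strains with a longer free-running period show a later
#' first LL peak.
#'
#' @param peaks A `peak_estimates` data frame from [detect_peaks()].
#' @param trace The [lum_trace] the peaks came from (supplies `ll_start_h`
#'   and the dawn reference).
#' @return Hours since the final entrained dawn, or `NA_real_` (with a
#'   warning) when no peak falls in LL.
#' @export
first_peak_in_ll <- function(peaks, trace) {
  stopifnot(inherits(trace, "lum_trace"))
  in_ll <- peaks$time_h >= trace$ll_start_h
  if (!any(in_ll)) {
    warning("no peak detected after LL onset for ", trace$strain_id, "/",
            trace$replicate_id)
    return(NA_real_)
  }
  min(peaks$time_h[in_ll]) - final_dawn(trace)
}
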