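#' Luminescence trace object
#'
#' Container for one replicate's uniformly sampled reporter signal together
#' with the entrainment/constant-light annotations the downstream analyses
#' need. Times are hours since experiment start (lights-on of entrainment
#' day 1); `ll_start_h` marks the release into constant light.
#'
#' @param strain_id,replicate_id Labels.
#' @param time_h Strictly increasing, uniformly spaced times in hours.
#' @param signal Finite signal values, same length as `time_h`.
#' @param ll_start_h Time of release into constant light, hours.
#' @param entrain_photoperiod_h Light hours per 24-h entrainment cycle.
#' @param stage Processing stage: "raw", "detrended" or "normalized".
#' @return An object of class `lum_trace`.
#' @export
lum_trace <- function(strain_id, replicate_id, time_h, signal,
                      ll_start_h, entrain_photoperiod_h = 15,
                      stage = "raw") {
  time_h <- as.numeric(time_h)
  signal <- as.numeric(signal)
  if (length(time_h) != length(signal)) {
    stop("time_h and signal must have the same length")
  }
  if (length(time_h) < 2) stop("a trace needs at least two samples")
  if (any(!is.finite(time_h)) || any(!is.finite(signal))) {
    stop("non-finite values in trace for strain ", strain_id,
         " replicate ", replicate_id)
  }
  dt <- diff(time_h)
  if (any(dt <= 0)) {
    stop("times must be strictly increasing (strain ", strain_id,
         " replicate ", replicate_id, ")")
  }
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("non-uniform sampling grid (strain ", strain_id,
         " replicate ", replicate_id, ")")
  }
  if (!is.finite(ll_start_h) || ll_start_h < 0 || ll_start_h > max(time_h)) {
    stop("ll_start_h must lie within the recorded time range")
  }
  structure(list(strain_id = as.character(strain_id),
                 replicate_id = as.character(replicate_id),
                 time_h = time_h, signal = signal,
                 ll_start_h = ll_start_h,
                 entrain_photoperiod_h = entrain_photoperiod_h,
                 stage = stage),
            class = "lum_trace")
}

#' @export
print.lum_trace <- function(x, ...) {
  dt <- x$time_h[2] - x$time_h[1]
  cat(sprintf("Luminescence trace %s/%s (%s)\n",
              x$strain_id, x$replicate_id, x$stage))
  cat(sprintf("  %d samples, %.3g-%.4g h every %.3g h; LL from %.4g h\n",
              length(x$time_h), min(x$time_h), max(x$time_h), dt,
              x$ll_start_h))
  invisible(x)
}

#' @param y Ignored.
#' @rdname lum_trace
#' @export
plot.lum_trace <- function(x, y, ...) {
  graphics::plot(x$time_h, x$signal, type = "l",
                 xlab = "time (h)",
                 ylab = if (x$stage == "raw") "luminescence" else
                   paste0(x$stage, " signal"),
                 main = paste0(x$strain_id, "/", x$replicate_id), ...)
  graphics::abline(v = x$ll_start_h, lty = 2, col = "grey40")
  invisible(x)
}

sampling_interval <- function(trace) trace$time_h[2] - trace$time_h[1]

# Dawn of the last entrained day: the lights-on preceding LL release.
final_dawn <- function(trace) trace$ll_start_h - trace$entrain_photoperiod_h
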