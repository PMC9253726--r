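#' Configuration for rhythm analysis
#'
#' Bundles the tunable parameters of the period-estimation stage: the
#' interior analysis window, the circadian period range used to pick the
#' reported component, the component budget and stopping confidence of the
#' multicomponent cosine fit, and the replicate-level exclusion thresholds
#' (relative amplitude error and between-replicate period SD).
#'
#' @param analysis_window_h Closed interval of times (hours) analysed.
#' @param circadian_range_h Period range (hours) from which the circadian
#'   component is selected.
#' @param max_components Maximum number of cosine components fitted.
#' @param rae_threshold Strain-mean RAE above which a strain is excluded.
#' @param sd_frp_threshold_h Between-replicate period SD (hours) above
#'   which a strain is excluded.
#' @param confidence_level Confidence level for amplitude intervals (used
#'   both in the component-stopping rule and in the RAE).
#' @param convergence_tol Relative RSS change declaring convergence.
#' @param max_iterations Iteration cap for the damped least-squares fit.
#' @param exclusion_rule `"rae_or_sd"` applies both thresholds (either one
#'   triggers exclusion); `"sd_only"` applies only the period-SD rule.
#' @return A list of class `rhythm_config`.
#' @export
rhythm_config <- function(analysis_window_h = c(60, 132),
                          circadian_range_h = c(15, 35),
                          max_components = 4,
                          rae_threshold = 0.1,
                          sd_frp_threshold_h = 1.5,
                          confidence_level = 0.95,
                          convergence_tol = 1e-10,
                          max_iterations = 200,
                          exclusion_rule = c("rae_or_sd", "sd_only")) {
  stopifnot(length(analysis_window_h) == 2,
            analysis_window_h[1] < analysis_window_h[2],
            length(circadian_range_h) == 2,
            circadian_range_h[1] < circadian_range_h[2],
            max_components >= 1, rae_threshold > 0,
            sd_frp_threshold_h > 0,
            confidence_level > 0, confidence_level < 1,
            convergence_tol > 0, max_iterations >= 1)
  structure(list(analysis_window_h = analysis_window_h,
                 circadian_range_h = circadian_range_h,
                 max_components = as.integer(max_components),
                 rae_threshold = rae_threshold,
                 sd_frp_threshold_h = sd_frp_threshold_h,
                 confidence_level = confidence_level,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 exclusion_rule = match.arg(exclusion_rule)),
            class = "rhythm_config")
}

#' Periodogram seeds for the cosine fit
#'
#' Computes the discrete Fourier periodogram of a (normalized) series and
#' converts its `k` strongest spectral peaks into (period, amplitude,
#' phase) starting values, ordered by descending spectral power. The
#' series is zero-padded (8x, rounded up to a power of two) before the
#' transform so that peak frequencies are localized well below the raw
#' Rayleigh resolution of the short analysis window; seeds are the local
#' maxima of the padded periodogram, excluding zero frequency. Phases are
#' peak-time offsets in hours measured from the first sample.
#'
#' @param values Numeric series on a uniform grid.
#' @param sampling_interval_h Grid spacing in hours.
#' @param k Number of seeds requested.
#' @return Data frame with columns `tau_h`, `amplitude`, `phase_h`, `power`.
#' @export
periodogram_seeds <- function(values, sampling_interval_h, k = 4) {
  n <- length(values)
  if (n < 16) stop("need at least 16 points for periodogram seeding")
  if (all(values == 0)) stop("all-zero input has no spectral content")
  n_pad <- 2^ceiling(log2(8 * n))
  x <- stats::fft(c(values - mean(values), rep(0, n_pad - n)))
  m <- n_pad %/% 2
  power <- Mod(x[2:(m + 1)])^2   # positive frequencies, excluding zero
  # local maxima of the padded periodogram are the spectral peaks
  is_peak <- c(power[1] > power[2],
               power[2:(m - 1)] > power[1:(m - 2)] &
                 power[2:(m - 1)] >= power[3:m],
               power[m] > power[m - 1])
  cand <- which(is_peak)
  if (length(cand) == 0) cand <- seq_len(m)
  cand <- cand[order(power[cand], decreasing = TRUE)]
  take <- cand[seq_len(min(k, length(cand)))]
  tau <- n_pad * sampling_interval_h / take   # take = cycles per padded length
  amp <- 2 * Mod(x[take + 1]) / n
  # y_j ~ A cos(2*pi*f*j*dt - psi), psi = -Arg(X); peak offset = psi*tau/2pi
  psi <- -Arg(x[take + 1])
  phase <- (psi * tau / (2 * pi)) %% tau
  data.frame(tau_h = tau, amplitude = amp, phase_h = phase,
             power = power[take])
}

# Residuals and Jacobian for c0 + sum_m A_m cos(2*pi*(t - phi_m)/tau_m).
mc_model <- function(par, t) {
  m <- (length(par) - 1L) %/% 3L
  y <- rep(par[1], length(t))
  if (m > 0) {
    for (j in seq_len(m)) {
      tau <- par[3 * j - 1]; A <- par[3 * j]; phi <- par[3 * j + 1]
      y <- y + A * cos(2 * pi * (t - phi) / tau)
    }
  }
  y
}

mc_jacobian <- function(par, t) {
  m <- (length(par) - 1L) %/% 3L
  J <- matrix(0, length(t), length(par))
  J[, 1] <- 1
  if (m > 0) {
    for (j in seq_len(m)) {
      tau <- par[3 * j - 1]; A <- par[3 * j]; phi <- par[3 * j + 1]
      u <- 2 * pi * (t - phi) / tau
      J[, 3 * j - 1] <- A * sin(u) * 2 * pi * (t - phi) / tau^2
      J[, 3 * j]     <- cos(u)
      J[, 3 * j + 1] <- A * sin(u) * 2 * pi / tau
    }
  }
  J
}

# Wrap phases to [0, tau) and flip negative amplitudes into the phase.
mc_canonicalize <- function(par) {
  m <- (length(par) - 1L) %/% 3L
  if (m > 0) {
    for (j in seq_len(m)) {
      tau <- par[3 * j - 1]
      if (par[3 * j] < 0) {
        par[3 * j] <- -par[3 * j]
        par[3 * j + 1] <- par[3 * j + 1] + tau / 2
      }
      par[3 * j + 1] <- par[3 * j + 1] %% tau
    }
  }
  par
}

#' Multicomponent cosine fit by FFT-seeded nonlinear least squares
#'
#' Fits \deqn{y(t) = c_0 + \sum_m A_m \cos(2\pi (t - \phi_m)/\tau_m)} by
#' damped (Levenberg--Marquardt) least squares with an analytic Jacobian.
#' Components are added one at a time, each seeded from the strongest
#' frequency of the residual periodogram; a newly added component is kept
#' only when its amplitude is significantly greater than zero at
#' `config$confidence_level` (linearized t-interval from the parameter
#' covariance \eqn{\hat\sigma^2 (J^\top J)^{-1}}); otherwise it is
#' discarded and fitting stops. Negative amplitudes are flipped into the
#' phase, which is wrapped to `[0, tau)`.
#'
#' @param times Sample times in hours (uniform grid).
#' @param values Signal values.
#' @param config A [rhythm_config()].
#' @return An object of class `rhythm_fit`; see [estimate_frp()] for the
#'   fields and available methods.
#' @examples
#' t <- seq(60, 132, by = 1 / 3)
#' y <- 3 + 2 * cos(2 * pi * (t - 5) / 25)
#' fit <- fit_multicomponent_cosine(t, y)
#' coef(fit)
#' @export
fit_multicomponent_cosine <- function(times, values,
                                      config = rhythm_config()) {
  stopifnot(length(times) == length(values), length(times) >= 16)
  dt <- times[2] - times[1]
  n <- length(values)

  ctrl <- minpack.lm::nls.lm.control(
    ftol = config$convergence_tol, ptol = config$convergence_tol,
    maxiter = config$max_iterations)

  fit_par <- function(par) {
    # maxiter overruns are reported via the converged flag, not a warning
    withCallingHandlers(
      minpack.lm::nls.lm(
        par = par,
        fn = function(p) values - mc_model(p, times),
        jac = function(p) -mc_jacobian(p, times),
        control = ctrl),
      warning = function(w) {
        if (grepl("maxiter|info", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }

  make_state <- function(par, converged) {
    par <- mc_canonicalize(par)
    r <- values - mc_model(par, times)
    rss <- sum(r^2)
    p <- length(par)
    J <- mc_jacobian(par, times)
    JtJ <- crossprod(J)
    sigma2 <- if (n > p) rss / (n - p) else 0
    cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) NULL)
    list(par = par, rss = rss, sigma2 = sigma2, cov = cov,
         converged = converged, df = n - p)
  }

  state <- make_state(mean(values), TRUE)  # intercept-only baseline
  n_tested <- 0L
  while ((length(state$par) - 1L) %/% 3L < config$max_components) {
    resid <- values - mc_model(state$par, times)
    seeds <- tryCatch(periodogram_seeds(resid, dt, k = 1),
                      error = function(e) NULL)
    if (is.null(seeds) || seeds$amplitude[1] <= 0) break
    par0 <- c(state$par, seeds$tau_h[1], seeds$amplitude[1],
              seeds$phase_h[1])
    lmfit <- fit_par(par0)
    cand <- make_state(lmfit$par, lmfit$info %in% 1:4)
    n_tested <- n_tested + 1L
    # significance of the newest component's amplitude
    jA <- length(cand$par) - 1L  # amplitude is second-to-last
    ok <- FALSE
    if (!is.null(cand$cov) && cand$df > 0) {
      se <- sqrt(max(cand$cov[jA, jA], 0))
      tcrit <- stats::qt(1 - (1 - config$confidence_level) / 2, cand$df)
      ok <- is.finite(se) && cand$par[jA] > tcrit * se
    } else if (cand$sigma2 == 0 || is.null(cand$cov)) {
      # exact fit (zero residual variance): amplitude trivially significant
      ok <- cand$par[jA] > 0 && cand$sigma2 == 0
    }
    if (!ok) break
    if (cand$rss > state$rss + 1e-12 * max(state$rss, 1)) break
    state <- cand
  }

  m <- (length(state$par) - 1L) %/% 3L
  comps <- if (m > 0) {
    idx <- seq_len(m)
    amp_se <- vapply(idx, function(j) {
      if (is.null(state$cov)) return(NA_real_)
      sqrt(max(state$cov[3 * j, 3 * j], 0))
    }, numeric(1))
    tcrit <- if (state$df > 0) {
      stats::qt(1 - (1 - config$confidence_level) / 2, state$df)
    } else NA_real_
    data.frame(tau_h = state$par[3 * idx - 1],
               amplitude = state$par[3 * idx],
               phase_h = state$par[3 * idx + 1],
               amplitude_se = amp_se,
               amplitude_ci_halfwidth = tcrit * amp_se)
  } else {
    data.frame(tau_h = numeric(0), amplitude = numeric(0),
               phase_h = numeric(0), amplitude_se = numeric(0),
               amplitude_ci_halfwidth = numeric(0))
  }

  structure(list(c0 = unname(state$par[1]),
                 components = comps,
                 n_components = m,
                 rss = state$rss,
                 sigma2 = state$sigma2,
                 df = state$df,
                 n = n,
                 cov = state$cov,
                 par = state$par,
                 converged = state$converged,
                 times = times, values = values,
                 config = config),
            class = "rhythm_fit")
}

#' Relative amplitude error of a fitted component
#'
#' RAE is the half-width of the amplitude confidence interval divided by
#' the fitted amplitude, capped at 1: it increases from 0 (perfectly
#' determined rhythm) to 1 as the rhythm approaches statistical
#' insignificance. The interval is the linearized t-interval
#' \eqn{t_{1-\alpha/2, n-p}\,\widehat{SE}(A)} with
#' \eqn{\widehat{SE}} from \eqn{\hat\sigma^2 (J^\top J)^{-1}} at the
#' optimum.
#'
#' @param fit A `rhythm_fit`.
#' @param component Row index into `fit$components`, or `"circadian"` to
#'   use the circadian component selected by [estimate_frp()].
#' @return A number in `[0, 1]`; 1 (with a warning) when the covariance is
#'   singular.
#' @export
rae <- function(fit, component = 1L) {
  stopifnot(inherits(fit, "rhythm_fit"))
  if (identical(component, "circadian")) {
    component <- attr(fit, "circadian_index")
    if (is.null(component) || is.na(component)) return(1)
  }
  if (fit$n_components < 1 || component > fit$n_components) return(1)
  A <- fit$components$amplitude[component]
  if (!is.finite(A) || A <= 0) return(1)
  half <- fit$components$amplitude_ci_halfwidth[component]
  if (!is.finite(half)) {
    warning("singular parameter covariance; RAE set to 1")
    return(1)
  }
  min(half / A, 1)
}

#' Estimate the free-running period of one trace
#'
#' Restricts a normalized trace to the interior analysis window (default
#' 60--132 h), runs the FFT-seeded multicomponent cosine fit, and selects
#' the circadian component: the fitted component with period inside
#' `config$circadian_range_h` having the largest amplitude. The returned
#' fit carries the period (`tau_h`), amplitude, phase and RAE of that
#' component; when no component falls in the circadian range, `tau_h` is
#' `NA` and `rae` is 1 (arrhythmic).
#'
#' @param trace A normalized [lum_trace] (see [preprocess_trace()]); a raw
#'   trace is accepted and preprocessed with a message.
#' @param config A [rhythm_config()].
#' @return An object of class `c("frp_fit", "rhythm_fit")` with additional
#'   fields `tau_h`, `amplitude`, `phase_h`, `rae`, `strain_id`,
#'   `replicate_id`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' tr <- simulate_luminescence(tau_h = 25, seed = 1)
#' fit <- estimate_frp(preprocess_trace(tr))
#' fit
#' @export
estimate_frp <- function(trace, config = rhythm_config()) {
  stopifnot(inherits(trace, "lum_trace"))
  if (trace$stage != "normalized") {
    message("trace is not normalized; applying preprocess_trace()")
    trace <- preprocess_trace(trace)
  }
  win <- config$analysis_window_h
  dt <- sampling_interval(trace)
  keep <- trace$time_h >= win[1] - dt / 2 & trace$time_h <= win[2] + dt / 2
  if (trace$time_h[1] > win[1] + dt / 2 ||
      trace$time_h[length(trace$time_h)] < win[2] - dt / 2) {
    stop(sprintf("trace (%.4g-%.4g h) does not cover the analysis window %g-%g h",
                 trace$time_h[1], trace$time_h[length(trace$time_h)],
                 win[1], win[2]))
  }
  fit <- fit_multicomponent_cosine(trace$time_h[keep], trace$signal[keep],
                                   config)
  rng <- config$circadian_range_h
  comps <- fit$components
  in_range <- which(comps$tau_h >= rng[1] & comps$tau_h <= rng[2])
  if (length(in_range) > 0) {
    ci <- in_range[which.max(comps$amplitude[in_range])]
    attr(fit, "circadian_index") <- ci
    fit$tau_h <- comps$tau_h[ci]
    fit$amplitude <- comps$amplitude[ci]
    fit$phase_h <- comps$phase_h[ci]
    fit$rae <- rae(fit, ci)
  } else {
    attr(fit, "circadian_index") <- NA_integer_
    fit$tau_h <- NA_real_
    fit$amplitude <- NA_real_
    fit$phase_h <- NA_real_
    fit$rae <- 1
  }
  fit$strain_id <- trace$strain_id
  fit$replicate_id <- trace$replicate_id
  class(fit) <- c("frp_fit", class(fit))
  fit
}

#' @export
print.rhythm_fit <- function(x, digits = 4, ...) {
  cat("Multicomponent cosine fit (", x$n_components, " component",
      if (x$n_components != 1) "s", ", n = ", x$n, ")\n", sep = "")
  cat("  mesor c0 =", format(x$c0, digits = digits),
      "  RSS =", format(x$rss, digits = digits),
      if (!x$converged) "  [not converged]", "\n")
  if (x$n_components > 0) {
    print(format(x$components[c("tau_h", "amplitude", "phase_h")],
                 digits = digits), ...)
  }
  invisible(x)
}

#' @export
print.frp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("FRP estimate for %s/%s\n", x$strain_id, x$replicate_id))
  if (is.na(x$tau_h)) {
    cat("  no circadian component in range; RAE = 1 (arrhythmic)\n")
  } else {
    cat(sprintf("  period tau = %.*g h, amplitude = %.*g, phase = %.*g h, RAE = %.3g\n",
                digits, x$tau_h, digits, x$amplitude, digits, x$phase_h,
                x$rae))
  }
  cat(sprintf("  %d component(s), RSS = %.4g%s\n", x$n_components, x$rss,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' @export
coef.rhythm_fit <- function(object, ...) {
  out <- c(c0 = object$c0)
  if (object$n_components > 0) {
    for (j in seq_len(object$n_components)) {
      v <- unlist(object$components[j, c("tau_h", "amplitude", "phase_h")])
      names(v) <- paste0(c("tau_h", "amplitude", "phase_h"), j)
      out <- c(out, v)
    }
  }
  out
}

#' @export
fitted.rhythm_fit <- function(object, ...) {
  mc_model(object$par, object$times)
}

#' @export
residuals.rhythm_fit <- function(object, ...) {
  object$values - fitted(object)
}

#' @param newdata Optional numeric vector of times (hours) at which to
#'   evaluate the fitted curve.
#' @rdname estimate_frp
#' @export
predict.rhythm_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times else as.numeric(newdata)
  mc_model(object$par, t)
}

#' @export
summary.rhythm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rhythm_fit")
}

#' @export
print.summary.rhythm_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$n_components > 0) {
    cat("Amplitude CIs (half-widths):",
        paste(format(f$components$amplitude_ci_halfwidth, digits = 3),
              collapse = ", "), "\n")
  }
  cat("sigma^2 =", format(f$sigma2, digits = 4), "on", f$df,
      "residual df\n")
  invisible(x)
}

#' @export
plot.rhythm_fit <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", col = "grey50",
                 xlab = "time (h)", ylab = "normalized signal", ...)
  graphics::lines(x$times, fitted(x), col = "firebrick", lwd = 2)
  invisible(x)
}
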