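#' External-coincidence gate model
#'
#' A minimal quantitative rendering of clock-gated, dark-permitted floral
#' induction: the florigen-induction gate opens `d0_h` hours after
#' lights-off in a 24-h entrained strain, and the gate delay shifts by `k`
#' hours per hour of free-running period above 24 h. Flowering is induced
#' when the gate falls in darkness, i.e. when the night length `24 - DL`
#' exceeds the gate delay, so the predicted critical day length is
#' \deqn{CDL(\tau) = 24 - (d_0 + k\,(\tau - 24)).}
#' With `k > 0` a longer period delays the gate and shortens the CDL,
#' giving the negative period--CDL relationship. This is a toy phenotype
#' model, not an inference about molecular mechanism.
#'
#' @param d0_h Gate delay after lights-off at `tau = 24` h, hours
#'   (0 < d0_h < 24).
#' @param k Gate-delay change per hour of `(tau - 24)`; expected >= 0
#'   under the gate hypothesis (a negative fit is flagged, not hidden).
#' @return Object of class `gate_model` with fields `d0_h`, `k`, and
#'   `consistent` (TRUE when `k >= 0`). Methods: `print`, `coef`,
#'   `predict`.
#' @examples
#' gm <- gate_model(d0_h = 11, k = 1)
#' predicted_cdl(gm, c(24, 26))  # 13, 11
#' @export
gate_model <- function(d0_h, k) {
  stopifnot(is.finite(d0_h), d0_h > 0, d0_h < 24, is.finite(k))
  consistent <- k >= 0
  if (!consistent) {
    warning("k < 0: fitted gate shift is inconsistent with the gate ",
            "hypothesis (longer period should delay the gate)")
  }
  structure(list(d0_h = d0_h, k = k, consistent = consistent),
            class = "gate_model")
}

#' Predicted critical day length under the gate model
#'
#' @param model A [gate_model()].
#' @param tau_h Free-running period(s), hours (> 0).
#' @return Predicted CDL(s) in hours, clamped to (0, 24) with a warning
#'   when the linear rule leaves that range.
#' @export
predicted_cdl <- function(model, tau_h) {
  stopifnot(inherits(model, "gate_model"), all(tau_h > 0))
  cdl <- 24 - (model$d0_h + model$k * (tau_h - 24))
  out_of_range <- cdl <= 0 | cdl >= 24
  if (any(out_of_range)) {
    warning("predicted CDL outside (0, 24) h for some periods; clamped")
    eps <- 1e-8
    cdl <- pmin(pmax(cdl, eps), 24 - eps)
  }
  cdl
}

#' @param newdata Numeric periods (hours).
#' @rdname gate_model
#' @export
predict.gate_model <- function(object, newdata, ...) {
  predicted_cdl(object, newdata)
}

#' @export
print.gate_model <- function(x, digits = 4, ...) {
  cat("External-coincidence gate model\n")
  cat(sprintf("  gate delay after dusk at tau = 24 h: d0 = %s h\n",
              format(x$d0_h, digits = digits)))
  cat(sprintf("  delay shift per hour of (tau - 24): k = %s\n",
              format(x$k, digits = digits)))
  cat(sprintf("  predicted CDL(tau) = 24 - (d0 + k (tau - 24))%s\n",
              if (!x$consistent) "  [k < 0: inconsistent]" else ""))
  invisible(x)
}

#' @export
coef.gate_model <- function(object, ...) {
  c(d0_h = object$d0_h, k = object$k)
}

#' Fit the gate model to observed period--CDL pairs
#'
#' Fits a Deming line (errors in both variables, `delta = 1`) of CDL on
#' period and reparameterizes it exactly as a gate model:
#' `k = -slope`, `d0 = 24 - (intercept + 24 * slope)`, so that
#' `predicted_cdl(fit, tau)` reproduces the Deming line for every `tau`.
#' A positive regression slope yields `k < 0`, which is returned flagged as
#' inconsistent with the gate hypothesis rather than hidden.
#'
#' @param tau_h,cdl_h Paired observations (>= 3 complete pairs).
#' @param delta Error-variance ratio for the Deming fit.
#' @return A [gate_model()] with an additional `deming` field holding the
#'   underlying line fit.
#' @examples
#' tau <- c(23, 24, 25, 26)
#' fit_gate_model(tau, 13 - (tau - 24))  # d0 = 11, k = 1
#' @export
fit_gate_model <- function(tau_h, cdl_h, delta = 1) {
  dm <- deming_fit(tau_h, cdl_h, delta)
  k <- -dm$slope
  d0 <- 24 - (dm$intercept + 24 * dm$slope)
  gm <- gate_model(d0_h = d0, k = k)
  gm$deming <- dm
  gm
}
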