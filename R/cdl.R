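#' Pooled flowering rates by day length
#'
#' Computes the flowering rate at each tested day length, either pooling
#' counts across replicates (default: rate = 100 * sum(flowering) /
#' sum(total), weighting wells by frond number) or averaging the
#' per-replicate percentages.
#'
#' @param assay A `flowering_assay` data frame (columns `day_length_h`,
#'   `n_flowering`, `n_total`, optionally `strain_id`, `replicate_id`).
#' @param mode `"pooled"` or `"averaged"`.
#' @return Data frame with columns `day_length_h` and `rate_pct`, sorted
#'   by day length.
#' @examples
#' fa <- data.frame(day_length_h = c(12, 12), n_flowering = c(3, 5),
#'                  n_total = c(10, 10))
#' pooled_rates(fa)  # 40 percent
#' @export
pooled_rates <- function(assay, mode = c("pooled", "averaged")) {
  mode <- match.arg(mode)
  stopifnot(all(c("day_length_h", "n_flowering", "n_total") %in%
                  names(assay)))
  if (any(assay$n_flowering < 0) || any(assay$n_flowering > assay$n_total)) {
    stop("n_flowering must lie in [0, n_total]")
  }
  if (any(assay$n_total < 1)) stop("n_total must be >= 1 in every record")
  sp <- split(assay, assay$day_length_h)
  dl <- as.numeric(names(sp))
  rate <- vapply(sp, function(d) {
    if (mode == "pooled") 100 * sum(d$n_flowering) / sum(d$n_total)
    else mean(100 * d$n_flowering / d$n_total)
  }, numeric(1))
  ord <- order(dl)
  data.frame(day_length_h = dl[ord], rate_pct = unname(rate[ord]))
}

#' Estimate the critical day length from flowering rates
#'
#' Determines the critical day length (CDL) of a short-day flowering
#' response as the day length where 50 percent of the maximum flowering
#' rate (Fmax) is expected under a piecewise-linear function: the pooled
#' rates are linearly interpolated over the sorted day lengths, and the CDL
#' is the first downward crossing of Fmax/2 at or after the day length
#' attaining Fmax (the descending limb of the response). When the
#' interpolated curve never falls to Fmax/2 after the maximum the CDL is
#' right-censored (longer than the longest tested day length).
#'
#' @param x A `flowering_assay` data frame, or a rates table as returned by
#'   [pooled_rates()].
#' @param mode Replicate handling passed to [pooled_rates()] when `x` is an
#'   assay.
#' @param strain_id Label; taken from `x` when present.
#' @return An object of class `cdl_fit` with fields `strain_id`, `cdl_h`
#'   (NA when censored or undefined), `censored` (`"none"`, `"right"` or
#'   `"undefined"`), `fmax_pct`, `crossing_segment` (bracketing day-length
#'   pair) and `rates` (the pooled rates table). Methods: `print`, `coef`,
#'   `plot`, `predict` (interpolated rate at new day lengths).
#' @examples
#' r <- data.frame(day_length_h = c(12, 12.5, 13), rate_pct = c(100, 75, 0))
#' estimate_cdl(r)  # CDL 12.667 h
#' @export
estimate_cdl <- function(x, mode = c("pooled", "averaged"),
                         strain_id = NULL) {
  mode <- match.arg(mode)
  if (is.null(strain_id)) {
    strain_id <- if ("strain_id" %in% names(x)) as.character(x$strain_id[1])
    else "strain"
  }
  rates <- if ("rate_pct" %in% names(x)) {
    x[order(x$day_length_h), c("day_length_h", "rate_pct"), drop = FALSE]
  } else {
    pooled_rates(x, mode)
  }
  if (nrow(rates) < 2) stop("need at least two distinct day lengths")
  if (anyDuplicated(rates$day_length_h)) stop("duplicate day lengths")

  dl <- rates$day_length_h
  r <- rates$rate_pct
  fmax <- max(r)
  res <- list(strain_id = strain_id, fmax_pct = fmax, rates = rates,
              cdl_h = NA_real_, censored = "none",
              crossing_segment = c(NA_real_, NA_real_))

  if (fmax <= 0) {
    res$censored <- "undefined"
    warning("no flowering at any day length; CDL undefined for ", strain_id)
    class(res) <- "cdl_fit"
    return(res)
  }

  half <- fmax / 2
  imax <- which.max(r)  # first day length attaining Fmax
  cdl <- NA_real_
  seg <- c(NA_real_, NA_real_)
  if (r[imax] == half) {  # degenerate: fmax == 0 handled above
    cdl <- dl[imax]
    seg <- c(dl[imax], dl[imax])
  } else {
    for (i in seq(imax, length(dl) - 1L)) {
      if (r[i] >= half && r[i + 1L] <= half) {
        if (r[i] == r[i + 1L]) next  # flat at half: keep scanning
        cdl <- dl[i] + (dl[i + 1L] - dl[i]) * (r[i] - half) /
          (r[i] - r[i + 1L])
        seg <- c(dl[i], dl[i + 1L])
        break
      }
    }
  }
  if (is.na(cdl)) {
    res$censored <- "right"
  } else {
    res$cdl_h <- cdl
    res$crossing_segment <- seg
  }
  class(res) <- "cdl_fit"
  res
}

#' @export
print.cdl_fit <- function(x, ...) {
  cat("Critical day length for", x$strain_id, "\n")
  cat(sprintf("  Fmax = %.3g%%", x$fmax_pct))
  if (x$censored == "none") {
    cat(sprintf("; CDL = %.4g h (crossing in [%g, %g] h)\n",
                x$cdl_h, x$crossing_segment[1], x$crossing_segment[2]))
  } else if (x$censored == "right") {
    cat(sprintf("; CDL > %g h (right-censored)\n",
                max(x$rates$day_length_h)))
  } else {
    cat("; CDL undefined (no flowering)\n")
  }
  invisible(x)
}

#' @export
coef.cdl_fit <- function(object, ...) {
  c(cdl_h = object$cdl_h, fmax_pct = object$fmax_pct)
}

#' @param newdata Numeric day lengths at which to evaluate the
#'   piecewise-linear flowering response.
#' @rdname estimate_cdl
#' @export
predict.cdl_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$rates$day_length_h
  stats::approx(object$rates$day_length_h, object$rates$rate_pct,
                xout = newdata, rule = 2)$y
}

#' @export
plot.cdl_fit <- function(x, ...) {
  graphics::plot(x$rates$day_length_h, x$rates$rate_pct, type = "b",
                 pch = 16, xlab = "day length (h)",
                 ylab = "flowering rate (%)",
                 main = paste("CDL:", x$strain_id), ...)
  graphics::abline(h = x$fmax_pct / 2, lty = 3)
  if (x$censored == "none") {
    graphics::abline(v = x$cdl_h, lty = 2, col = "firebrick")
  }
  invisible(x)
}

#' Critical night length
#'
#' For a short-day plant, floral induction requires the night to exceed a
#' critical duration; under a 24-h cycle this is simply `24 - CDL`.
#'
#' @param cdl_h Critical day length(s), hours.
#' @return Critical night length(s), hours.
#' @export
critical_night_length <- function(cdl_h) 24 - cdl_h
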