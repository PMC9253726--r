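#' Aggregate replicate period estimates for one strain
#'
#' Combines per-replicate FRP fits into the strain-level phenotype: mean
#' and sample SD of the replicate periods, mean RAE, and the exclusion
#' flag. A strain is excluded when its mean RAE exceeds
#' `config$rae_threshold` (default 0.1) or its between-replicate period SD
#' exceeds `config$sd_frp_threshold_h` (default 1.5 h) or any replicate
#' lacks a circadian component; with `exclusion_rule = "sd_only"` only the
#' SD rule (plus the missing-component rule) applies. The mean (not the
#' maximum) RAE across replicates is the thresholded quantity, because
#' strain-level rhythm quality is reported as the replicate mean.
#'
#' @param fits List of `frp_fit` objects for one strain (typically 3
#'   replicates), or a data frame with columns `tau_h` and `rae` (and
#'   optionally `first_peak_h`).
#' @param config A [rhythm_config()].
#' @param strain_id Strain label; taken from the fits when omitted.
#' @param first_peak_h Optional numeric vector of per-replicate first-LL
#'   peak times (hours since final dawn) to average into the phenotype.
#' @return A one-row data frame of class `strain_rhythm` with columns
#'   `strain_id`, `n_replicates`, `mean_frp_h`, `sd_frp_h`, `mean_rae`,
#'   `first_peak_mean_h`, `excluded`, `reason`.
#' @examples
#' d <- data.frame(tau_h = c(24.0, 24.2, 24.4), rae = c(0.03, 0.04, 0.05))
#' aggregate_replicates(d, strain_id = "demo")
#' @export
aggregate_replicates <- function(fits, config = rhythm_config(),
                                 strain_id = NULL, first_peak_h = NULL) {
  if (is.data.frame(fits)) {
    tab <- fits
    if (is.null(first_peak_h) && "first_peak_h" %in% names(tab)) {
      first_peak_h <- tab$first_peak_h
    }
  } else {
    stopifnot(length(fits) >= 1,
              all(vapply(fits, inherits, logical(1), "frp_fit")))
    tab <- data.frame(
      tau_h = vapply(fits, function(f) f$tau_h, numeric(1)),
      rae = vapply(fits, function(f) f$rae, numeric(1)))
    if (is.null(strain_id)) strain_id <- fits[[1]]$strain_id
  }
  if (nrow(tab) == 0) stop("no replicate estimates supplied")
  if (is.null(strain_id)) strain_id <- "strain"

  missing_comp <- any(is.na(tab$tau_h))
  mean_frp <- if (missing_comp) NA_real_ else mean(tab$tau_h)
  sd_frp <- if (missing_comp || nrow(tab) < 2) NA_real_ else
    stats::sd(tab$tau_h)
  mean_rae <- mean(tab$rae)
  fp_mean <- if (is.null(first_peak_h)) NA_real_ else
    mean(first_peak_h, na.rm = TRUE)

  reasons <- character(0)
  if (missing_comp) reasons <- c(reasons, "no_circadian_component")
  if (config$exclusion_rule == "rae_or_sd" &&
      is.finite(mean_rae) && mean_rae > config$rae_threshold) {
    reasons <- c(reasons, "rae")
  }
  if (is.finite(sd_frp) && sd_frp > config$sd_frp_threshold_h) {
    reasons <- c(reasons, "sd_frp")
  }
  out <- data.frame(strain_id = strain_id,
                    n_replicates = nrow(tab),
                    mean_frp_h = mean_frp,
                    sd_frp_h = sd_frp,
                    mean_rae = mean_rae,
                    first_peak_mean_h = fp_mean,
                    excluded = length(reasons) > 0,
                    reason = paste(reasons, collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("strain_rhythm", "data.frame")
  out
}

#' Rhythm analysis for a set of traces
#'
#' Runs the full rhythm pipeline over a list of raw traces: preprocess
#' (detrend + normalize), peak detection with the first-LL-peak phenotype,
#' period estimation, and per-strain aggregation with the exclusion rule.
#'
#' @param traces List of raw [lum_trace] objects.
#' @param config A [rhythm_config()].
#' @param peaks_on `"detrended"` (default) or `"raw"`: which stage the peak
#'   detector runs on.
#' @return List with `replicates` (one row per trace: strain, replicate,
#'   tau_h, rae, amplitude, phase_h, first_peak_h, converged) and `strains`
#'   (one `strain_rhythm` row per strain).
#' @export
analyze_rhythms <- function(traces, config = rhythm_config(),
                            peaks_on = c("detrended", "raw")) {
  peaks_on <- match.arg(peaks_on)
  stopifnot(length(traces) >= 1)
  rows <- lapply(traces, function(tr) {
    det <- moving_average_detrend(tr)
    norm <- moving_sd_normalize(det)
    pk_trace <- if (peaks_on == "detrended") det else tr
    pk <- detect_peaks(pk_trace)
    fp <- suppressWarnings(first_peak_in_ll(pk, pk_trace))
    fit <- estimate_frp(norm, config)
    data.frame(strain_id = tr$strain_id, replicate_id = tr$replicate_id,
               tau_h = fit$tau_h, rae = fit$rae,
               amplitude = fit$amplitude, phase_h = fit$phase_h,
               first_peak_h = fp, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  replicates <- do.call(rbind, rows)
  rownames(replicates) <- NULL
  strains <- do.call(rbind, lapply(split(replicates, replicates$strain_id),
                                   function(d) {
    aggregate_replicates(d, config, strain_id = d$strain_id[1])
  }))
  rownames(strains) <- NULL
  class(strains) <- c("strain_rhythm", "data.frame")
  list(replicates = replicates, strains = strains)
}
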