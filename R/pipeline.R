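#' Pipeline configuration
#'
#' Collects the options of the end-to-end analysis: input sources (file
#' paths or in-memory objects), the rhythm-analysis configuration, CDL
#' options, association options, and the seed recorded in output headers.
#'
#' @param traces List of [lum_trace] objects, or the path of a
#'   luminescence table.
#' @param flowering List of `flowering_assay` data frames, or the path of
#'   a flowering table.
#' @param metadata Optional data frame with columns `strain_id`,
#'   `population_id`, `latitude_deg` merged into the phenotype records.
#' @param rhythm A [rhythm_config()].
#' @param cdl_mode Replicate handling for flowering rates (`"pooled"` or
#'   `"averaged"`).
#' @param delta Error-variance ratio for Deming fits.
#' @param alpha Significance level for letter displays.
#' @param seed Seed recorded in output headers (no randomness is used by
#'   the pipeline itself).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(traces = NULL, flowering = NULL,
                            metadata = NULL,
                            rhythm = rhythm_config(),
                            cdl_mode = c("pooled", "averaged"),
                            delta = 1, alpha = 0.05, seed = 1) {
  cdl_mode <- match.arg(cdl_mode)
  stopifnot(inherits(rhythm, "rhythm_config"), delta > 0,
            alpha > 0, alpha < 1)
  if (is.character(traces) && !file.exists(traces)) {
    stop("trace file not found: ", traces)
  }
  if (is.character(flowering) && !file.exists(flowering)) {
    stop("flowering file not found: ", flowering)
  }
  structure(list(traces = traces, flowering = flowering,
                 metadata = metadata, rhythm = rhythm,
                 cdl_mode = cdl_mode, delta = delta, alpha = alpha,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end analysis
#'
#' Ties the stages together: read (or accept) luminescence traces and
#' flowering assays, quantify rhythms per replicate and per strain with
#' the exclusion rule, estimate each strain's critical day length, merge
#' into phenotype records, and run the association analyses and the gate
#' model fit. Deterministic given inputs and configuration.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: a list with elements
#'   `replicates`, `strains`, `cdl` (per-strain CDL table), `records`
#'   (merged phenotype table), `association` (a `panel_association`, or
#'   NULL when fewer than 3 usable strains), `gate` (a `gate_model`, or
#'   NULL likewise) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  traces <- config$traces
  if (is.character(traces)) traces <- read_luminescence_table(traces)
  assays <- config$flowering
  if (is.character(assays)) assays <- read_flowering_table(assays)
  if (is.null(traces) || length(traces) == 0) stop("no traces supplied")
  if (is.null(assays) || length(assays) == 0) {
    stop("no flowering assays supplied")
  }

  rhythms <- analyze_rhythms(traces, config$rhythm)

  cdl_fits <- lapply(assays, estimate_cdl, mode = config$cdl_mode)
  cdl_tab <- do.call(rbind, lapply(cdl_fits, function(f) {
    data.frame(strain_id = f$strain_id, cdl_h = f$cdl_h,
               censored = f$censored, fmax_pct = f$fmax_pct,
               stringsAsFactors = FALSE)
  }))
  rownames(cdl_tab) <- NULL

  records <- merge(rhythms$strains, cdl_tab, by = "strain_id",
                   all = TRUE)
  records$cdl_censored <- records$censored != "none"
  if (!is.null(config$metadata)) {
    records <- merge(records, config$metadata, by = "strain_id",
                     all.x = TRUE)
  }
  excluded <- records$strain_id[records$excluded %in% TRUE]
  if (length(excluded) > 0) {
    message("excluded strains (unstable rhythms): ",
            paste(excluded, collapse = ", "))
  }

  assoc <- tryCatch(panel_association(records, config$delta),
                    error = function(e) {
                      warning("association skipped: ", conditionMessage(e))
                      NULL
                    })
  gate <- NULL
  ok <- !records$excluded %in% TRUE & is.finite(records$mean_frp_h) &
    is.finite(records$cdl_h) & !records$cdl_censored
  if (sum(ok) >= 3) {
    gate <- tryCatch(
      fit_gate_model(records$mean_frp_h[ok], records$cdl_h[ok],
                     config$delta),
      warning = function(w) {
        suppressWarnings(fit_gate_model(records$mean_frp_h[ok],
                                        records$cdl_h[ok], config$delta))
      })
  }

  structure(list(replicates = rhythms$replicates,
                 strains = rhythms$strains,
                 cdl = cdl_tab, records = records,
                 association = assoc, gate = gate, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("lemnaclock pipeline result\n")
  cat(sprintf("  %d replicate traces, %d strains (%d excluded)\n",
              nrow(x$replicates), nrow(x$strains), sum(x$strains$excluded)))
  cat(sprintf("  CDL estimated for %d strains (%d censored/undefined)\n",
              nrow(x$cdl), sum(x$cdl$censored != "none")))
  if (!is.null(x$association)) print(x$association)
  if (!is.null(x$gate)) {
    cat(sprintf("  gate model: d0 = %.3g h, k = %.3g\n",
                x$gate$d0_h, x$gate$k))
  }
  invisible(x)
}

#' Write pipeline result tables
#'
#' Writes the replicate, strain, CDL and merged-record tables as
#' comma-separated text files, each with a `#` header carrying the package
#' version, the configured seed and a configuration hash so that outputs
#' are traceable to the run that produced them.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# lemnaclock %s seed=%s config_hash=%s",
                 as.character(utils::packageVersion("lemnaclock")),
                 result$config$seed, config_hash(result$config))
  tabs <- list(replicates = result$replicates, strains = result$strains,
               cdl = result$cdl, records = result$records)
  for (nm in names(tabs)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(tabs[[nm]], con, row.names = FALSE)
    close(con)
  }
  invisible(dir)
}

# FNV-1a hash of the deparsed configuration options (not the data).
config_hash <- function(config) {
  opts <- config[setdiff(names(config), c("traces", "flowering",
                                          "metadata"))]
  s <- paste(deparse(opts), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
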