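#' Read a luminescence table into traces
#'
#' Reads a long-format delimited text file (comma-separated, UTF-8, header
#' `strain,replicate,time_h,signal,ll_start_h`, optionally
#' `entrain_photoperiod_h`; `#` lines are comments) and returns one
#' validated [lum_trace] per (strain, replicate). Malformed input is
#' rejected, never coerced: a duplicated or missing timestamp, a negative
#' signal, or a non-uniform grid raises an error naming the offending
#' strain/replicate and time.
#'
#' @param path File path.
#' @return Named list of [lum_trace] objects (`strain/replicate` names).
#' @export
read_luminescence_table <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("strain", "replicate", "time_h", "signal", "ll_start_h")
  if (!all(req %in% names(d))) {
    stop("luminescence table must have columns: ",
         paste(req, collapse = ", "))
  }
  if (nrow(d) == 0) {
    warning("empty luminescence table: ", path)
    return(list())
  }
  if (any(!is.finite(d$signal)) || any(d$signal < 0)) {
    stop("negative or non-finite signal values in ", path)
  }
  ep <- if ("entrain_photoperiod_h" %in% names(d)) d$entrain_photoperiod_h
  else rep(15, nrow(d))
  key <- paste(d$strain, d$replicate, sep = "/")
  out <- lapply(split(seq_len(nrow(d)), key), function(idx) {
    dd <- d[idx, ]
    dd <- dd[order(dd$time_h), ]
    if (anyDuplicated(dd$time_h)) {
      t_dup <- dd$time_h[which(duplicated(dd$time_h))[1]]
      stop(sprintf("duplicated timestamp t = %g for %s/%s",
                   t_dup, dd$strain[1], dd$replicate[1]))
    }
    lum_trace(dd$strain[1], dd$replicate[1], dd$time_h, dd$signal,
              ll_start_h = dd$ll_start_h[1],
              entrain_photoperiod_h = ep[idx][1])
  })
  out[order(names(out))]
}

#' Write traces as a luminescence table
#'
#' Inverse of [read_luminescence_table()]; a `#` header records the seed
#' when one is supplied.
#'
#' @param traces List of [lum_trace] objects.
#' @param path Output file path.
#' @param seed Optional seed to record in the file header.
#' @return `path`, invisibly.
#' @export
write_luminescence_table <- function(traces, path, seed = NULL) {
  rows <- lapply(traces, function(tr) {
    data.frame(strain = tr$strain_id, replicate = tr$replicate_id,
               time_h = tr$time_h, signal = tr$signal,
               ll_start_h = tr$ll_start_h,
               entrain_photoperiod_h = tr$entrain_photoperiod_h,
               stringsAsFactors = FALSE)
  })
  write_table_with_header(do.call(rbind, rows), path, seed)
}

#' Read a flowering-assay table
#'
#' Reads a delimited text file with header
#' `strain,day_length_h,replicate,n_flowering,n_total` and returns one
#' validated `flowering_assay` data frame per strain. Count
#' inconsistencies are rejected with the offending row number.
#'
#' @param path File path.
#' @return Named list of `flowering_assay` data frames.
#' @export
read_flowering_table <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("strain", "day_length_h", "replicate", "n_flowering", "n_total")
  if (!all(req %in% names(d))) {
    stop("flowering table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(d) == 0) {
    warning("empty flowering table: ", path)
    return(list())
  }
  bad <- which(d$n_flowering > d$n_total | d$n_flowering < 0 |
                 d$n_total < 1)
  if (length(bad) > 0) {
    stop("invalid counts (n_flowering > n_total, negative, or n_total < 1) ",
         "at row ", bad[1])
  }
  out <- lapply(split(d, d$strain), function(dd) {
    a <- data.frame(strain_id = dd$strain, day_length_h = dd$day_length_h,
                    replicate_id = as.character(dd$replicate),
                    n_flowering = dd$n_flowering, n_total = dd$n_total,
                    stringsAsFactors = FALSE)
    a <- a[order(a$day_length_h, a$replicate_id), ]
    rownames(a) <- NULL
    class(a) <- c("flowering_assay", "data.frame")
    a
  })
  out[order(names(out))]
}

#' Write flowering assays as a table
#'
#' @param assays List of (or a single) `flowering_assay` data frame(s).
#' @param path Output file path.
#' @param seed Optional seed to record in the file header.
#' @return `path`, invisibly.
#' @export
write_flowering_table <- function(assays, path, seed = NULL) {
  if (is.data.frame(assays)) assays <- list(assays)
  d <- do.call(rbind, lapply(assays, function(a) {
    data.frame(strain = a$strain_id, day_length_h = a$day_length_h,
               replicate = a$replicate_id, n_flowering = a$n_flowering,
               n_total = a$n_total, stringsAsFactors = FALSE)
  }))
  write_table_with_header(d, path, seed)
}

write_table_with_header <- function(d, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lemnaclock %s%s",
                     as.character(utils::packageVersion("lemnaclock")),
                     if (!is.null(seed)) paste0(" seed=", seed) else ""),
             con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}
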