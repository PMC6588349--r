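#' Construct a single-channel intensity trace
#'
#' A uniformly sampled fluorescence (or current) time series for one spot or
#' one recording. Time must be strictly increasing with constant spacing
#' (tolerance 1 part in 1e3) and all intensities finite.
#'
#' @param trace_id identifier.
#' @param time_s numeric vector of sample times in seconds.
#' @param intensity numeric vector, same length as `time_s`.
#' @param channel text tag (e.g. "bleach", "donor", "current").
#' @return object of class `intensity_trace`.
#' @export
intensity_trace <- function(trace_id, time_s, intensity, channel = "intensity") {
  if (length(time_s) != length(intensity)) {
    stop("time_s and intensity must have the same length")
  }
  if (length(time_s) < 10L) {
    stop("trace '", trace_id, "' has ", length(time_s), " samples; need at least 10")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    stop("trace '", trace_id, "': time_s must be strictly increasing")
  }
  if ((max(dt) - min(dt)) > 1e-3 * stats::median(dt)) {
    stop("trace '", trace_id, "': sampling must be uniform to 1 part in 1e3")
  }
  if (!all(is.finite(intensity))) {
    stop("trace '", trace_id, "': all intensities must be finite")
  }
  structure(
    list(trace_id = as.character(trace_id), time_s = as.numeric(time_s),
         intensity = as.numeric(intensity), channel = channel),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace '%s' (%s): %d samples, %.3g-%.3g s\n",
              x$trace_id, x$channel, length(x$time_s),
              x$time_s[1], x$time_s[length(x$time_s)]))
  invisible(x)
}

# column schemas for the plain-text interchange tables
.table_schemas <- list(
  trace  = c("trace_id", "time_s", "intensity"),
  fret   = c("time_s", "donor", "acceptor"),
  dose   = c("concentration_uM", "response", "replicate"),
  quench = c("time_ms", "fluorescence", "trial_id", "quencher"),
  epochs = c("label", "start_s", "end_s", "drug", "concentration_uM")
)

#' Read a tidy trace/series table with validation
#'
#' All interchange is via comma-separated text with a header row, '.'
#' decimal, UTF-8. Malformed rows are reported with their line numbers
#' (line 1 is the header).
#'
#' @param path file path.
#' @param schema one of `"trace"` (columns trace_id, time_s, intensity and
#'   optionally channel), `"fret"` (time_s, donor, acceptor), `"dose"`
#'   (concentration_uM, response, replicate), `"quench"` (time_ms,
#'   fluorescence, trial_id, quencher), `"epochs"` (label, start_s, end_s,
#'   drug, concentration_uM).
#' @return for `"trace"`, a named list of [intensity_trace()] objects; for
#'   the other schemas, a validated data.frame.
#' @export
read_trace_table <- function(path, schema = c("trace", "fret", "dose", "quench", "epochs")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- .table_schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s) for schema '", schema, "': ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop(path, ": table is empty")
  num_cols <- switch(schema,
    trace  = c("time_s", "intensity"),
    fret   = c("time_s", "donor", "acceptor"),
    dose   = c("concentration_uM", "response"),
    quench = c("time_ms", "fluorescence"),
    epochs = c("start_s", "end_s", "concentration_uM"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(path, ": non-finite or non-numeric value in column '", cc,
           "' at line(s) ", paste(utils::head(bad + 1L, 5), collapse = ", "))
    }
    df[[cc]] <- v
  }
  if (schema == "trace") {
    if (!"channel" %in% names(df)) df$channel <- "intensity"
    ids <- unique(df$trace_id)
    traces <- lapply(ids, function(id) {
      rows <- which(df$trace_id == id)
      tt <- df$time_s[rows]
      if (any(diff(tt) <= 0)) {
        k <- rows[which(diff(tt) <= 0)[1] + 1L]
        stop(path, ": time_s not strictly increasing for trace '", id,
             "' at line ", k + 1L)
      }
      intensity_trace(id, tt, df$intensity[rows], channel = df$channel[rows[1]])
    })
    names(traces) <- ids
    return(traces)
  }
  if (schema == "fret" && any(diff(df$time_s) <= 0)) {
    k <- which(diff(df$time_s) <= 0)[1] + 1L
    stop(path, ": time_s not strictly increasing at line ", k + 1L)
  }
  if (schema == "quench") {
    df$quencher <- as.logical(df$quencher)
    if (anyNA(df$quencher)) stop(path, ": column 'quencher' must be logical (TRUE/FALSE)")
  }
  df
}

#' Write traces or series to a tidy CSV table
#'
#' @param x a list of [intensity_trace()] objects, a single trace, a
#'   `fret_series`, or a data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  if (inherits(x, "intensity_trace")) x <- list(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "intensity_trace")) {
    df <- do.call(rbind, lapply(x, function(tr) {
      data.frame(trace_id = tr$trace_id, time_s = tr$time_s,
                 intensity = tr$intensity, channel = tr$channel)
    }))
  } else if (inherits(x, "fret_series")) {
    df <- data.frame(time_s = x$time_s, donor = x$donor, acceptor = x$acceptor)
  } else if (is.data.frame(x)) {
    df <- x
  } else {
    stop("don't know how to write an object of class ", paste(class(x), collapse = "/"))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
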