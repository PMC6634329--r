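#' Read a pupil trace from TSV/CSV
#'
#' Expects a header with columns `time_ms` and `pupil` and optional
#' `blink` and `valid` columns (0/1). Missing pupil values (empty cells
#' or NaN) become invalid samples; an explicit `valid` column (written by
#' [write_pupil_trace()] to preserve the mask of interpolated samples)
#' is combined with the missing-value rule. Header comment lines written
#' by [write_pupil_trace()] restore the block id and standardization
#' flag.
#'
#' @param path file path; tab- or comma-separated, sniffed from the header.
#' @param sample_rate sampling rate in Hz (default 1000); the file's time
#'   column must advance in constant steps of `1000 / sample_rate` ms.
#' @param block_id block label; defaults to the file name without
#'   extension.
#' @return A [pupil_trace()].
#' @export
read_pupil_trace <- function(path, sample_rate = 1000, block_id = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  standardized <- any(grepl("standardized:\\s*true", meta,
                            ignore.case = TRUE))
  if (is.null(block_id)) {
    m <- grep("block_id:", meta, value = TRUE)
    block_id <- if (length(m)) trimws(sub(".*block_id:", "", m[1]))
                else sub("\\.[^.]*$", "", basename(path))
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("file has no header row: ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          na.strings = c("", "NA", "NaN"),
                          stringsAsFactors = FALSE)
  need <- c("time_ms", "pupil")
  if (!all(need %in% names(df)))
    stop("malformed header: need columns time_ms, pupil in ", path)
  if (nrow(df) == 0)
    return(pupil_trace(numeric(0), numeric(0), sample_rate = sample_rate,
                       block_id = block_id, standardized = standardized))
  step <- 1000 / sample_rate
  d <- diff(df$time_ms)
  if (any(d <= 0))
    stop(sprintf("non-monotonic time at row %d of %s",
                 which(d <= 0)[1] + 1L, path))
  if (any(abs(d - step) > 1e-6 * step))
    stop(sprintf("inconsistent sampling step at row %d of %s",
                 which(abs(d - step) > 1e-6 * step)[1] + 1L, path))
  blink <- if ("blink" %in% names(df)) {
    b <- df$blink
    b[is.na(b)] <- 0
    as.logical(b)
  } else rep(FALSE, nrow(df))
  valid <- if ("valid" %in% names(df)) {
    as.logical(df$valid) & !is.na(df$pupil) & !blink
  } else {
    !is.na(df$pupil) & !blink
  }
  pupil_trace(times = df$time_ms, pupil = df$pupil, valid = valid,
              sample_rate = sample_rate, blink = blink,
              block_id = block_id, standardized = standardized)
}

#' Write a pupil trace to TSV
#'
#' Columns `time_ms`, `pupil`, `blink`, `valid` in fixed order. Every
#' finite pupil value is written (15 significant digits, which
#' reproduces doubles on read), including values at invalid samples —
#' after interpolation those carry the filled-in estimates, and the
#' explicit `valid` column keeps the mask, so cleaned traces round-trip
#' losslessly. Missing values are empty cells. The block id and
#' standardization flag are preserved in `#` header comments.
#'
#' @param trace a [pupil_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pupil_trace <- function(trace, path) {
  validate_pupil_trace(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pupil_trace block_id: %s", trace$block_id), con)
  writeLines(sprintf("# sample_rate_hz: %g", trace$sample_rate), con)
  writeLines(sprintf("# standardized: %s",
                     if (trace$standardized) "true" else "false"), con)
  writeLines("time_ms\tpupil\tblink\tvalid", con)
  pup <- ifelse(is.finite(trace$pupil), sprintf("%.15g", trace$pupil), "")
  writeLines(sprintf("%.9g\t%s\t%d\t%d", trace$times, pup,
                     as.integer(trace$blink), as.integer(trace$valid)),
             con)
  invisible(path)
}

#' Read percept reports from TSV
#'
#' Accepts two dialects, auto-detected from the header:
#' * interval format — columns `onset_ms`, `offset_ms`, `label` with
#'   labels in [PERCEPT_LABELS]; gaps between intervals are filled with
#'   `"none"`;
#' * event format — columns `time_ms`, `event` with events
#'   `L_down`/`L_up`/`R_down`/`R_up`, converted via
#'   [events_to_timeline()].
#'
#' @param path file path (TSV or CSV).
#' @param block_duration_ms total block duration in ms.
#' @param block_id block label; defaults to the file name.
#' @return A [percept_timeline()] covering the full block.
#' @export
read_percept_events <- function(path, block_duration_ms, block_id = NULL) {
  if (is.null(block_id))
    block_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("file has no header row: ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (all(c("onset_ms", "offset_ms", "label") %in% names(df))) {
    if (nrow(df) && any(df$onset_ms < 0)) stop("negative times in ", path)
    tl <- fill_gaps_with_none(df$onset_ms, df$offset_ms, df$label,
                              block_duration_ms, block_id)
  } else if (all(c("time_ms", "event") %in% names(df))) {
    tl <- events_to_timeline(df$time_ms, df$event, block_duration_ms,
                             block_id)
  } else {
    stop("unrecognized percept file header in ", path,
         " (need onset_ms/offset_ms/label or time_ms/event)")
  }
  tl
}

fill_gaps_with_none <- function(onset, offset, label, dur, block_id) {
  o <- order(onset)
  onset <- as.numeric(onset)[o]; offset <- as.numeric(offset)[o]
  label <- as.character(label)[o]
  keep <- offset > onset
  onset <- onset[keep]; offset <- offset[keep]; label <- label[keep]
  out_on <- numeric(0); out_off <- numeric(0); out_lab <- character(0)
  t <- 0
  for (i in seq_along(onset)) {
    if (onset[i] > t) {
      out_on <- c(out_on, t); out_off <- c(out_off, onset[i])
      out_lab <- c(out_lab, "none")
    }
    out_on <- c(out_on, onset[i]); out_off <- c(out_off, offset[i])
    out_lab <- c(out_lab, label[i])
    t <- offset[i]
  }
  if (t < dur) {
    out_on <- c(out_on, t); out_off <- c(out_off, dur)
    out_lab <- c(out_lab, "none")
  }
  percept_timeline(out_on, out_off, out_lab, dur, block_id)
}

#' Write a percept timeline to TSV (interval dialect)
#'
#' @param tl a [percept_timeline()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_percept_timeline <- function(tl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# percept_timeline block_id: %s", attr(tl, "block_id")),
             con)
  writeLines(sprintf("# block_duration_ms: %g",
                     attr(tl, "block_duration_ms")), con)
  writeLines("onset_ms\toffset_ms\tlabel", con)
  writeLines(sprintf("%.9g\t%.9g\t%s", tl$onset, tl$offset, tl$label), con)
  invisible(path)
}

#' Write per-cycle F1 records to TSV
#'
#' @param cycles a cycle-record data.frame from [extract_cycles()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(cycles, path) {
  out <- data.frame(index = cycles$index, onset_ms = cycles$onset_ms,
                    label = cycles$label,
                    re_z = Re(cycles$z), im_z = Im(cycles$z),
                    frac_interpolated = cycles$frac_interpolated)
  utils::write.table(format(out, digits = 9, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cycle F1 records written by [write_cycles()]
#'
#' @param path file path.
#' @return data.frame with a complex `z` column reconstructed from the
#'   stored real/imaginary parts.
#' @export
read_cycles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(index = df$index, onset_ms = df$onset_ms, label = df$label,
             z = complex(real = df$re_z, imaginary = df$im_z),
             frac_interpolated = df$frac_interpolated)
}
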