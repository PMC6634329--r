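#' Construct a pupil trace
#'
#' A `pupil_trace` holds one block's uniformly sampled pupil time series:
#' sample times in milliseconds from block onset, pupil size (arbitrary
#' units raw, z-units after standardization), a per-sample validity mask
#' (`FALSE` = blink / artifact / removed) and an optional blink flag that
#' records which invalid samples originate from detected blinks.
#'
#' @param times numeric vector, sample times in ms from block onset;
#'   strictly increasing with constant step `1000 / sample_rate`.
#' @param pupil numeric vector of pupil sizes, same length as `times`.
#'   May contain `NA` at invalid samples.
#' @param valid logical vector, same length; defaults to `!is.na(pupil)`.
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param blink logical vector flagging blink-origin samples; defaults to
#'   all `FALSE`. Blink samples are always invalid.
#' @param block_id character label for the block.
#' @param standardized logical; `TRUE` after per-block z-standardization.
#'
#' @return An object of class `pupil_trace`: a list with the above fields.
#' @seealso [read_pupil_trace()], [preprocess()], [zscore_block()]
#' @export
#' @examples
#' tr <- pupil_trace(times = 0:9, pupil = sin(0:9 / 3))
#' tr
pupil_trace <- function(times, pupil, valid = NULL, sample_rate = 1000,
                        blink = NULL, block_id = "block",
                        standardized = FALSE) {
  times <- as.numeric(times)
  pupil <- as.numeric(pupil)
  n <- length(times)
  if (length(pupil) != n)
    stop("`times` and `pupil` must have the same length")
  if (is.null(valid)) valid <- !is.na(pupil)
  valid <- as.logical(valid)
  if (length(valid) != n)
    stop("`valid` must have the same length as `times`")
  if (is.null(blink)) blink <- rep(FALSE, n)
  blink <- as.logical(blink)
  if (length(blink) != n)
    stop("`blink` must have the same length as `times`")
  valid[blink] <- FALSE
  valid[is.na(valid)] <- FALSE
  tr <- structure(
    list(times = times, pupil = pupil, valid = valid, blink = blink,
         sample_rate = as.numeric(sample_rate),
         block_id = as.character(block_id),
         standardized = isTRUE(standardized)),
    class = "pupil_trace")
  validate_pupil_trace(tr)
  tr
}

#' Validate a pupil trace
#'
#' Checks the structural invariants of a [pupil_trace()]: equal field
#' lengths, strictly increasing times with the constant step implied by the
#' sample rate, and (if the trace is flagged as standardized) mean 0 / SD 1
#' over valid samples within `1e-9`.
#'
#' @param tr a `pupil_trace`.
#' @param tol relative tolerance on the sampling step (default `1e-6`).
#' @return `tr`, invisibly; stops with an informative error otherwise.
#' @export
validate_pupil_trace <- function(tr, tol = 1e-6) {
  stopifnot(inherits(tr, "pupil_trace"))
  n <- length(tr$times)
  if (length(tr$pupil) != n || length(tr$valid) != n ||
      length(tr$blink) != n)
    stop("pupil_trace fields have inconsistent lengths")
  if (!is.finite(tr$sample_rate) || tr$sample_rate <= 0)
    stop("sample_rate must be positive")
  if (n >= 2) {
    step <- 1000 / tr$sample_rate
    d <- diff(tr$times)
    if (any(d <= 0))
      stop(sprintf("times not strictly increasing at row %d",
                   which(d <= 0)[1] + 1L))
    if (any(abs(d - step) > tol * step))
      stop(sprintf("inconsistent sampling step at row %d (expected %g ms)",
                   which(abs(d - step) > tol * step)[1] + 1L, step))
  }
  if (any(!is.finite(tr$pupil[tr$valid])))
    stop("valid samples must have finite pupil values")
  if (isTRUE(tr$standardized)) {
    # standardization acts on the fully interpolated block, so the
    # moments are checked over all finite samples, not the valid subset
    x <- tr$pupil[is.finite(tr$pupil)]
    if (abs(mean(x)) > 1e-9 || abs(stats::sd(x) - 1) > 1e-9)
      stop("trace flagged standardized but samples are not z-scored")
  }
  invisible(tr)
}

#' @export
print.pupil_trace <- function(x, ...) {
  dur <- if (length(x$times)) diff(range(x$times)) + 1000 / x$sample_rate else 0
  cat(sprintf(
    "pupil_trace '%s': %d samples @ %g Hz (%.1f s), %d invalid (%d blink)%s\n",
    x$block_id, length(x$times), x$sample_rate, dur / 1000,
    sum(!x$valid), sum(x$blink),
    if (x$standardized) ", z-standardized" else ""))
  invisible(x)
}

#' @export
length.pupil_trace <- function(x) length(x$times)

#' @export
as.data.frame.pupil_trace <- function(x, ...) {
  data.frame(time_ms = x$times, pupil = x$pupil, valid = x$valid,
             blink = x$blink)
}
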