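#' Reject change-rate outliers
#'
#' Residual blink artifacts appear as extremely rapid apparent changes in
#' pupil size. Let `d_i = pupil[i+1] - pupil[i]` over all currently valid
#' adjacent sample pairs; the SD of these first differences is computed
#' once over the whole block, and sample `i` is invalidated whenever
#' `|d_i| > k_sd * SD` (single pass; a sample is thus removed when the
#' step from it to the next sample is an outlier, which takes out both
#' flanks of a spike).
#'
#' @param trace a [pupil_trace()].
#' @param k_sd threshold multiplier (default 5).
#' @return The trace with offending samples invalidated; the
#'   first-difference SD is attached as attribute `change_rate_sd` and the
#'   rejection count as `n_rate_rejections`.
#' @export
reject_rate_outliers <- function(trace, k_sd = 5) {
  if (sum(trace$valid) < 3)
    stop("need at least 3 valid samples for change-rate rejection")
  n <- length(trace$times)
  pair_ok <- trace$valid[-n] & trace$valid[-1]
  d <- trace$pupil[-1] - trace$pupil[-n]
  s <- stats::sd(d[pair_ok])
  bad_first <- pair_ok & abs(d) > k_sd * s      # index i of pair (i, i+1)
  newvalid <- trace$valid
  newvalid[which(bad_first)] <- FALSE
  out <- trace
  out$valid <- newvalid
  attr(out, "change_rate_sd") <- s
  attr(out, "n_rate_rejections") <- sum(trace$valid) - sum(newvalid)
  out
}

#' Pad invalid runs around blinks
#'
#' Extends maximal runs of invalid samples by `pad_ms` on both sides
#' (clipped at the block edges), because pupil size is unreliable just
#' before and after a blink. Runs containing blink-flagged samples are
#' always padded; by default purely artifact-origin runs are padded too
#' (residual artifacts behave like blinks, and change-rate rejection
#' tends to leave ragged, partially caught spike trains whose surviving
#' neighbours are equally contaminated). Raise `min_run_ms` to pad only
#' artifact runs of at least that duration.
#'
#' @param trace a [pupil_trace()].
#' @param pad_ms padding in ms on each side (default 50).
#' @param min_run_ms minimum duration for padding non-blink runs
#'   (default 0 = pad every run); `Inf` pads blink runs only.
#' @return The trace with padded validity mask; the number of samples
#'   newly invalidated is attached as attribute `n_pad_removed`.
#' @export
pad_blinks <- function(trace, pad_ms = 50, min_run_ms = 0) {
  if (pad_ms <= 0) {
    attr(trace, "n_pad_removed") <- 0L
    return(trace)
  }
  n <- length(trace$times)
  step <- 1000 / trace$sample_rate
  pad_n <- round(pad_ms / step)
  inv <- !trace$valid
  if (!any(inv)) {
    attr(trace, "n_pad_removed") <- 0L
    return(trace)
  }
  r <- rle(inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  newvalid <- trace$valid
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    run_ms <- r$lengths[j] * step
    is_blink <- any(trace$blink[i0:i1])
    if (is_blink || run_ms >= min_run_ms) {
      a <- max(1L, i0 - pad_n)
      b <- min(n, i1 + pad_n)
      newvalid[a:b] <- FALSE
    }
  }
  out <- trace
  out$valid <- newvalid
  attr(out, "n_pad_removed") <- sum(trace$valid) - sum(newvalid)
  out
}

#' Interpolate invalid gaps with a cubic spline
#'
#' Interior invalid samples are replaced by a cubic spline fitted through
#' all valid samples; leading and trailing invalid runs, where spline
#' extrapolation is unstable, are filled with the nearest valid value.
#' The validity mask is retained so downstream stages can quantify how
#' much of each analysis window was filled.
#'
#' @param trace a [pupil_trace()].
#' @return The trace with all pupil values finite and the original mask
#'   kept; the fill count is attached as attribute `n_interpolated`.
#' @export
interpolate_gaps <- function(trace) {
  nv <- sum(trace$valid)
  if (nv < 4) stop("need at least 4 valid samples for spline interpolation")
  out <- trace
  inv <- !trace$valid
  if (!any(inv)) {
    attr(out, "n_interpolated") <- 0L
    return(out)
  }
  vidx <- which(trace$valid)
  first_v <- vidx[1]; last_v <- vidx[length(vidx)]
  fill <- which(inv)
  interior <- fill[fill > first_v & fill < last_v]
  if (length(interior)) {
    sp <- stats::spline(x = trace$times[vidx], y = trace$pupil[vidx],
                        xout = trace$times[interior], method = "fmm")
    out$pupil[interior] <- sp$y
  }
  if (first_v > 1)
    out$pupil[seq_len(first_v - 1)] <- trace$pupil[first_v]
  if (last_v < length(trace$times))
    out$pupil[seq(last_v + 1, length(trace$times))] <- trace$pupil[last_v]
  attr(out, "n_interpolated") <- length(fill)
  out
}

#' z-standardize a block
#'
#' Rescales the block's pupil time series to mean 0 and SD 1 over all
#' samples (the trace must be fully interpolated first). Idempotent and
#' invariant under affine transformations of the input.
#'
#' @param trace a fully interpolated [pupil_trace()].
#' @return The standardized trace (`standardized = TRUE`).
#' @export
zscore_block <- function(trace) {
  x <- trace$pupil
  if (any(!is.finite(x)))
    stop("trace must be fully interpolated before z-standardization")
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance block cannot be standardized")
  out <- trace
  out$pupil <- (x - mean(x)) / s
  out$standardized <- TRUE
  out
}

#' Cleaning report
#'
#' @param n_rate_rejections samples removed by the change-rate rule.
#' @param n_pad_removed samples removed by blink padding.
#' @param n_interpolated samples filled by interpolation.
#' @param change_rate_sd SD of the first differences used as threshold
#'   base.
#' @return An object of class `cleaning_report`.
#' @export
cleaning_report <- function(n_rate_rejections, n_pad_removed,
                            n_interpolated, change_rate_sd) {
  structure(list(n_rate_rejections = as.integer(n_rate_rejections),
                 n_pad_removed = as.integer(n_pad_removed),
                 n_interpolated = as.integer(n_interpolated),
                 change_rate_sd = change_rate_sd),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("cleaning_report: %d rate rejections, %d removed by ",
                     "padding, %d interpolated (diff SD %.4g)\n"),
              x$n_rate_rejections, x$n_pad_removed, x$n_interpolated,
              x$change_rate_sd))
  invisible(x)
}

#' Full preprocessing pipeline for one block
#'
#' Applies, in order: change-rate outlier rejection
#' ([reject_rate_outliers()]), blink padding ([pad_blinks()]),
#' cubic-spline interpolation ([interpolate_gaps()]) and per-block
#' z-standardization ([zscore_block()]).
#'
#' @param trace a raw [pupil_trace()].
#' @param k_sd change-rate threshold multiplier (default 5).
#' @param pad_ms blink padding in ms (default 50).
#' @param min_run_ms see [pad_blinks()].
#' @return list with `trace` (the cleaned, standardized [pupil_trace()])
#'   and `report` (a [cleaning_report()]).
#' @export
#' @examples
#' blk <- simulate_block(simulation_params(), stimulus_schedule(), seed = 7)
#' out <- preprocess(blk$trace)
#' out$report
preprocess <- function(trace, k_sd = 5, pad_ms = 50, min_run_ms = 0) {
  t1 <- reject_rate_outliers(trace, k_sd = k_sd)
  t2 <- pad_blinks(t1, pad_ms = pad_ms, min_run_ms = min_run_ms)
  t3 <- interpolate_gaps(t2)
  t4 <- zscore_block(t3)
  list(trace = t4,
       report = cleaning_report(
         n_rate_rejections = attr(t1, "n_rate_rejections"),
         n_pad_removed = attr(t2, "n_pad_removed"),
         n_interpolated = attr(t3, "n_interpolated"),
         change_rate_sd = attr(t1, "change_rate_sd")))
}
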