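#' Percept labels
#'
#' Vocabulary of perceptual-report labels: `"left"` / `"right"` name the EYE
#' whose image is reported exclusively dominant (the eye-to-image assignment
#' lives in the stimulus schedule), `"mixed"` is a piecemeal/superimposed
#' report (both buttons held), `"none"` means no button held.
#'
#' @export
PERCEPT_LABELS <- c("left", "right", "mixed", "none")

#' Construct a percept timeline
#'
#' A `percept_timeline` partitions one block into ordered, non-overlapping,
#' half-open intervals `[onset, offset)` (ms), each carrying a percept
#' label. The union of the intervals covers `[0, block_duration_ms)`.
#'
#' @param onset,offset numeric vectors of interval bounds in ms.
#' @param label character vector of labels, each in [PERCEPT_LABELS].
#' @param block_duration_ms total block duration in ms; defaults to
#'   `max(offset)`.
#' @param block_id character label.
#' @return An object of class `percept_timeline`: a data.frame with columns
#'   `onset`, `offset`, `label` and attributes `block_duration_ms`,
#'   `block_id`. Zero-length intervals are dropped.
#' @seealso [read_percept_events()], [events_to_timeline()]
#' @export
#' @examples
#' percept_timeline(c(0, 1000), c(1000, 2000), c("left", "none"))
percept_timeline <- function(onset, offset, label,
                             block_duration_ms = NULL, block_id = "block") {
  onset <- as.numeric(onset); offset <- as.numeric(offset)
  label <- as.character(label)
  if (length(onset) != length(offset) || length(onset) != length(label))
    stop("onset, offset and label must have equal lengths")
  keep <- offset > onset          # drop zero-length reports
  onset <- onset[keep]; offset <- offset[keep]; label <- label[keep]
  if (is.null(block_duration_ms))
    block_duration_ms <- if (length(offset)) max(offset) else 0
  o <- order(onset)
  tl <- structure(
    data.frame(onset = onset[o], offset = offset[o], label = label[o],
               stringsAsFactors = FALSE),
    block_duration_ms = as.numeric(block_duration_ms),
    block_id = as.character(block_id),
    class = c("percept_timeline", "data.frame"))
  validate_percept_timeline(tl)
  tl
}

#' Validate a percept timeline
#'
#' Checks that intervals are non-overlapping, ordered, with `onset < offset`
#' and labels in the vocabulary, and that their union exactly covers
#' `[0, block_duration_ms)`.
#'
#' @param tl a `percept_timeline`.
#' @param tol tolerance in ms for coverage checks (default `1e-6`).
#' @return `tl`, invisibly.
#' @export
validate_percept_timeline <- function(tl, tol = 1e-6) {
  stopifnot(inherits(tl, "percept_timeline"))
  bad <- setdiff(unique(tl$label), PERCEPT_LABELS)
  if (length(bad))
    stop("unknown percept label(s): ", paste(bad, collapse = ", "))
  if (any(tl$offset <= tl$onset))
    stop("intervals must satisfy onset < offset")
  dur <- attr(tl, "block_duration_ms")
  n <- nrow(tl)
  if (n == 0) {
    if (dur > tol) stop("empty timeline does not cover the block")
    return(invisible(tl))
  }
  if (abs(tl$onset[1]) > tol)
    stop("timeline must start at 0")
  if (n > 1 && any(abs(tl$onset[-1] - tl$offset[-n]) > tol))
    stop("timeline has gaps or overlaps between intervals")
  if (abs(tl$offset[n] - dur) > tol)
    stop("timeline must end at block_duration_ms")
  invisible(tl)
}

#' @export
print.percept_timeline <- function(x, ...) {
  cat(sprintf("percept_timeline '%s': %d intervals over %.1f s\n",
              attr(x, "block_id"), nrow(x),
              attr(x, "block_duration_ms") / 1000))
  tab <- tapply(x$offset - x$onset, factor(x$label, PERCEPT_LABELS), sum)
  tab[is.na(tab)] <- 0
  prop <- tab / attr(x, "block_duration_ms")
  cat("  time share:",
      paste(sprintf("%s %.1f%%", names(prop), 100 * prop), collapse = ", "),
      "\n")
  invisible(x)
}

#' Convert button events to a percept timeline
#'
#' Observers hold one button per stimulus: exactly one button held means the
#' corresponding eye's image is exclusively dominant, both held means a
#' mixed percept, none held means no report. This converts a press/release
#' event stream into the interval representation. Simultaneous events at
#' one timestamp process releases before presses, so a release+press pair
#' at the same millisecond produces no spurious zero-length mixed interval.
#'
#' @param time_ms numeric vector of event times (ms, >= 0).
#' @param event character vector: `"L_down"`, `"L_up"`, `"R_down"`,
#'   `"R_up"`.
#' @param block_duration_ms total block duration in ms.
#' @param block_id character label.
#' @return A [percept_timeline()] covering `[0, block_duration_ms)`.
#' @export
#' @examples
#' events_to_timeline(c(0, 500, 1000, 1500),
#'                    c("L_down", "R_down", "L_up", "R_up"), 1500)
events_to_timeline <- function(time_ms, event, block_duration_ms,
                               block_id = "block") {
  time_ms <- as.numeric(time_ms)
  event <- as.character(event)
  ok <- c("L_down", "L_up", "R_down", "R_up")
  if (length(time_ms) != length(event))
    stop("time_ms and event must have equal lengths")
  bad <- setdiff(unique(event), ok)
  if (length(bad)) stop("unknown event(s): ", paste(bad, collapse = ", "))
  if (any(time_ms < 0)) stop("negative event times")
  # releases before presses at equal timestamps
  is_up <- event %in% c("L_up", "R_up")
  o <- order(time_ms, !is_up)
  time_ms <- time_ms[o]; event <- event[o]

  state <- function(L, R) {
    if (L && R) "mixed" else if (L) "left" else if (R) "right" else "none"
  }
  L <- FALSE; R <- FALSE
  onset <- numeric(0); offset <- numeric(0); label <- character(0)
  t0 <- 0
  cur <- state(L, R)
  for (i in seq_along(time_ms)) {
    t <- time_ms[i]
    if (t > block_duration_ms) break
    Lp <- L; Rp <- R
    switch(event[i],
           L_down = { if (L) stop("unmatched press: L already down at ", t)
                      L <- TRUE },
           L_up   = { if (!L) stop("unmatched release: L not down at ", t)
                      L <- FALSE },
           R_down = { if (R) stop("unmatched press: R already down at ", t)
                      R <- TRUE },
           R_up   = { if (!R) stop("unmatched release: R not down at ", t)
                      R <- FALSE })
    new <- state(L, R)
    if (new != cur) {
      if (t > t0) {
        onset <- c(onset, t0); offset <- c(offset, t); label <- c(label, cur)
      }
      t0 <- t
      cur <- new
    }
  }
  if (block_duration_ms > t0) {
    onset <- c(onset, t0); offset <- c(offset, block_duration_ms)
    label <- c(label, cur)
  }
  percept_timeline(onset, offset, label, block_duration_ms, block_id)
}

#' Look up the percept label at given times
#'
#' @param tl a [percept_timeline()].
#' @param t_ms numeric vector of query times in ms; times outside
#'   `[0, block_duration_ms)` are clamped to the nearest interval.
#' @return character vector of labels.
#' @export
timeline_label_at <- function(tl, t_ms) {
  idx <- findInterval(t_ms, tl$onset, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(tl)] <- nrow(tl)
  tl$label[idx]
}

#' Shift a timeline in time
#'
#' Shifts every interval by `lag_ms` and re-truncates to the block,
#' filling the leading gap with `"none"`. Used to model the constant lag of
#' the overt button report behind the perceptual switch.
#'
#' @param tl a [percept_timeline()].
#' @param lag_ms shift in ms (positive = later).
#' @return A [percept_timeline()].
#' @export
shift_timeline <- function(tl, lag_ms) {
  dur <- attr(tl, "block_duration_ms")
  onset <- tl$onset + lag_ms
  offset <- tl$offset + lag_ms
  label <- tl$label
  if (lag_ms > 0) {
    onset <- c(0, onset); offset <- c(lag_ms, offset)
    label <- c("none", label)
  } else if (lag_ms < 0) {
    onset <- c(onset, dur + lag_ms); offset <- c(offset, dur)
    label <- c(label, "none")
  }
  keep <- onset < dur & offset > 0
  onset <- pmax(onset[keep], 0); offset <- pmin(offset[keep], dur)
  merge_timeline(percept_timeline(onset, offset, label[keep], dur,
                                  attr(tl, "block_id")))
}

#' Merge adjacent equal-label intervals
#'
#' @param tl a [percept_timeline()].
#' @return A [percept_timeline()] in canonical form (no two adjacent
#'   intervals share a label).
#' @export
merge_timeline <- function(tl) {
  if (nrow(tl) <= 1) return(tl)
  grp <- cumsum(c(TRUE, tl$label[-1] != tl$label[-nrow(tl)]))
  percept_timeline(tapply(tl$onset, grp, min),
                   tapply(tl$offset, grp, max),
                   tl$label[!duplicated(grp)],
                   attr(tl, "block_duration_ms"), attr(tl, "block_id"))
}
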