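#' Segment a trace into presentation cycles
#'
#' Chunks a standardized trace into windows of one presentation cycle
#' each, aligned so every window contains one full period of the left-eye
#' modulation sinusoid starting at -90° (its minimum). Because the period
#' is generally a non-integer number of samples (1000 / 1.7 = 588.235...),
#' each window holds a fixed `N = round(sample_rate / freq)` samples and
#' the onset of cycle `k` is re-anchored at `round(k * sample_rate /
#' freq)`, so alignment error never exceeds half a sample and does not
#' accumulate across the block. The trailing partial cycle is dropped.
#'
#' @param trace a [pupil_trace()].
#' @param sch a [stimulus_schedule()] (supplies `freq`).
#' @return data.frame with one row per cycle: `index` (0-based),
#'   `onset_ms`, `offset_ms`, `start_sample` (1-based), `n_samples`.
#' @export
#' @examples
#' tr <- pupil_trace(0:299999, rnorm(300000))
#' nrow(segment_cycles(tr, stimulus_schedule()))  # 510 cycles in 300 s
segment_cycles <- function(trace, sch) {
  n <- length(trace$times)
  period <- trace$sample_rate / sch$freq     # samples per cycle, exact
  N <- round(period)
  if (n < N) stop("trace shorter than one presentation cycle")
  k <- 0:floor(n / period)
  start <- round(k * period) + 1L            # 1-based onset sample
  keep <- start + N - 1L <= n
  k <- k[keep]; start <- start[keep]
  step <- 1000 / trace$sample_rate
  data.frame(index = k,
             onset_ms = trace$times[start],
             offset_ms = trace$times[start] + N * step,
             start_sample = start,
             n_samples = N)
}

#' Label cycles by exclusive percept
#'
#' A cycle is labelled `"left"` or `"right"` iff a single exclusive
#' interval of that label covers the entire window `[onset, offset)`;
#' any switch, mixed percept or unreported span inside the window makes
#' the cycle `"excluded"`. Only exclusive cycles enter the phase
#' statistics.
#'
#' @param windows data.frame from [segment_cycles()].
#' @param tl a [percept_timeline()] covering the block.
#' @return character vector of `"left"` / `"right"` / `"excluded"`, one
#'   per window.
#' @export
label_cycles <- function(windows, tl) {
  tl <- merge_timeline(tl)    # adjacent same-label reports are one percept
  excl <- tl[tl$label %in% c("left", "right"), , drop = FALSE]
  out <- rep("excluded", nrow(windows))
  if (!nrow(excl)) return(out)
  for (i in seq_len(nrow(windows))) {
    cover <- excl$onset <= windows$onset_ms[i] &
             excl$offset >= windows$offset_ms[i]
    if (any(cover)) out[i] <- excl$label[which(cover)[1]]
  }
  out
}

#' Complex F1 component of one presentation cycle
#'
#' Projects one cycle's samples onto the modulation frequency
#' (the DFT bin holding exactly one period) and returns the complex
#' coefficient `Z` with the convention fixed so that an input
#' `x_n = A * sin(2*pi*n/N)` gives `Z = i * A` (pure imaginary, positive)
#' and `x_n = A * cos(2*pi*n/N)` gives `Z = A` (pure real, positive):
#'
#' `Z = (2/N) * sum_n x_n * (cos(2*pi*n/N) + i * sin(2*pi*n/N))`
#'
#' i.e. the conjugated, `2/N`-normalized first DFT bin. The imaginary
#' part of `Z` is the amplitude of the sine-phase (reference-aligned)
#' content of the cycle, the real part the cosine-phase content; with the
#' -90° window anchoring, `Im(Z) > 0` means the pupil oscillates in phase
#' with the left-eye reference sinusoid. Computed via [stats::fft()].
#'
#' @param x numeric vector of one cycle's samples (length >= 8, no NA).
#' @return complex scalar `Z`.
#' @export
#' @examples
#' N <- 588
#' f1_component(sin(2 * pi * (0:(N - 1)) / N))   # ~ 0 + 1i
f1_component <- function(x) {
  N <- length(x)
  if (N < 8) stop("cycle must contain at least 8 samples")
  if (any(!is.finite(x))) stop("NA/NaN in cycle samples")
  (2 / N) * Conj(stats::fft(x)[2])
}

#' Extract labelled per-cycle F1 records for one block
#'
#' Composition of [segment_cycles()], [label_cycles()] and
#' [f1_component()]. Excluded cycles keep their `Z` for diagnostics but
#' are dropped from all statistics downstream. The fraction of
#' interpolated (originally invalid) samples per window is recorded;
#' cycles with more than half their samples filled are flagged
#' (`flag_interp`) but not excluded.
#'
#' @param trace a standardized [pupil_trace()] (see [preprocess()]).
#' @param tl a [percept_timeline()] of reported percepts.
#' @param sch a [stimulus_schedule()].
#' @return data.frame with columns `index`, `onset_ms`, `label`
#'   (`"left"`/`"right"`/`"excluded"`), `z` (complex),
#'   `frac_interpolated`, `flag_interp`.
#' @export
extract_cycles <- function(trace, tl, sch) {
  if (!isTRUE(trace$standardized))
    warning("extract_cycles expects a z-standardized trace")
  win <- segment_cycles(trace, sch)
  lab <- label_cycles(win, tl)
  z <- complex(nrow(win))
  frac <- numeric(nrow(win))
  for (i in seq_len(nrow(win))) {
    idx <- win$start_sample[i] + 0:(win$n_samples[i] - 1L)
    z[i] <- f1_component(trace$pupil[idx])
    frac[i] <- mean(!trace$valid[idx])
  }
  data.frame(index = win$index, onset_ms = win$onset_ms, label = lab,
             z = z, frac_interpolated = frac,
             flag_interp = frac > 0.5)
}
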