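#' Condition labels for a rivalry session
#'
#' Seven-block session design: an initial and a final static block,
#' counterphase (180°) and quarter-phase (90°) luminance modulation with
#' and without attention instructions, and an in-phase (0°) control.
#'
#' @export
CONDITION_LABELS <- c("static", "mod180_naive", "mod90_naive",
                      "mod0_control", "mod180_attend", "mod90_attend")

#' Construct a stimulus schedule
#'
#' Describes the dichoptic luminance modulation of one block: both eyes'
#' images are multiplied by a shifted, scaled sinusoid at the tagging
#' frequency, ranging between `lum_lo` and `lum_hi` of full image
#' luminance, with the right eye's modulation shifted by `phase_diff_deg`
#' relative to the left (left eye leading). The reference phase
#' `phase_left_deg` is chosen so that each analysis window contains one
#' full period of the left-eye sinusoid starting at -90° (its minimum).
#' Displayed pixel values are the modulation raised to `1/gamma` so the
#' modulation is sinusoidal in physical luminance rather than pixel value.
#'
#' @param freq modulation frequency in Hz (default 1.7).
#' @param phase_left_deg left-eye phase at window onset, degrees
#'   (default -90, i.e. the window starts at the luminance minimum).
#' @param phase_diff_deg right-minus-left phase offset in degrees;
#'   0, 90 or 180 in the standard design.
#' @param gamma display gamma exponent (default 2.26).
#' @param lum_lo,lum_hi modulation bounds as fractions of full image
#'   luminance (defaults 0.5 and 1.0).
#' @param refresh_hz display refresh rate in Hz (default 85).
#' @param block_duration_s block duration in seconds (default 300).
#' @param condition one of [CONDITION_LABELS].
#' @param eye_assignment named character vector mapping eyes to images,
#'   e.g. `c(left = "face", right = "house")`.
#' @return An object of class `stimulus_schedule`.
#' @seealso [luminance_signal()], [frames_per_cycle()], [cycle_length_ms()]
#' @export
#' @examples
#' sch <- stimulus_schedule(phase_diff_deg = 180)
#' frames_per_cycle(sch)   # 50 display frames per presentation cycle
#' cycle_length_ms(sch)    # 588 ms
stimulus_schedule <- function(freq = 1.7, phase_left_deg = -90,
                              phase_diff_deg = 180, gamma = 2.26,
                              lum_lo = 0.5, lum_hi = 1.0,
                              refresh_hz = 85, block_duration_s = 300,
                              condition = "mod180_naive",
                              eye_assignment = c(left = "face",
                                                 right = "house")) {
  condition <- match.arg(condition, CONDITION_LABELS)
  sch <- structure(
    list(freq = freq, phase_left_deg = phase_left_deg,
         phase_diff_deg = phase_diff_deg, gamma = gamma,
         lum_lo = lum_lo, lum_hi = lum_hi, refresh_hz = refresh_hz,
         block_duration_s = block_duration_s, condition = condition,
         eye_assignment = eye_assignment),
    class = "stimulus_schedule")
  validate_stimulus_schedule(sch)
  sch
}

#' Validate a stimulus schedule
#'
#' @param sch a `stimulus_schedule`.
#' @return `sch`, invisibly.
#' @export
validate_stimulus_schedule <- function(sch) {
  stopifnot(inherits(sch, "stimulus_schedule"))
  if (!(sch$lum_lo >= 0 && sch$lum_lo < sch$lum_hi && sch$lum_hi <= 1))
    stop("luminance bounds must satisfy 0 <= lum_lo < lum_hi <= 1")
  if (sch$gamma <= 0) stop("gamma must be positive")
  if (sch$freq <= 0) stop("freq must be positive")
  if (sch$refresh_hz <= 0) stop("refresh_hz must be positive")
  if (sch$block_duration_s <= 0) stop("block_duration_s must be positive")
  ea <- sch$eye_assignment
  if (!all(c("left", "right") %in% names(ea)) ||
      !setequal(unname(ea[c("left", "right")]), c("face", "house")))
    stop("eye_assignment must map left/right to face/house")
  invisible(sch)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf(
    paste0("stimulus_schedule [%s]: %g Hz, phase diff %g deg, ",
           "lum %.2f-%.2f, gamma %.2f, %g s block\n"),
    x$condition, x$freq, x$phase_diff_deg, x$lum_lo, x$lum_hi,
    x$gamma, x$block_duration_s))
  cat(sprintf("  eyes: left=%s, right=%s\n",
              x$eye_assignment[["left"]], x$eye_assignment[["right"]]))
  invisible(x)
}

#' Display frames per presentation cycle
#'
#' One presentation cycle spans `refresh_hz / freq` display frames; with
#' the standard 85 Hz display and 1.7 Hz modulation this is exactly 50.
#'
#' @param sch a [stimulus_schedule()].
#' @return number of display frames per modulation cycle.
#' @export
frames_per_cycle <- function(sch) sch$refresh_hz / sch$freq

#' Presentation cycle length in milliseconds
#'
#' `1000 / freq`, rounded to the nearest millisecond for the standard
#' 1000 Hz pupil sampling: 588 ms at 1.7 Hz.
#'
#' @param sch a [stimulus_schedule()].
#' @return cycle length in ms (integer).
#' @export
cycle_length_ms <- function(sch) round(1000 / sch$freq)

#' Luminance modulation signal for one eye
#'
#' The modulation presented to each eye is
#' `L(t) = lum_lo + (lum_hi - lum_lo) * (sin(2*pi*freq*t/1000 + phi) + 1) / 2`
#' with `phi = phase_left_deg` for the left eye and
#' `phi = phase_left_deg + phase_diff_deg` for the right. The companion
#' column `pixel` is the gamma-corrected pixel multiplier `L^(1/gamma)`
#' that renders the modulation sinusoidal in physical luminance.
#'
#' @param sch a [stimulus_schedule()].
#' @param eye `"left"` or `"right"`.
#' @param times_ms numeric vector of times in ms (any real values; the
#'   sinusoid is defined for negative times as well).
#' @return data.frame with columns `time_ms`, `lum` (luminance fraction in
#'   `[lum_lo, lum_hi]`) and `pixel` (gamma-corrected multiplier).
#' @export
#' @examples
#' sch <- stimulus_schedule(phase_diff_deg = 180)
#' ls <- luminance_signal(sch, "left", 0:587)
#' range(ls$lum)     # 0.5 .. 1.0
luminance_signal <- function(sch, eye = c("left", "right"), times_ms) {
  eye <- match.arg(eye)
  phi <- sch$phase_left_deg +
    if (eye == "right") sch$phase_diff_deg else 0
  lum <- sch$lum_lo + (sch$lum_hi - sch$lum_lo) *
    (sin(2 * pi * sch$freq * times_ms / 1000 + phi * pi / 180) + 1) / 2
  data.frame(time_ms = as.numeric(times_ms), lum = lum,
             pixel = lum^(1 / sch$gamma))
}

#' Map an eye label to the image it carries
#'
#' @param sch a [stimulus_schedule()].
#' @param eye character vector of `"left"` / `"right"` (other labels pass
#'   through as `NA`).
#' @return character vector of `"face"` / `"house"` / `NA`.
#' @export
eye_to_image <- function(sch, eye) {
  out <- rep(NA_character_, length(eye))
  out[eye == "left"] <- sch$eye_assignment[["left"]]
  out[eye == "right"] <- sch$eye_assignment[["right"]]
  out
}
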