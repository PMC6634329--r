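#' Simulation parameters for synthetic rivalry sessions
#'
#' The generative model behind the synthetic fixtures: exclusive-dominance
#' durations follow a gamma distribution (the standard description of
#' rivalry dominance-duration histograms), calibrated so the median
#' matches the ~2.7 s reported for this paradigm; transitions pass through
#' mixed-percept interludes sized to occupy `mixed_frac` of the block in
#' expectation; the overt button report lags the perceptual switch by a
#' constant `report_lag_ms`; the pupil responds to a percept-weighted
#' mixture of the two eyes' luminance signals, inverted (more light,
#' smaller pupil) and delayed by `pupil_delay_ms`, on top of a slow drift
#' and white measurement noise; blinks occur as a Poisson process, leave
#' gaps of missing data and are flanked by high-amplitude spike artifacts.
#'
#' @param dominance_shape gamma shape of exclusive-dominance durations
#'   (default 3.5, a typical rivalry value).
#' @param dominance_median_s median exclusive-dominance duration in s
#'   (default 2.7); the gamma scale is solved from shape and median.
#' @param mixed_frac expected fraction of block time in mixed percepts
#'   (default 0.29).
#' @param report_lag_ms constant button-report lag in ms (default 400).
#' @param w_dom pupil weight of the dominant stimulus, in `[0.5, 1]`
#'   (default 0.9); the suppressed stimulus contributes `1 - w_dom`.
#' @param pupil_delay_ms pupil response latency in ms (default 400).
#' @param gain oscillation gain in raw pupil units per unit luminance
#'   (default 120).
#' @param baseline mean pupil size in raw units (default 2200).
#' @param drift_sd SD of the slow drift component in raw units
#'   (default 60).
#' @param noise_sd SD of white measurement noise in raw units
#'   (default 25).
#' @param blink_rate_hz blink frequency in Hz (default 0.25).
#' @param blink_dur_ms mean blink duration in ms (default 150).
#' @param spike_pad_ms duration of the spike artifacts flanking each blink
#'   gap in ms (default 60).
#' @param spike_sd_mult spike amplitude as a multiple of the trace SD
#'   (default 10).
#' @return An object of class `simulation_params` (a named list).
#' @export
simulation_params <- function(dominance_shape = 3.5,
                              dominance_median_s = 2.7,
                              mixed_frac = 0.29,
                              report_lag_ms = 400,
                              w_dom = 0.9,
                              pupil_delay_ms = 400,
                              gain = 120,
                              baseline = 2200,
                              drift_sd = 60,
                              noise_sd = 25,
                              blink_rate_hz = 0.25,
                              blink_dur_ms = 150,
                              spike_pad_ms = 60,
                              spike_sd_mult = 10) {
  p <- structure(
    list(dominance_shape = dominance_shape,
         dominance_median_s = dominance_median_s,
         mixed_frac = mixed_frac, report_lag_ms = report_lag_ms,
         w_dom = w_dom, pupil_delay_ms = pupil_delay_ms, gain = gain,
         baseline = baseline, drift_sd = drift_sd, noise_sd = noise_sd,
         blink_rate_hz = blink_rate_hz, blink_dur_ms = blink_dur_ms,
         spike_pad_ms = spike_pad_ms, spike_sd_mult = spike_sd_mult),
    class = "simulation_params")
  validate_simulation_params(p)
  p
}

#' Validate simulation parameters
#'
#' @param p a `simulation_params`.
#' @return `p`, invisibly.
#' @export
validate_simulation_params <- function(p) {
  if (!(p$w_dom >= 0.5 && p$w_dom <= 1))
    stop("w_dom must lie in [0.5, 1]")
  if (p$dominance_shape <= 0 || p$dominance_median_s <= 0)
    stop("dominance distribution parameters must be positive")
  if (p$mixed_frac < 0 || p$mixed_frac >= 1)
    stop("mixed_frac must lie in [0, 1)")
  nn <- c("report_lag_ms", "pupil_delay_ms", "gain", "drift_sd",
          "noise_sd", "blink_rate_hz", "blink_dur_ms", "spike_pad_ms",
          "spike_sd_mult")
  for (k in nn) if (p[[k]] < 0) stop(k, " must be >= 0")
  invisible(p)
}

#' Gamma scale solving for a target median
#'
#' @param shape gamma shape.
#' @param median_s target median in seconds.
#' @return scale parameter theta such that `qgamma(0.5, shape, scale =
#'   theta) == median_s`.
#' @export
dominance_scale <- function(shape, median_s) {
  median_s / stats::qgamma(0.5, shape = shape, scale = 1)
}

#' Simulate perceptual-report timelines for one block
#'
#' Draws alternating left/right exclusive-dominance periods from the gamma
#' law, separated by mixed interludes whose mean duration is set so mixed
#' time is `mixed_frac` of the block in expectation. Returns both the
#' ground-truth timeline (what the observer perceived) and the reported
#' timeline (ground truth delayed by `report_lag_ms`, leading gap filled
#' with `"none"`).
#'
#' @param params a [simulation_params()].
#' @param sch a [stimulus_schedule()] (supplies block duration).
#' @param block_id block label.
#' @return list with elements `truth` and `reported`, both
#'   [percept_timeline()]s.
#' @export
simulate_reports <- function(params, sch, block_id = "block") {
  dur_ms <- sch$block_duration_s * 1000
  shape <- params$dominance_shape
  scale <- dominance_scale(shape, params$dominance_median_s)
  mean_dom_ms <- shape * scale * 1000
  mean_mix_ms <- if (params$mixed_frac > 0)
    mean_dom_ms * params$mixed_frac / (1 - params$mixed_frac) else 0

  eye <- sample(c("left", "right"), 1)
  onset <- numeric(0); offset <- numeric(0); label <- character(0)
  t <- 0
  while (t < dur_ms) {
    d <- stats::rgamma(1, shape = shape, scale = scale) * 1000
    onset <- c(onset, t); offset <- c(offset, min(t + d, dur_ms))
    label <- c(label, eye)
    t <- t + d
    if (t >= dur_ms) break
    if (mean_mix_ms > 0) {
      m <- stats::rgamma(1, shape = 2, scale = mean_mix_ms / 2)
      onset <- c(onset, t); offset <- c(offset, min(t + m, dur_ms))
      label <- c(label, "mixed")
      t <- t + m
    }
    eye <- if (eye == "left") "right" else "left"
  }
  truth <- percept_timeline(onset, offset, label, dur_ms, block_id)
  reported <- shift_timeline(truth, params$report_lag_ms)
  list(truth = truth, reported = reported)
}

#' Simulate a raw pupil trace for one block
#'
#' The deterministic core of the model is
#' `pupil(t) = baseline - gain * [w(t) * L_dom(t - delay) +
#' (1 - w(t)) * L_sup(t - delay)] + drift(t) + noise(t)`,
#' where during exclusive dominance `L_dom` is the dominant eye's
#' luminance signal and `w(t) = w_dom`, and during mixed/none periods both
#' eyes contribute equally (`w = 0.5`). The sign inversion encodes the
#' pupillary light response (brighter stimulus, smaller pupil). Drift is
#' white noise band-limited below 0.2 Hz and scaled to `drift_sd`; blinks
#' arrive as a Poisson process, blank the trace (`valid = FALSE`,
#' `blink = TRUE`) and are flanked by `spike_pad_ms` of +/-
#' `spike_sd_mult` x SD spike artifacts so that residual-artifact
#' detection has true positives to find. Static blocks (condition
#' `"static"`) carry no luminance oscillation.
#'
#' @param params a [simulation_params()].
#' @param sch a [stimulus_schedule()].
#' @param truth ground-truth [percept_timeline()] (lag-free), as returned
#'   by [simulate_reports()].
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param block_id block label.
#' @return A raw [pupil_trace()] with blinks marked; the logical
#'   attribute `"artifact"` records which (still valid) samples carry
#'   injected spike artifacts, as ground truth for cleaning validation.
#' @export
simulate_pupil <- function(params, sch, truth, sample_rate = 1000,
                           block_id = "block") {
  dur_ms <- sch$block_duration_s * 1000
  if (params$pupil_delay_ms >= dur_ms)
    stop("pupil_delay_ms must be shorter than the block")
  step <- 1000 / sample_rate
  times <- seq(0, dur_ms - step, by = step)
  n <- length(times)
  t_src <- times - params$pupil_delay_ms

  if (sch$condition == "static") {
    osc <- rep(sch$lum_hi, n)        # constant full luminance, both eyes
  } else {
    lab <- timeline_label_at(truth, pmax(t_src, 0))
    lum_l <- luminance_signal(sch, "left", t_src)$lum
    lum_r <- luminance_signal(sch, "right", t_src)$lum
    w <- ifelse(lab %in% c("left", "right"), params$w_dom, 0.5)
    ldom <- ifelse(lab == "right", lum_r, lum_l)   # left also covers mixed
    lsup <- ifelse(lab == "right", lum_l, lum_r)
    osc <- w * ldom + (1 - w) * lsup
  }

  drift <- if (params$drift_sd > 0) {
    raw <- stats::rnorm(n)
    bf <- signal::butter(2, 0.2 / (sample_rate / 2), type = "low")
    sm <- signal::filtfilt(bf, raw)
    s <- stats::sd(sm)
    if (s > 0) params$drift_sd * sm / s else rep(0, n)
  } else rep(0, n)
  noise <- if (params$noise_sd > 0) {
    # measurement noise: white across the analysis band but band-limited
    # to 50 Hz, as in real pupillometry (sample-to-sample white noise at
    # 1 kHz would be physically implausible and would make any
    # interpolation across blink gaps ill-posed)
    raw <- stats::rnorm(n)
    bf <- signal::butter(2, min(50 / (sample_rate / 2), 0.99),
                         type = "low")
    sm <- signal::filtfilt(bf, raw)
    s <- stats::sd(sm)
    if (s > 0) params$noise_sd * sm / s else rep(0, n)
  } else rep(0, n)

  pupil <- params$baseline - params$gain * osc + drift + noise
  valid <- rep(TRUE, n)
  blink <- rep(FALSE, n)

  artifact <- rep(FALSE, n)
  n_blinks <- stats::rpois(1, params$blink_rate_hz * dur_ms / 1000)
  if (n_blinks > 0) {
    sd_tr <- stats::sd(pupil)
    pad_n <- max(1L, round(params$spike_pad_ms / step))
    starts <- sort(stats::runif(n_blinks, 0, dur_ms))
    for (s0 in starts) {
      d <- stats::rexp(1, 1 / params$blink_dur_ms)
      i0 <- max(1L, 1L + floor(s0 / step))
      i1 <- min(n, 1L + floor((s0 + d) / step))
      if (i1 < i0) next
      blink[i0:i1] <- TRUE
      pupil[i0:i1] <- NA_real_
      pre <- seq(max(1L, i0 - pad_n), i0 - 1L)
      post <- seq(i1 + 1L, min(n, i1 + pad_n))
      # never spike a sample twice: overlapping flanks of nearby blinks
      # would partially cancel and hide the artifact
      if (i0 > 1L) pre <- pre[!artifact[pre] & !blink[pre]] else pre <- integer(0)
      if (i1 < n) post <- post[!artifact[post] & !blink[post]] else post <- integer(0)
      if (length(pre)) {
        pupil[pre] <- pupil[pre] +
          params$spike_sd_mult * sd_tr * (-1)^seq_along(pre)
        artifact[pre] <- TRUE
      }
      if (length(post)) {
        pupil[post] <- pupil[post] +
          params$spike_sd_mult * sd_tr * (-1)^seq_along(post)
        artifact[post] <- TRUE
      }
    }
    valid <- valid & !blink
    artifact <- artifact & !blink
  }
  tr <- pupil_trace(times, pupil, valid = valid, sample_rate = sample_rate,
                    blink = blink, block_id = block_id)
  # ground truth for validation: which valid samples carry injected spikes
  attr(tr, "artifact") <- artifact
  tr
}

#' Simulate one complete block
#'
#' Convenience wrapper: seeds the RNG, draws the report timelines and the
#' pupil trace in one call. Identical `seed` and parameters give
#' bit-identical output.
#'
#' @param params a [simulation_params()].
#' @param sch a [stimulus_schedule()].
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @param sample_rate sampling rate in Hz.
#' @param block_id block label.
#' @return list with `trace` (raw [pupil_trace()]), `reported` and
#'   `truth` ([percept_timeline()]s), plus the `params`, `schedule` and
#'   `seed` used.
#' @export
simulate_block <- function(params, sch, seed = NULL, sample_rate = 1000,
                           block_id = "block") {
  if (!is.null(seed)) set.seed(seed)
  rep <- simulate_reports(params, sch, block_id)
  trace <- simulate_pupil(params, sch, rep$truth, sample_rate, block_id)
  list(trace = trace, reported = rep$reported, truth = rep$truth,
       params = params, schedule = sch, seed = seed)
}

#' Seven-block session condition order
#'
#' The standard session: initial static block, the two naive
#' luminance-modulation blocks (counterphase and 90°, order
#' counterbalanced across observers), the in-phase control, the two
#' attention-instruction modulation blocks, and a final static block. The
#' eye-to-image assignment alternates block by block.
#'
#' @param mod180_first logical; if `TRUE` the 180° blocks precede the 90°
#'   blocks within the naive and attention pairs.
#' @return character vector of 7 condition labels.
#' @export
session_condition_order <- function(mod180_first = TRUE) {
  naive <- if (mod180_first) c("mod180_naive", "mod90_naive")
           else c("mod90_naive", "mod180_naive")
  attend <- if (mod180_first) c("mod180_attend", "mod90_attend")
            else c("mod90_attend", "mod180_attend")
  c("static", naive, "mod0_control", attend, "static")
}

condition_phase_diff <- function(condition) {
  switch(condition,
         static = 0,
         mod0_control = 0,
         mod180_naive = , mod180_attend = 180,
         mod90_naive = , mod90_attend = 90,
         stop("unknown condition: ", condition))
}

#' Build the schedule for one block of a session
#'
#' @param condition one of [CONDITION_LABELS].
#' @param face_left logical; `TRUE` puts the face image in the left eye.
#' @param cfg a [default_config()] supplying schedule parameters.
#' @return A [stimulus_schedule()].
#' @export
block_schedule <- function(condition, face_left = TRUE,
                           cfg = default_config()) {
  s <- cfg$schedule
  stimulus_schedule(
    freq = s$freq, phase_left_deg = s$phase_left_deg,
    phase_diff_deg = condition_phase_diff(condition),
    gamma = s$gamma, lum_lo = s$lum_lo, lum_hi = s$lum_hi,
    refresh_hz = s$refresh_hz, block_duration_s = s$block_duration_s,
    condition = condition,
    eye_assignment = if (face_left) c(left = "face", right = "house")
                     else c(left = "house", right = "face"))
}

#' Write a synthetic seven-block session to disk
#'
#' Generates one observer's session (7 blocks in the standard order, eye
#' assignment alternating per block), writes each block's raw trace and
#' reported events in the package TSV dialects, and a JSON manifest
#' holding the seed, parameters, condition order and per-block ground
#' truth.
#'
#' @param cfg a [default_config()]; `cfg$seed` seeds the generator and
#'   `cfg$simulation` supplies the model parameters.
#' @param dir output directory, created if needed.
#' @param mod180_first block-order counterbalancing flag.
#' @param face_left_first eye assignment of block 1.
#' @return Path to the manifest JSON, invisibly.
#' @export
make_fixture_session <- function(cfg = default_config(), dir,
                                 mod180_first = TRUE,
                                 face_left_first = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(simulation_params, as.list(unclass(cfg$simulation)))
  conds <- session_condition_order(mod180_first)
  set.seed(as.integer(cfg$seed))
  manifest <- list(seed = as.integer(cfg$seed),
                   params = unclass(params),
                   conditions = conds, blocks = list())
  for (b in seq_along(conds)) {
    face_left <- xor(!face_left_first, b %% 2 == 1)
    sch <- block_schedule(conds[b], face_left, cfg)
    id <- sprintf("block%02d", b)
    rep <- simulate_reports(params, sch, id)
    trace <- simulate_pupil(params, sch, rep$truth, block_id = id)
    write_pupil_trace(trace, file.path(dir, paste0(id, "_trace.tsv")))
    write_percept_timeline(rep$reported,
                           file.path(dir, paste0(id, "_events.tsv")))
    manifest$blocks[[id]] <- list(
      condition = conds[b],
      face_left = face_left,
      phase_diff_deg = sch$phase_diff_deg,
      truth = data.frame(onset = rep$truth$onset,
                         offset = rep$truth$offset,
                         label = rep$truth$label))
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(mpath)
}
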