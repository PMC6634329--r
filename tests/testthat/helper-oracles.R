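# Independent reference implementations used as oracles. These stay
# deliberately naive (loops, direct sums) and share no code with the
# package internals they check.

# Mann-Whitney AUC by exhaustive pair counting, right = positive class.
mw_auc <- function(left, right) {
  wins <- 0
  for (r in right) for (l in left) {
    if (r > l) wins <- wins + 1
    else if (r == l) wins <- wins + 0.5
  }
  wins / (length(left) * length(right))
}

# F1 coefficient by direct trigonometric inner products (the pinned
# convention: sine input -> i, cosine input -> 1).
trig_z <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  a <- (2 / N) * sum(x * sin(2 * pi * n / N))
  b <- (2 / N) * sum(x * cos(2 * pi * n / N))
  complex(real = b, imaginary = a)
}

# Change-rate rule re-implemented naively: SD of first differences over
# valid adjacent pairs, then invalidate the earlier pair member.
brute_rate_reject <- function(pupil, valid, k) {
  n <- length(pupil)
  d <- c()
  for (i in 1:(n - 1)) if (valid[i] && valid[i + 1])
    d <- c(d, pupil[i + 1] - pupil[i])
  s <- sd(d)
  out <- valid
  for (i in 1:(n - 1)) {
    if (valid[i] && valid[i + 1] &&
        abs(pupil[i + 1] - pupil[i]) > k * s)
      out[i] <- FALSE
  }
  out
}

# Button-press state machine evaluated sample by sample: the label at any
# time is a pure function of which buttons are down.
brute_button_labels <- function(time_ms, event, at_times) {
  lab <- character(length(at_times))
  for (j in seq_along(at_times)) {
    t <- at_times[j]
    L <- R <- FALSE
    # releases before presses at equal timestamps
    o <- order(time_ms, !(event %in% c("L_up", "R_up")))
    for (i in o) {
      if (time_ms[i] > t) next
      if (event[i] == "L_down") L <- TRUE
      if (event[i] == "L_up") L <- FALSE
      if (event[i] == "R_down") R <- TRUE
      if (event[i] == "R_up") R <- FALSE
    }
    lab[j] <- if (L && R) "mixed" else if (L) "left"
              else if (R) "right" else "none"
  }
  lab
}

# Random percept timeline on an integer-ms grid.
random_timeline <- function(dur_ms, mean_len_ms = 1500) {
  t <- 0; onset <- c(); offset <- c(); label <- c()
  labs <- c("left", "right", "mixed", "none")
  while (t < dur_ms) {
    len <- max(1, round(rexp(1, 1 / mean_len_ms)))
    onset <- c(onset, t); offset <- c(offset, min(t + len, dur_ms))
    label <- c(label, sample(labs, 1))
    t <- t + len
  }
  percept_timeline(onset, offset, label, dur_ms)
}

# Noise-free settings for deterministic pipeline checks; overridable.
quiet_params <- function(...) {
  base <- list(noise_sd = 0, drift_sd = 0, blink_rate_hz = 0,
               report_lag_ms = 0, pupil_delay_ms = 0)
  do.call(simulation_params, utils::modifyList(base, list(...)))
}
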