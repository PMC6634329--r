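#' Summarize rivalry behavior for a set of blocks
#'
#' For every block: the median duration of exclusive dominance periods per
#' stimulus type (face/house, mapped from the reporting eye through the
#' block's eye assignment) and the proportions of block time spent in
#' exclusive-face, exclusive-house, mixed and unreported states (the four
#' proportions sum to 1 per block).
#'
#' @param timelines named list of [percept_timeline()]s, one per block.
#' @param schedules named list of [stimulus_schedule()]s with matching
#'   names (supplies `condition` and `eye_assignment`).
#' @param subject subject label attached to every row.
#' @return list with `durations` (one row per exclusive interval:
#'   `subject`, `block`, `condition`, `stimulus`, `duration_s`),
#'   `medians` (per block x stimulus median duration; `NA` when a cell
#'   has no exclusive periods) and `proportions` (per block: `p_face`,
#'   `p_house`, `p_mixed`, `p_none`).
#' @export
summarize_behavior <- function(timelines, schedules, subject = "s01") {
  stopifnot(identical(sort(names(timelines)), sort(names(schedules))))
  dur_rows <- list(); med_rows <- list(); prop_rows <- list()
  for (b in names(timelines)) {
    tl <- timelines[[b]]; sch <- schedules[[b]]
    total <- attr(tl, "block_duration_ms")
    stim <- eye_to_image(sch, tl$label)
    len_s <- (tl$offset - tl$onset) / 1000
    excl <- !is.na(stim)
    if (any(excl))
      dur_rows[[b]] <- data.frame(
        subject = subject, block = b, condition = sch$condition,
        stimulus = stim[excl], duration_s = len_s[excl])
    for (im in c("face", "house")) {
      d <- len_s[excl & stim == im & !is.na(stim)]
      med_rows[[paste(b, im)]] <- data.frame(
        subject = subject, block = b, condition = sch$condition,
        stimulus = im,
        median_duration_s = if (length(d)) stats::median(d) else NA_real_,
        n_periods = length(d))
    }
    share <- function(lab) sum(len_s[tl$label == lab]) * 1000 / total
    ea <- sch$eye_assignment
    p_face <- if (ea[["left"]] == "face") share("left") else share("right")
    p_house <- if (ea[["left"]] == "house") share("left") else share("right")
    prop_rows[[b]] <- data.frame(
      subject = subject, block = b, condition = sch$condition,
      p_face = p_face, p_house = p_house,
      p_mixed = share("mixed"), p_none = share("none"))
  }
  list(durations = do.call(rbind, c(dur_rows, make.row.names = FALSE)),
       medians = do.call(rbind, c(med_rows, make.row.names = FALSE)),
       proportions = do.call(rbind, c(prop_rows, make.row.names = FALSE)))
}

#' Attention-instruction report proportions
#'
#' During attention-instruction blocks the observer is asked, in
#' alternating fixed-length intervals, to attend one of the two images.
#' This computes, for each image, the proportion of instructed-to-attend
#' time during which that image was reported as part of the percept at
#' all — exclusive dominance of that image's eye or a mixed report (not
#' necessarily exclusive perception).
#'
#' @param tl a [percept_timeline()].
#' @param sch the block's [stimulus_schedule()].
#' @param first_attended image attended in the first instruction interval
#'   (`"house"` or `"face"`).
#' @param interval_s instruction alternation interval in seconds
#'   (default 30).
#' @return data.frame with one row per image: `attended`, `p_reported`
#'   (share of that image's instructed time in which it was part of the
#'   percept) and `p_other_reported` (share for the non-attended image in
#'   the same intervals).
#' @export
attention_proportions <- function(tl, sch, first_attended = "house",
                                  interval_s = 30) {
  first_attended <- match.arg(first_attended, c("house", "face"))
  dur <- attr(tl, "block_duration_ms")
  iv_ms <- interval_s * 1000
  starts <- seq(0, dur - 1e-9, by = iv_ms)
  attended <- rep(c(first_attended,
                    setdiff(c("house", "face"), first_attended)),
                  length.out = length(starts))
  stim_l <- sch$eye_assignment[["left"]]
  # time inside [a, b) during which image `im` is part of the percept
  part_time <- function(a, b, im) {
    ov_on <- pmax(tl$onset, a); ov_off <- pmin(tl$offset, b)
    ov <- pmax(ov_off - ov_on, 0)
    eye <- if (stim_l == im) "left" else "right"
    sum(ov[tl$label %in% c(eye, "mixed")])
  }
  out <- lapply(c("house", "face"), function(im) {
    sel <- which(attended == im)
    tt <- sum(pmin(starts[sel] + iv_ms, dur) - starts[sel])
    rep_t <- sum(vapply(sel, function(i)
      part_time(starts[i], min(starts[i] + iv_ms, dur), im), 0))
    oth <- setdiff(c("house", "face"), im)
    oth_t <- sum(vapply(sel, function(i)
      part_time(starts[i], min(starts[i] + iv_ms, dur), oth), 0))
    data.frame(attended = im, p_reported = rep_t / tt,
               p_other_reported = oth_t / tt)
  })
  do.call(rbind, out)
}

#' Two-way repeated-measures ANOVA with generalized eta-squared
#'
#' Fully within-subjects two-factor ANOVA (e.g. 2 stimulus types x 7
#' conditions) on a complete balanced table. F ratios use the
#' conventional error strata (each within factor tested against its
#' subject-by-factor interaction, uncorrected df); effect sizes are
#' generalized eta-squared,
#' `eta2_G = SS_effect / (SS_effect + SS_subjects + SS_err_A + SS_err_B +
#' SS_err_AB)`,
#' the Olejnik-Algina definition for fully within designs, which is
#' comparable across designs. Degenerate all-equal data yield `F = 0`,
#' `p = 1`.
#'
#' @param data data.frame with columns `subject`, `type`, `condition`,
#'   `value`; every subject must contribute exactly one value per
#'   type x condition cell.
#' @return An object of class `anova_result`: data.frame with one row per
#'   effect (`type`, `condition`, `type:condition`): `F`, `df1`, `df2`,
#'   `p`, `eta2_g`, plus attribute `ss` holding the full sum-of-squares
#'   decomposition.
#' @export
rm_anova_2x7 <- function(data) {
  need <- c("subject", "type", "condition", "value")
  stopifnot(all(need %in% names(data)))
  if (any(is.na(data$value))) stop("missing cells in the ANOVA table")
  S <- factor(data$subject); A <- factor(data$type)
  B <- factor(data$condition)
  ns <- nlevels(S); na <- nlevels(A); nb <- nlevels(B)
  if (nrow(data) != ns * na * nb ||
      any(table(S, A, B) != 1))
    stop("table must be complete and balanced (one value per cell)")
  y <- data$value
  gm <- mean(y)
  mS <- tapply(y, S, mean); mA <- tapply(y, A, mean)
  mB <- tapply(y, B, mean)
  mSA <- tapply(y, list(S, A), mean); mSB <- tapply(y, list(S, B), mean)
  mAB <- tapply(y, list(A, B), mean)
  ss_S <- na * nb * sum((mS - gm)^2)
  ss_A <- ns * nb * sum((mA - gm)^2)
  ss_B <- ns * na * sum((mB - gm)^2)
  ss_AB <- ns * sum((mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  ss_SA <- nb * sum((mSA - outer(mS - gm, mA - gm, "+") - gm)^2)
  ss_SB <- na * sum((mSB - outer(mS - gm, mB - gm, "+") - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_SAB <- ss_tot - ss_S - ss_A - ss_B - ss_AB - ss_SA - ss_SB
  denom_g <- ss_S + ss_SA + ss_SB + ss_SAB

  eff <- function(name, ss_e, df1, ss_err, df2) {
    if (ss_err <= 0 || ss_e < 0) {
      f <- 0; p <- 1
    } else {
      f <- (ss_e / df1) / (ss_err / df2)
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    data.frame(effect = name, F = f, df1 = df1, df2 = df2, p = p,
               eta2_g = if (ss_e + denom_g > 0) ss_e / (ss_e + denom_g)
                        else 0)
  }
  res <- rbind(
    eff("type", ss_A, na - 1, ss_SA, (ns - 1) * (na - 1)),
    eff("condition", ss_B, nb - 1, ss_SB, (ns - 1) * (nb - 1)),
    eff("type:condition", ss_AB, (na - 1) * (nb - 1), ss_SAB,
        (ns - 1) * (na - 1) * (nb - 1)))
  attr(res, "ss") <- c(subjects = ss_S, type = ss_A, condition = ss_B,
                       `type:condition` = ss_AB, err_type = ss_SA,
                       err_condition = ss_SB, err_interaction = ss_SAB,
                       total = ss_tot)
  class(res) <- c("anova_result", "data.frame")
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subjects, uncorrected df)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  df$eta2_g <- signif(df$eta2_g, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Minimum detectable effect size (sensitivity analysis)
#'
#' The smallest true effect size `d` that a two-sided one-sample/paired
#' t-test with `n` subjects detects with the requested power at level
#' `alpha`. Power is evaluated exactly through the noncentral t
#' distribution (`df = n - 1`, noncentrality `d * sqrt(n)`) and `d` is
#' found by bisection to `1e-4`. With 12 subjects, alpha .05 and power
#' .80 the minimum detectable effect is d = 0.89 (1.15 for power .95).
#'
#' @param n number of subjects (>= 2).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return minimal detectable Cohen's d.
#' @seealso [power_paired_t()]
#' @export
#' @examples
#' sensitivity_min_d(12, 0.05, 0.80)
sensitivity_min_d <- function(n, alpha = 0.05, power = 0.80) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, power > 0, power < 1)
  lo <- 0; hi <- 1
  while (power_paired_t(hi, n, alpha) < power) {
    hi <- hi * 2
    if (hi > 1e4) stop("requested power unattainable")
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (power_paired_t(mid, n, alpha) >= power) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Exact power of the two-sided one-sample/paired t-test
#'
#' @param d true effect size (Cohen's d).
#' @param n number of subjects.
#' @param alpha two-sided significance level.
#' @return probability of rejecting at level `alpha` given `d`.
#' @export
power_paired_t <- function(d, n, alpha = 0.05) {
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}
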