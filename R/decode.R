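#' Two-source mixture amplitude
#'
#' In a linear, noise-free model where the dominant percept drives the
#' pupil oscillation with weight `w` and the suppressed percept with
#' `1 - w`, the amplitude of the summed oscillation relative to a single
#' source is `|w + (1 - w) * exp(i * delta_phi)|`. For `w = 0.9` this
#' yields 91% of the single-source amplitude under a 90° inter-eye phase
#' offset and 80% under counterphase (180°); for equal weights
#' (`w = 0.5`), 90° yields `sqrt(0.5)` (71%) and 180° cancels to 0.
#' Consequently oscillation amplitudes — and hence `|Z|` — are not
#' comparable across phase-offset conditions, which is why percept
#' dependence is tested within condition.
#'
#' @param w dominant-percept weight in `[0, 1]`.
#' @param delta_phi_deg inter-eye phase offset in degrees.
#' @return amplitude as a fraction of the single-source amplitude.
#' @export
#' @examples
#' mixture_amplitude(0.9, 90)    # 0.9055
#' mixture_amplitude(0.9, 180)   # 0.80
#' mixture_amplitude(0.5, 90)    # 0.7071
#' mixture_amplitude(0.5, 180)   # 0
mixture_amplitude <- function(w, delta_phi_deg) {
  stopifnot(all(w >= 0 & w <= 1))
  Mod(w + (1 - w) * exp(1i * delta_phi_deg * pi / 180))
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test plus two effect sizes: `d_s`, the mean
#' difference over the pooled SD of the two sets (the convention used
#' with the reported t values in this paradigm), and `d_z = t / sqrt(n)`,
#' the standard paired-design effect size, reported alongside.
#'
#' @param a,b numeric vectors of subject-matched measurements.
#' @return list with `t`, `df`, `p`, `d_s`, `d_z`, `n`,
#'   `mean_diff`.
#' @export
paired_t_with_ds <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  diffs <- a - b
  if (stats::sd(diffs) == 0) {
    tt <- list(statistic = 0, parameter = n - 1, p.value = 1)
  } else {
    ht <- stats::t.test(a, b, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  sd_pool <- sqrt((stats::var(a) + stats::var(b)) / 2)
  d_s <- if (sd_pool > 0) (mean(a) - mean(b)) / sd_pool else 0
  list(t = tt$statistic, df = tt$parameter, p = tt$p.value,
       d_s = d_s, d_z = tt$statistic / sqrt(n), n = n,
       mean_diff = mean(diffs))
}

#' Paired test on the sine-phase component across subjects
#'
#' Tests whether the imaginary (sine-phase) part of the per-subject mean
#' F1 component differs between left-eye-reported and right-eye-reported
#' cycles, with a two-sided paired t-test across subjects.
#'
#' @param group data.frame with one row per subject: complex columns
#'   `mean_z_left` and `mean_z_right` (per-subject means of `Z` over
#'   exclusive cycles), as built by [subject_condition_z()].
#' @return list as in [paired_t_with_ds()].
#' @export
paired_im_test <- function(group) {
  stopifnot(all(c("mean_z_left", "mean_z_right") %in% names(group)))
  ok <- stats::complete.cases(Re(group$mean_z_left),
                              Re(group$mean_z_right))
  if (sum(ok) < 2) stop("need at least 2 subjects with both means")
  paired_t_with_ds(Im(group$mean_z_left[ok]), Im(group$mean_z_right[ok]))
}

#' Per-subject complex means of Z by reported eye
#'
#' @param cycles data.frame of cycle records ([extract_cycles()]) with an
#'   added `subject` column, or a list of per-subject cycle data.frames.
#' @return data.frame with `subject`, `n_left`, `n_right`,
#'   `mean_z_left`, `mean_z_right` (complex; `NA` when a class is empty).
#' @export
subject_condition_z <- function(cycles) {
  if (is.data.frame(cycles)) {
    stopifnot("subject" %in% names(cycles))
    cycles <- split(cycles, cycles$subject)
  }
  res <- lapply(names(cycles), function(s) {
    cy <- cycles[[s]]
    zl <- cy$z[cy$label == "left"]
    zr <- cy$z[cy$label == "right"]
    data.frame(subject = s, n_left = length(zl), n_right = length(zr),
               mean_z_left = if (length(zl)) mean(zl) else NA_complex_,
               mean_z_right = if (length(zr)) mean(zr) else NA_complex_)
  })
  do.call(rbind, res)
}

#' ROC curve and AUC for percept scores
#'
#' Threshold classifier: a cycle is predicted right-eye-dominant when its
#' score exceeds the threshold (positive class = right eye). Sweeping the
#' threshold over all distinct scores yields hit and false-alarm rates;
#' the ROC is the step curve through those points and the AUC its
#' trapezoidal area. Ties between classes contribute half, so the AUC
#' equals the normalized Mann-Whitney statistic
#' `(#\{right > left\} + 0.5 * #ties) / (n_left * n_right)`.
#'
#' @param scores_left scores of left-eye-dominant cycles.
#' @param scores_right scores of right-eye-dominant cycles (positive
#'   class).
#' @return list with `auc` and `roc`, a data.frame of `(fpr, tpr)` points
#'   from (0,0) to (1,1).
#' @export
roc_auc <- function(scores_left, scores_right) {
  if (!length(scores_left) || !length(scores_right))
    stop("both classes must be non-empty")
  thr <- sort(unique(c(scores_left, scores_right)), decreasing = TRUE)
  tpr <- vapply(thr, function(th) mean(scores_right >= th), 0)
  fpr <- vapply(thr, function(th) mean(scores_left >= th), 0)
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(auc = auc, roc = roc)
}

#' Optimal complex-plane rotation for decoding
#'
#' Rather than scoring cycles only by the sine-phase component `Im(Z)`,
#' any projection axis in the complex plane can be used:
#' `score(theta) = Im(Z * exp(-i * theta))`. The AUC is computed for every
#' angle in 1° steps over `[0°, 180°)` and folded for orientation
#' (`max(AUC, 1 - AUC)`, since flipping the axis swaps the classes), which
#' covers all possible rotations; the angle maximizing the folded AUC is
#' returned (smallest angle on ties).
#'
#' @param z_left,z_right complex vectors of per-cycle `Z` by reported eye.
#' @param step_deg search step in degrees (default 1).
#' @return list with `theta_opt` (degrees), `auc_opt`, and `auc_by_angle`,
#'   a data.frame of `theta`, `auc` (raw, right eye positive) and
#'   `auc_folded`.
#' @export
optimal_rotation <- function(z_left, z_right, step_deg = 1) {
  thetas <- seq(0, 180 - step_deg, by = step_deg)
  auc <- vapply(thetas, function(th) {
    rot <- exp(-1i * th * pi / 180)
    roc_auc(Im(z_left * rot), Im(z_right * rot))$auc
  }, 0)
  folded <- pmax(auc, 1 - auc)
  i <- which.max(folded)            # which.max takes the first maximum
  list(theta_opt = thetas[i], auc_opt = folded[i],
       auc_by_angle = data.frame(theta = thetas, auc = auc,
                                 auc_folded = folded))
}

#' Decode percepts for a full session
#'
#' Per subject and condition: the per-cycle AUC along the sine-phase axis
#' (`Im(Z)`, right eye positive) and the optimal-rotation AUC; per
#' condition: the paired t-test on `Im(Z)` of per-subject means and a
#' one-sample two-sided t-test of the per-subject AUCs against chance
#' (0.5). Excluded cycles never enter any statistic; a subject missing a
#' class in some condition is dropped from that condition's group tests
#' with `NA` in the table.
#'
#' @param cycles data.frame of cycle records with `subject` and
#'   `condition` columns (and `label`, `z` as from [extract_cycles()]).
#' @param step_deg rotation search step in degrees.
#' @return list with `by_subject` (one row per subject x condition:
#'   `n_left`, `n_right`, `auc_im`, `theta_opt`, `auc_opt`) and
#'   `by_condition` (group stats: `im_t`, `im_df`, `im_p`, `im_d_s`,
#'   `mean_auc_im`, `auc_t`, `auc_p`, `mean_auc_opt`, `n_subjects`).
#' @export
decode_session <- function(cycles, step_deg = 1) {
  stopifnot(all(c("subject", "condition", "label", "z") %in%
                names(cycles)))
  cycles <- cycles[cycles$label %in% c("left", "right"), , drop = FALSE]
  by_subj <- list(); k <- 0
  for (cond in unique(cycles$condition)) {
    cc <- cycles[cycles$condition == cond, , drop = FALSE]
    for (s in unique(cc$subject)) {
      cy <- cc[cc$subject == s, , drop = FALSE]
      zl <- cy$z[cy$label == "left"]; zr <- cy$z[cy$label == "right"]
      k <- k + 1
      if (length(zl) && length(zr)) {
        opt <- optimal_rotation(zl, zr, step_deg)
        by_subj[[k]] <- data.frame(
          subject = s, condition = cond,
          n_left = length(zl), n_right = length(zr),
          mean_z_left = mean(zl), mean_z_right = mean(zr),
          auc_im = roc_auc(Im(zl), Im(zr))$auc,
          theta_opt = opt$theta_opt, auc_opt = opt$auc_opt)
      } else {
        by_subj[[k]] <- data.frame(
          subject = s, condition = cond,
          n_left = length(zl), n_right = length(zr),
          mean_z_left = NA_complex_, mean_z_right = NA_complex_,
          auc_im = NA_real_, theta_opt = NA_real_, auc_opt = NA_real_)
      }
    }
  }
  by_subj <- do.call(rbind, by_subj)

  by_cond <- lapply(unique(by_subj$condition), function(cond) {
    sub <- by_subj[by_subj$condition == cond & !is.na(by_subj$auc_im), ,
                   drop = FALSE]
    if (nrow(sub) < 2) {
      return(data.frame(condition = cond, n_subjects = nrow(sub),
                        im_t = NA_real_, im_df = NA_real_,
                        im_p = NA_real_, im_d_s = NA_real_,
                        mean_auc_im = mean(sub$auc_im),
                        auc_t = NA_real_, auc_p = NA_real_,
                        mean_auc_opt = mean(sub$auc_opt)))
    }
    imt <- paired_t_with_ds(Im(sub$mean_z_left), Im(sub$mean_z_right))
    auct <- if (stats::sd(sub$auc_im) > 0) {
      ht <- stats::t.test(sub$auc_im, mu = 0.5)
      list(t = unname(ht$statistic), p = ht$p.value)
    } else list(t = 0, p = 1)
    data.frame(condition = cond, n_subjects = nrow(sub),
               im_t = imt$t, im_df = imt$df, im_p = imt$p,
               im_d_s = imt$d_s,
               mean_auc_im = mean(sub$auc_im),
               auc_t = auct$t, auc_p = auct$p,
               mean_auc_opt = mean(sub$auc_opt))
  })
  list(by_subject = by_subj, by_condition = do.call(rbind, by_cond))
}
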