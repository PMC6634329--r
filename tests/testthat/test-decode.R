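test_that("mixture amplitude reproduces the analytic cases", {
  expect_equal(mixture_amplitude(0.9, 90), sqrt(0.81 + 0.01))
  expect_equal(round(100 * mixture_amplitude(0.9, 90)), 91)
  expect_equal(mixture_amplitude(0.9, 180), 0.8)
  expect_equal(mixture_amplitude(0.5, 90), sqrt(0.5))
  expect_equal(round(100 * mixture_amplitude(0.5, 90)), 71)
  expect_equal(mixture_amplitude(0.5, 180), 0)
  expect_equal(mixture_amplitude(1, c(0, 45, 137, 180)), rep(1, 4))
  expect_error(mixture_amplitude(1.2, 90))
})

test_that("mixture amplitude is monotone in the phase offset", {
  for (w in c(0.6, 0.75, 0.9)) {
    a <- mixture_amplitude(w, seq(0, 180, by = 5))
    expect_equal(a[1], 1)
    expect_true(all(diff(a) < 0))
  }
})

test_that("paired t-test matches the closed-form textbook formula", {
  a <- c(1.1, 2.3, 0.7); b <- c(0.9, 1.8, 1.0)
  res <- paired_t_with_ds(a, b)
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_ref, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-abs(t_ref), 2), tolerance = 1e-12)
  expect_equal(res$d_s, (mean(a) - mean(b)) /
                 sqrt((var(a) + var(b)) / 2), tolerance = 1e-12)
  expect_equal(res$d_z, t_ref / sqrt(3), tolerance = 1e-12)

  same <- paired_t_with_ds(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t_with_ds(1, 1), "2 pairs")
})

test_that("group Im(Z) test is powered on strong counterphase sessions", {
  # 12 simulated subjects, w_dom 0.9, modest noise: the percept effect on
  # the sine-phase component must reject in (essentially) every replicate
  params <- simulation_params(noise_sd = 10, drift_sd = 20,
                              blink_rate_hz = 0)
  sch <- stimulus_schedule(phase_diff_deg = 180, block_duration_s = 60)
  n_rej <- 0
  for (r in 1:20) {
    rows <- lapply(1:12, function(s) {
      blk <- simulate_block(params, sch, seed = 5000 + 100 * r + s)
      cy <- extract_cycles(zscore_block(interpolate_gaps(blk$trace)),
                           blk$reported, sch)
      cy$subject <- sprintf("s%02d", s)
      cy
    })
    grp <- subject_condition_z(do.call(rbind, rows))
    if (paired_im_test(grp)$p < 0.05) n_rej <- n_rej + 1
  }
  expect_gte(n_rej / 20, 0.95)
})

test_that("AUC equals brute-force Mann-Whitney pair counting", {
  set.seed(99)
  for (rep in 1:50) {
    nl <- sample(2:30, 1); nr <- sample(2:30, 1)
    # integer scores force plenty of ties
    l <- sample(0:5, nl, replace = TRUE) + rnorm(nl, 0, 0.01 * (rep %% 2))
    r <- sample(0:5, nr, replace = TRUE) + 0.5 +
      rnorm(nr, 0, 0.01 * (rep %% 2))
    expect_equal(roc_auc(l, r)$auc, mw_auc(l, r), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(1, 2), c(3, 4))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(101)
  for (rep in 1:10) {
    l <- rnorm(40); r <- rnorm(35, 0.8)
    ref <- as.numeric(pROC::auc(
      pROC::roc(response = c(rep(0, 40), rep(1, 35)),
                predictor = c(l, r), quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(l, r)$auc, ref, tolerance = 1e-12)
  }
})

test_that("ROC curve is a valid monotone step curve", {
  set.seed(7)
  roc <- roc_auc(rnorm(20), rnorm(25, 1))$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("rotation search geometry behaves as expected", {
  set.seed(15)
  # clusters separated along the real axis: the best projection is near
  # 90 degrees (exactly 90 only up to sampling noise and AUC plateaus)
  zl <- complex(real = rnorm(200, -1, 1), imaginary = rnorm(200, 0, 1))
  zr <- complex(real = rnorm(200, 1, 1), imaginary = rnorm(200, 0, 1))
  opt <- optimal_rotation(zl, zr)
  expect_gte(opt$theta_opt, 45)
  expect_lte(opt$theta_opt, 135)
  a90 <- opt$auc_by_angle$auc_folded[opt$auc_by_angle$theta == 90]
  expect_gte(a90, 0.95 * opt$auc_opt)
  expect_gt(opt$auc_opt, 0.85)

  # the optimum dominates the fixed sine-phase axis
  for (rep in 1:10) {
    zl <- complex(real = rnorm(25), imaginary = rnorm(25))
    zr <- complex(real = rnorm(25, 0.5), imaginary = rnorm(25, 0.3))
    opt <- optimal_rotation(zl, zr)
    expect_gte(opt$auc_opt, roc_auc(Im(zl), Im(zr))$auc)
    # 180-degree antiperiodicity before folding
    a0 <- opt$auc_by_angle$auc[opt$auc_by_angle$theta == 40]
    rot <- exp(-1i * (40 + 180) * pi / 180)
    expect_equal(roc_auc(Im(zl * rot), Im(zr * rot))$auc, 1 - a0,
                 tolerance = 1e-12)
  }
})

test_that("rotating all Z together shifts the optimum accordingly", {
  set.seed(25)
  zl <- complex(real = rnorm(40, -1), imaginary = rnorm(40, 0.5))
  zr <- complex(real = rnorm(40, 1), imaginary = rnorm(40, -0.5))
  base <- optimal_rotation(zl, zr)
  for (phi in c(30, 77, 140)) {
    rot <- exp(1i * phi * pi / 180)
    shifted <- optimal_rotation(zl * rot, zr * rot)
    expect_equal(shifted$auc_opt, base$auc_opt, tolerance = 1e-12)
    # the shifted image of the old optimum is again optimal (the argmax
    # itself may move along a plateau of tied AUCs)
    at <- (base$theta_opt + phi) %% 180
    expect_equal(
      shifted$auc_by_angle$auc_folded[shifted$auc_by_angle$theta == at],
      shifted$auc_opt, tolerance = 1e-12)
  }
})

test_that("1-degree search is within discretization of a finer search", {
  set.seed(33)
  for (rep in 1:5) {
    zl <- complex(real = rnorm(15), imaginary = rnorm(15))
    zr <- complex(real = rnorm(15, 0.7), imaginary = rnorm(15, 0.4))
    coarse <- optimal_rotation(zl, zr, step_deg = 1)
    fine <- optimal_rotation(zl, zr, step_deg = 0.1)
    # the finer grid can only improve, and only by what one 1-degree
    # step can buy on a finite sample
    expect_gte(fine$auc_opt + 1e-12, coarse$auc_opt)
    expect_lte(fine$auc_opt - coarse$auc_opt, 0.05)
    # the coarse optimum is exact on its own grid
    expect_equal(coarse$auc_opt,
                 max(fine$auc_by_angle$auc_folded[
                   fine$auc_by_angle$theta %% 1 < 1e-9]),
                 tolerance = 1e-12)
  }
})

test_that("session decoding separates conditions as designed", {
  cfg <- default_config(schedule = list(block_duration_s = 60))
  params <- simulation_params(noise_sd = 10, drift_sd = 20,
                              blink_rate_hz = 0.1)
  cy <- run_synthetic_study(n_subjects = 4,
                            conditions = c("mod180_naive",
                                           "mod0_control"),
                            params = params, cfg = cfg, seed = 77)
  res <- decode_session(cy)
  r180 <- res$by_condition[res$by_condition$condition == "mod180_naive", ]
  r0 <- res$by_condition[res$by_condition$condition == "mod0_control", ]
  expect_gt(r180$mean_auc_im, r0$mean_auc_im)
  expect_gt(r180$mean_auc_opt, 0.8)
  expect_lt(abs(r0$mean_auc_im - 0.5), 0.12)
  # per-subject table bookkeeping
  expect_equal(nrow(res$by_subject), 8)
  expect_true(all(res$by_subject$n_left + res$by_subject$n_right <=
                    102))   # 60 s at 1.7 Hz
  # excluded cycles never enter: all class counts from exclusive labels
  cnt <- table(cy$subject, cy$condition, cy$label)
  for (i in seq_len(nrow(res$by_subject))) {
    row <- res$by_subject[i, ]
    expect_equal(row$n_left,
                 unname(cnt[row$subject, row$condition, "left"]))
  }
})
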