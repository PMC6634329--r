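test_that("behavior summaries compute medians and time shares", {
  sch <- stimulus_schedule(block_duration_s = 300,
                           eye_assignment = c(left = "face",
                                              right = "house"))
  tl <- percept_timeline(0, 300000, "left", 300000)
  beh <- summarize_behavior(list(b1 = tl), list(b1 = sch))
  med <- beh$medians
  expect_equal(med$median_duration_s[med$stimulus == "face"], 300)
  expect_true(is.na(med$median_duration_s[med$stimulus == "house"]))
  expect_equal(beh$proportions$p_face, 1)
  expect_equal(beh$proportions$p_house + beh$proportions$p_mixed +
                 beh$proportions$p_none, 0)

  # hand-built durations {1,2,3} s -> median 2 s
  tl2 <- percept_timeline(
    c(0, 1000, 2000, 4000, 5000, 8000),
    c(1000, 2000, 4000, 5000, 8000, 10000),
    c("left", "mixed", "left", "mixed", "left", "none"), 10000)
  beh2 <- summarize_behavior(list(b = tl2), list(b = sch))
  expect_equal(
    beh2$medians$median_duration_s[beh2$medians$stimulus == "face"], 2)
  expect_equal(beh2$proportions$p_face, 0.6)
  expect_equal(beh2$proportions$p_mixed, 0.2)
  # proportions always partition the block
  expect_equal(with(beh2$proportions, p_face + p_house + p_mixed + p_none),
               1, tolerance = 1e-9)
})

test_that("behavior proportions recover the simulated ground truth", {
  sch <- stimulus_schedule(block_duration_s = 600)
  params <- simulation_params(report_lag_ms = 0)
  set.seed(4)
  rep <- simulate_reports(params, sch)
  beh <- summarize_behavior(list(b = rep$reported), list(b = sch))
  tr <- rep$truth
  p_left_truth <- sum((tr$offset - tr$onset)[tr$label == "left"]) / 600000
  expect_equal(beh$proportions$p_face, p_left_truth, tolerance = 1e-9)
})

test_that("attention proportions count any report of the instructed image", {
  sch <- stimulus_schedule(block_duration_s = 60,
                           eye_assignment = c(left = "house",
                                              right = "face"))
  # house (left eye) dominant for the whole first 30 s instruction
  # interval, mixed for all of the second
  tl <- percept_timeline(c(0, 30000), c(30000, 60000),
                         c("left", "mixed"), 60000)
  ap <- attention_proportions(tl, sch, first_attended = "house",
                              interval_s = 30)
  expect_equal(ap$p_reported[ap$attended == "house"], 1)   # exclusive
  expect_equal(ap$p_reported[ap$attended == "face"], 1)    # via mixed
  expect_equal(ap$p_other_reported[ap$attended == "face"], 1)
  expect_equal(ap$p_other_reported[ap$attended == "house"], 0)
})

test_that("rm-ANOVA matches a hand-worked decomposition and aov", {
  set.seed(44)
  tab <- expand.grid(subject = paste0("s", 1:3),
                     type = c("face", "house"),
                     condition = paste0("c", 1:7))
  tab$value <- rnorm(nrow(tab)) +
    rep(rnorm(3), times = 14) +                      # subject effects
    ifelse(tab$type == "face", 0.4, 0)               # a type effect
  res <- rm_anova_2x7(tab)

  fit <- stats::aov(value ~ type * condition +
                      Error(subject / (type * condition)), data = tab)
  sm <- summary(fit)
  get_f <- function(stratum, effect) {
    t <- sm[[stratum]][[1]]
    t[trimws(rownames(t)) == effect, "F value"]
  }
  expect_equal(res$F[res$effect == "type"],
               get_f("Error: subject:type", "type"), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition"],
               get_f("Error: subject:condition", "condition"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "type:condition"],
               get_f("Error: subject:type:condition", "type:condition"),
               tolerance = 1e-10)
  expect_equal(res$df1, c(1, 6, 6))
  expect_equal(res$df2, c(2, 12, 12))

  # generalized eta^2 against its definition, from aov sums of squares
  ss <- attr(res, "ss")
  denom <- ss[["subjects"]] + ss[["err_type"]] + ss[["err_condition"]] +
    ss[["err_interaction"]]
  expect_equal(res$eta2_g[res$effect == "type"],
               ss[["type"]] / (ss[["type"]] + denom), tolerance = 1e-12)

  # total sum-of-squares decomposition closes
  expect_equal(sum(ss[names(ss) != "total"]), ss[["total"]],
               tolerance = 1e-9)
})

test_that("generalized eta^2 never exceeds partial eta^2", {
  set.seed(50)
  for (rep in 1:10) {
    tab <- expand.grid(subject = paste0("s", 1:6),
                       type = c("a", "b"),
                       condition = paste0("c", 1:4))
    tab$value <- rnorm(nrow(tab)) + rep(rnorm(6), times = 8)
    res <- rm_anova_2x7(tab)
    ss <- attr(res, "ss")
    partial <- c(ss[["type"]] / (ss[["type"]] + ss[["err_type"]]),
                 ss[["condition"]] /
                   (ss[["condition"]] + ss[["err_condition"]]),
                 ss[["type:condition"]] /
                   (ss[["type:condition"]] + ss[["err_interaction"]]))
    expect_true(all(res$eta2_g <= partial + 1e-12))
    expect_true(all(res$eta2_g >= 0 & res$eta2_g <= 1))
    expect_true(all(res$F >= 0))
  }
})

test_that("rm-ANOVA edge cases: degenerate and malformed tables", {
  tab <- expand.grid(subject = paste0("s", 1:3), type = c("a", "b"),
                     condition = paste0("c", 1:7))
  tab$value <- 1
  res <- rm_anova_2x7(tab)
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  expect_error(rm_anova_2x7(tab[-1, ]), "balanced")
  tab$value[3] <- NA
  expect_error(rm_anova_2x7(tab), "missing")
})

test_that("the null 2x7 design rejects near the nominal rate", {
  set.seed(60)
  n_rep <- 200
  rej <- matrix(FALSE, n_rep, 3)
  for (r in 1:n_rep) {
    tab <- expand.grid(subject = paste0("s", 1:12),
                       type = c("a", "b"), condition = paste0("c", 1:7))
    tab$value <- rnorm(nrow(tab)) + rep(rnorm(12), times = 14)
    rej[r, ] <- rm_anova_2x7(tab)$p < 0.05
  }
  # binomial 99% band around 0.05 for 200 replicates: ~[0.01, 0.10]
  for (j in 1:3) {
    expect_gte(mean(rej[, j]), 0.005)
    expect_lte(mean(rej[, j]), 0.105)
  }
})

test_that("sensitivity analysis solves the noncentral-t power equation", {
  d80 <- sensitivity_min_d(12, 0.05, 0.80)
  d95 <- sensitivity_min_d(12, 0.05, 0.95)
  expect_equal(d80, 0.8887, tolerance = 1e-3)
  expect_equal(d95, 1.1460, tolerance = 1e-3)
  # bracketing: power crosses the target exactly at the solution
  expect_gte(power_paired_t(d80 + 1e-3, 12), 0.80)
  expect_lt(power_paired_t(d80 - 0.01, 12), 0.80)
  expect_gte(power_paired_t(d95 + 1e-3, 12), 0.95)
  expect_lt(power_paired_t(d95 - 0.01, 12), 0.95)
  # agreement with the stock power solver
  ref <- stats::power.t.test(n = 12, power = 0.8, type = "one.sample",
                             sig.level = 0.05)$delta
  expect_equal(d80, ref, tolerance = 1e-3)
})

test_that("sensitivity d is monotone in power and sample size", {
  ds <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95),
               function(p) sensitivity_min_d(12, 0.05, p), 0)
  expect_true(all(diff(ds) > 0))
  dn <- vapply(c(6, 12, 24, 48),
               function(n) sensitivity_min_d(n, 0.05, 0.8), 0)
  expect_true(all(diff(dn) < 0))
  expect_error(sensitivity_min_d(1, 0.05, 0.8))
})

test_that("attention-biased fixtures show the built-in bias", {
  # bias reports toward the attended image by lengthening its dominance
  sch <- stimulus_schedule(block_duration_s = 300,
                           condition = "mod180_attend")
  set.seed(70)
  a <- numeric(8); b <- numeric(8)
  for (s in 1:8) {
    # simple biased generator: attended-eye periods drawn longer
    t <- 0; onset <- c(); offset <- c(); label <- c(); eye <- "left"
    while (t < 300000) {
      len <- rgamma(1, 3.5, scale = if (eye == "left") 1.3 else 0.7) * 1000
      onset <- c(onset, t); offset <- c(offset, min(t + len, 300000))
      label <- c(label, eye)
      t <- t + len
      eye <- if (eye == "left") "right" else "left"
    }
    tl <- percept_timeline(onset, offset, label, 300000)
    ap <- attention_proportions(tl, sch, first_attended = "face")
    # left eye carries the face image here: face is "attended-boosted"
    a[s] <- ap$p_reported[ap$attended == "face"]
    b[s] <- ap$p_other_reported[ap$attended == "face"]
  }
  res <- paired_t_with_ds(a, b)
  expect_lt(res$p, 0.05)
  expect_gt(res$d_s, 0)
})
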