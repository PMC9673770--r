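test_that("the Poisson-binomial DP equals full enumeration", {
  set.seed(99)
  for (i in 1:25) {
    p <- runif(6)
    d <- dpoisbinom(p)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    for (k in 0:7) {
      expect_equal(poisson_binomial_tail(p, k), pb_tail_enum(p, k),
                   tolerance = 1e-12)
    }
  }
  # equal rates collapse to the binomial tail: P(S >= 3 | p = 1/2) = 42/64
  expect_equal(poisson_binomial_tail(rep(0.5, 6), 3), 42 / 64)
  expect_equal(poisson_binomial_tail(runif(6), 0), 1)
})

test_that("score tails under the RA marker rates are internally consistent
           with the published co-positivity and sensitivity", {
  p_ra <- c(0.690, 0.517, 0.586, 0.379, 0.586, 0.310)
  expect_lt(abs(poisson_binomial_tail(p_ra, 2) - 0.914), 0.02)
  expect_lt(abs(poisson_binomial_tail(p_ra, 3) - 0.673), 0.02)
})

test_that("model-implied ROC hits the degenerate anchors", {
  p <- c(0.690, 0.517, 0.586, 0.379, 0.586, 0.310)
  expect_equal(model_roc(p, p)$auc, 0.5, tolerance = 1e-12)
  expect_equal(model_roc(rep(1, 6), rep(0, 6))$auc, 1)
  m <- model_roc(p, p / 2)
  expect_true(all(diff(m$points$sensitivity) <= 0))
  expect_true(all(diff(m$points$specificity) >= 0))
})

test_that("calibration recovers a known logit shift and rejects
           unreachable targets", {
  p_ra <- c(0.690, 0.517, 0.586, 0.379, 0.586, 0.310)
  delta_star <- 0.9
  q_star <- plogis(qlogis(p_ra) - delta_star)
  m <- model_roc(p_ra, q_star)
  targets <- c(sens = poisson_binomial_tail(p_ra, 3),
               spec = 1 - poisson_binomial_tail(q_star, 3),
               auc = m$auc)
  cal <- calibrate_nra_rates(p_ra, targets = targets)
  expect_equal(cal$delta, delta_star, tolerance = 1e-6)
  expect_lt(cal$objective, 1e-10)
  # a zero shift leaves the classes identical: chance-level AUC
  cal0 <- calibrate_nra_rates(p_ra, targets = c(sens = poisson_binomial_tail(p_ra, 3),
                                                spec = 1 - poisson_binomial_tail(p_ra, 3),
                                                auc = 0.5))
  expect_equal(cal0$delta, 0, tolerance = 1e-5)
  expect_equal(cal0$achieved[["auc"]], 0.5, tolerance = 1e-6)
  expect_error(calibrate_nra_rates(p_ra, targets = c(sens = 0.999,
                                                     spec = 0.999,
                                                     auc = 0.999)),
               "infeasible")
})

test_that("the packaged calibration approaches the published operating point", {
  cfg <- default_config()
  cal <- calibrate_nra_rates(cfg$p_ra)
  expect_equal(cal$p_nra, cfg$p_nra, tolerance = 1e-10)
  expect_lt(abs(cal$achieved[["spec"]] - 0.630), 0.03)
  expect_lt(abs(cal$achieved[["auc"]] - 0.69), 0.03)
})

test_that("generation is deterministic in the seed", {
  cfg <- default_config(n = 150, seed = 31)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(default_config(n = 150, seed = 32))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("simulated cohorts recover the configured prevalence and
           per-marker RA rates", {
  cfg <- default_config(n = 5000, seed = 8)
  cohort <- generate_cohort(cfg)
  phat <- mean(cohort$diagnosis == "RA")
  se <- sqrt(cfg$prevalence * (1 - cfg$prevalence) / cfg$n)
  expect_lt(abs(phat - cfg$prevalence), 3 * se)

  scored <- score_cohort(cohort)
  ra <- scored[scored$diagnosis == "RA", ]
  markers <- c("painful_joints", "swollen_joints", "esr_high", "crp_high",
               "rf_positive", "erosive_arthritis")
  for (j in seq_along(markers)) {
    rate <- mean(ra[[markers[j]]])
    se_j <- sqrt(cfg$p_ra[j] * (1 - cfg$p_ra[j]) / nrow(ra))
    expect_lt(abs(rate - cfg$p_ra[j]), 3.5 * se_j)
  }
})

test_that("dichotomizing emitted labs reproduces the generated indicators
           and ages respect the inclusion bound", {
  cohort <- generate_cohort(default_config(n = 5000, seed = 12))
  expect_true(all(cohort$age > 16))
  scored <- score_cohort(cohort)
  # lab-emission consistency: joint counts positive iff indicator set
  expect_identical(scored$painful_joints,
                   as.integer(cohort$painful_joint_count >= 1))
  expect_identical(scored$esr_high, as.integer(cohort$esr > 28))
  expect_identical(scored$rf_positive, as.integer(cohort$rf >= 20))
  # the inclusion filter retains every generated record
  expect_equal(apply_inclusion(cohort)$report$n_retained, 5000)
})

test_that("an exchangeable latent correlation preserves the marginals while
           inflating co-positivity", {
  cfg0 <- default_config(n = 4000, seed = 21, rho = 0)
  cfg8 <- default_config(n = 4000, seed = 21, rho = 0.8)
  s0 <- score_cohort(generate_cohort(cfg0))
  s8 <- score_cohort(generate_cohort(cfg8))
  markers <- c("painful_joints", "swollen_joints", "esr_high", "crp_high",
               "rf_positive", "erosive_arthritis")
  ra0 <- s0[s0$diagnosis == "RA", ]; ra8 <- s8[s8$diagnosis == "RA", ]
  for (j in seq_along(markers)) {
    expect_lt(abs(mean(ra8[[markers[j]]]) - cfg8$p_ra[j]), 0.07)
  }
  # stronger dependence spreads the score distribution outward
  expect_gt(var(ra8$score), var(ra0$score))
})

test_that("configurations validate and round-trip through JSON", {
  cfg <- default_config(n = 77, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  expect_identical(as.data.frame(generate_cohort(back)),
                   as.data.frame(generate_cohort(cfg)))
  bad <- cfg; bad$prevalence <- 1.4
  expect_error(generate_cohort(bad), "prevalence")
  bad2 <- cfg; bad2$p_ra <- c(0.5, 0.5)
  expect_error(generate_cohort(bad2), "p_ra")
})
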