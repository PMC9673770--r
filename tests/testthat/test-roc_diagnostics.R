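test_that("criterion thresholds are midpoints plus outer sentinels", {
  expect_equal(threshold_set(0:6), c(-1, seq(0.5, 5.5, by = 1), 7))
  expect_true(2.5 %in% threshold_set(c(3, 4, 1, 0, 2, 3)))
  expect_equal(threshold_set(c(4, 4, 4)), c(3, 5))
  expect_equal(threshold_set(c(0, 2)), c(-1, 1, 3))
})

test_that("confusion counts and sensitivity/specificity match hand tallies", {
  toy <- scored_set(c(3, 4, 1), c(0, 2, 3))
  conf <- confusion_at(toy, 2.5)
  expect_equal(conf, c(tp = 2L, fn = 1L, fp = 1L, tn = 2L))
  ss <- sensitivity_specificity(conf)
  expect_equal(unname(ss), c(2 / 3, 2 / 3))
  expect_equal(unname(confusion_at(toy, -2)), c(3L, 0L, 3L, 0L))
  expect_equal(unname(confusion_at(toy, 99)), c(0L, 3L, 0L, 3L))
  expect_error(confusion_at(scored_set(c(1, 2), numeric(0)), 1), "nonempty")
})

test_that("the ROC curve is monotone and anchored at both corners", {
  toy <- scored_set(c(3, 4, 1), c(0, 2, 3))
  curve <- roc_curve(toy)
  expect_equal(nrow(curve), 6)  # 5 distinct values -> 4 midpoints + 2 outer
  expect_equal(curve$sensitivity[1], 0)
  expect_equal(curve$specificity[1], 1)
  expect_equal(curve$sensitivity[nrow(curve)], 1)
  expect_equal(curve$specificity[nrow(curve)], 0)
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_true(all(diff(curve$specificity) <= 0))
  expect_true(all(diff(curve$criterion) < 0))

  sep <- roc_curve(scored_set(c(2, 3), c(0, 1)))
  expect_true(any(sep$sensitivity == 1 & sep$specificity == 1))
  expect_equal(auc_trapezoid(sep), 1)
  diag <- roc_curve(scored_set(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(auc_trapezoid(diag), 0.5)
})

test_that("trapezoidal and rank AUC agree with the pairwise oracle", {
  ra <- c(1, 2, 2); nra <- c(0, 2, 1)
  toy <- scored_set(ra, nra)
  expect_equal(auc_rank(toy), 6.5 / 9)
  expect_equal(auc_trapezoid(roc_curve(toy)), 6.5 / 9)
  expect_equal(auc_pairwise(ra, nra), 6.5 / 9)
})

test_that("trapezoid equals rank equals pairwise enumeration on random
           instances, with label-swap antisymmetry and shift invariance", {
  set.seed(2024)
  for (i in 1:300) {
    n_pos <- sample(2:12, 1); n_neg <- sample(2:12, 1)
    ra <- sample(0:6, n_pos, replace = TRUE)
    nra <- sample(0:6, n_neg, replace = TRUE)
    s <- scored_set(ra, nra)
    a_trap <- auc_trapezoid(roc_curve(s))
    a_rank <- auc_rank(s)
    expect_equal(a_trap, a_rank, tolerance = 1e-12)
    expect_equal(a_rank, auc_pairwise(ra, nra), tolerance = 1e-12)
    # swapping the class labels reflects the AUC
    swapped <- s
    swapped$diagnosis <- ifelse(s$diagnosis == "RA", "NRA", "RA")
    expect_equal(auc_rank(swapped), 1 - a_rank, tolerance = 1e-12)
    # adding a constant to every score changes nothing
    shifted <- s; shifted$score <- s$score + 3
    expect_equal(auc_trapezoid(roc_curve(shifted)), a_trap, tolerance = 1e-12)
  }
})

test_that("empirical AUC matches pROC on simulated cohorts", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    scored <- score_cohort(generate_cohort(default_config(n = 300, seed = seed)))
    ref <- pROC::auc(pROC::roc(scored$diagnosis, scored$score,
                               levels = c("NRA", "RA"), direction = "<",
                               quiet = TRUE))
    expect_equal(auc_trapezoid(roc_curve(scored)), as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil interval matches the closed form and shrinks with n", {
  est <- auc_ci(0.69, n_pos = 58, n_neg = 343)
  # closed form evaluated by hand: Q1 = .69/1.31, Q2 = 2*.69^2/1.69
  q1 <- 0.69 / (2 - 0.69); q2 <- 2 * 0.69^2 / (1 + 0.69)
  se_hand <- sqrt((0.69 * 0.31 + 57 * (q1 - 0.69^2) + 342 * (q2 - 0.69^2)) /
                    (58 * 343))
  expect_equal(est$se, se_hand)
  expect_equal(est$se, 0.0407, tolerance = 0.002)
  expect_equal(c(est$ci_low, est$ci_high), c(0.610, 0.770), tolerance = 0.002)
  expect_true(est$ci_low <= est$auc && est$auc <= est$ci_high)
  # symmetric about 0.5 for a chance-level test with equal groups
  mid <- auc_ci(0.5, 30, 30)
  expect_equal(mid$auc - mid$ci_low, mid$ci_high - mid$auc, tolerance = 1e-12)
  # degenerate perfect separation has zero width
  perfect <- auc_ci(1, 10, 10)
  expect_equal(perfect$se, 0)
  expect_equal(c(perfect$ci_low, perfect$ci_high), c(1, 1))
  # SE -> 0 as both groups grow with A fixed
  ses <- vapply(c(10, 100, 1000, 10000),
                function(n) auc_ci(0.69, n, n)$se, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[4], 0.01)
  expect_error(auc_ci(0.7, 1, 50), "at least 2")
})

test_that("DeLong interval agrees with pROC's implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    scored <- score_cohort(generate_cohort(default_config(n = 250, seed = seed + 10)))
    curve <- roc_curve(scored)
    est <- auc_ci(auc_trapezoid(curve), attr(curve, "n_pos"),
                  attr(curve, "n_neg"), method = "delong", scored = scored)
    ref <- pROC::ci.auc(pROC::roc(scored$diagnosis, scored$score,
                                  levels = c("NRA", "RA"), direction = "<",
                                  quiet = TRUE), method = "delong")
    expect_equal(est$ci_low, max(0, as.numeric(ref)[1]), tolerance = 1e-8)
    expect_equal(est$ci_high, min(1, as.numeric(ref)[3]), tolerance = 1e-8)
  }
  expect_error(auc_ci(0.7, 10, 10, method = "delong"), "scored")
})

test_that("Youden-optimal criterion maximizes J with low-criterion ties", {
  toy <- scored_set(c(3, 4, 1), c(0, 2, 3))
  # hand evaluation: J = 1/3 at criteria 0.5, 2.5 and 3.5; the tie-break
  # rule picks the smallest (most sensitive) criterion
  opt <- youden_optimal(roc_curve(toy))
  expect_equal(opt$criterion, 0.5)
  expect_equal(opt$J, 1 / 3)
  sep <- youden_optimal(roc_curve(scored_set(c(2, 3), c(0, 1))))
  expect_equal(sep$J, 1)
  expect_equal(sep$criterion, 1.5)
  diag <- youden_optimal(roc_curve(scored_set(c(0, 1, 2), c(0, 1, 2))))
  expect_equal(diag$J, 0)
  expect_equal(diag$criterion, -1)  # smallest criterion under a full tie
})

test_that("the score-by-diagnosis cross-tabulation conserves group sizes", {
  ct <- score_crosstab(scored_set(c(3, 3, 4), c(0)))
  expect_equal(ct$count_ra, c(0L, 0L, 0L, 2L, 1L, 0L, 0L))
  expect_equal(ct$count_nra, c(1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_error(score_crosstab(scored_set(c(3), numeric(0))), "nonempty")
  expect_error(score_crosstab(scored_set(c(7), c(1))), "0..6")

  scored <- score_cohort(generate_cohort(default_config(n = 401, seed = 4)))
  ct <- score_crosstab(scored)
  expect_equal(sum(ct$count_ra), sum(scored$diagnosis == "RA"))
  expect_equal(sum(ct$count_nra), sum(scored$diagnosis == "NRA"))

  # file round-trip and reconstruction of the scored multiset
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosstab(ct, path)
  expect_equal(as.data.frame(read_crosstab(path)), as.data.frame(ct),
               ignore_attr = TRUE)
  rebuilt <- scores_from_crosstab(ct)
  expect_equal(auc_rank(rebuilt), auc_rank(scored), tolerance = 1e-12)
  expect_equal(as.data.frame(score_crosstab(rebuilt)), as.data.frame(ct),
               ignore_attr = TRUE)
})
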