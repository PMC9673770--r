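#' Criterion thresholds for a set of scores
#'
#' Candidate ROC criteria are the midpoints between consecutive distinct
#' observed score values, extended by one unit below the minimum and above
#' the maximum so the curve reaches both degenerate corners. For integer
#' scores spanning 0..6 this yields -1, 0.5, 1.5, ..., 5.5, 7, which is the
#' convention under which a criterion such as 2.5 arises.
#'
#' @param scores numeric vector of observed scores.
#' @return Increasing numeric vector of criteria.
#' @export
threshold_set <- function(scores) {
  if (length(scores) == 0L) stop("scores must be nonempty")
  v <- sort(unique(scores))
  if (length(v) == 1L) return(c(v - 1, v + 1))
  c(v[1] - 1, (v[-length(v)] + v[-1]) / 2, v[length(v)] + 1)
}

extract_scores <- function(scored) {
  df <- as.data.frame(scored)
  if (!all(c("score", "diagnosis") %in% names(df))) {
    stop("scored records need 'score' and 'diagnosis' columns")
  }
  pos <- df$score[df$diagnosis == "RA"]
  neg <- df$score[df$diagnosis == "NRA"]
  list(pos = pos, neg = neg)
}

#' Confusion matrix of the score at a criterion
#'
#' A record is test-positive when its score is greater than or equal to the
#' criterion; higher scores indicate RA.
#'
#' @param scored an `ra_scored` data frame (or any data frame with `score`
#'   and `diagnosis`).
#' @param criterion real threshold.
#' @return Named vector `c(tp, fn, fp, tn)`.
#' @export
confusion_at <- function(scored, criterion) {
  s <- extract_scores(scored)
  if (length(s$pos) == 0L || length(s$neg) == 0L) {
    stop("both diagnosis groups must be nonempty to form a confusion matrix")
  }
  c(tp = sum(s$pos >= criterion), fn = sum(s$pos < criterion),
    fp = sum(s$neg >= criterion), tn = sum(s$neg < criterion))
}

#' Sensitivity and specificity from a confusion matrix
#'
#' @param confusion named vector `c(tp, fn, fp, tn)` from [confusion_at()].
#' @return Named vector `c(sensitivity, specificity)` of proportions.
#' @export
sensitivity_specificity <- function(confusion) {
  tp <- confusion[["tp"]]; fn <- confusion[["fn"]]
  fp <- confusion[["fp"]]; tn <- confusion[["tn"]]
  if (tp + fn == 0 || fp + tn == 0) {
    stop("sensitivity/specificity undefined: a diagnosis group is empty")
  }
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Empirical ROC curve of the prediction score
#'
#' One operating point per criterion from [threshold_set()], ordered by
#' descending criterion so sensitivity is non-decreasing and specificity
#' non-increasing along the curve; the first and last points are the
#' degenerate corners (sensitivity 0 / specificity 1 and sensitivity 1 /
#' specificity 0).
#'
#' @param scored an `ra_scored` data frame.
#' @return Data frame of class `ra_roc` with columns `criterion`,
#'   `sensitivity`, `specificity`, and attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scored) {
  s <- extract_scores(scored)
  if (length(s$pos) == 0L || length(s$neg) == 0L) {
    stop("both diagnosis groups must be nonempty for a ROC curve")
  }
  crit <- rev(threshold_set(c(s$pos, s$neg)))
  pts <- t(vapply(crit, function(cr) {
    sensitivity_specificity(confusion_at(scored, cr))
  }, c(sensitivity = 0, specificity = 0)))
  out <- data.frame(criterion = crit,
                    sensitivity = pts[, "sensitivity"],
                    specificity = pts[, "specificity"])
  rownames(out) <- NULL
  structure(out, class = c("ra_roc", "data.frame"),
            n_pos = length(s$pos), n_neg = length(s$neg))
}

#' Area under the ROC curve by the trapezoidal rule
#'
#' Integrates sensitivity over 1 - specificity across the ordered operating
#' points of the empirical curve.
#'
#' @param curve an `ra_roc` from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(curve) {
  x <- 1 - curve$specificity
  y <- curve$sensitivity
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Rank (Mann-Whitney) estimate of the AUC
#'
#' The probability that a random RA record outscores a random NRA record,
#' counting ties as one half. Computed from midranks, which is equivalent
#' to averaging over all `n_pos * n_neg` pairs; it equals the trapezoidal
#' area of the empirical ROC curve.
#'
#' @param scored an `ra_scored` data frame.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scored) {
  s <- extract_scores(scored)
  if (length(s$pos) == 0L || length(s$neg) == 0L) {
    stop("both diagnosis groups must be nonempty for the AUC")
  }
  r <- rank(c(s$pos, s$neg))
  n_pos <- length(s$pos); n_neg <- length(s$neg)
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confidence interval for the AUC
#'
#' Two standard errors are available. `hanley_mcneil` uses the closed form
#' `SE^2 = [A(1-A) + (n_pos-1)(Q1 - A^2) + (n_neg-1)(Q2 - A^2)] /
#' (n_pos n_neg)` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. `delong` uses
#' the empirical covariance of the placement values and requires the scored
#' records. The interval is `A +/- z SE`, clipped to `[0, 1]`.
#'
#' @param auc the AUC estimate `A`.
#' @param n_pos,n_neg group sizes (each at least 2).
#' @param confidence confidence level, default 0.95.
#' @param method `"hanley_mcneil"` (default) or `"delong"`.
#' @param scored scored records, required for `method = "delong"`.
#' @return List of class `auc_estimate` with `auc`, `se`, `ci_low`,
#'   `ci_high`, `method`, `confidence`.
#' @export
auc_ci <- function(auc, n_pos, n_neg, confidence = 0.95,
                   method = c("hanley_mcneil", "delong"), scored = NULL) {
  method <- match.arg(method)
  if (n_pos < 2 || n_neg < 2) {
    stop("each diagnosis group must have at least 2 records for a CI")
  }
  if (method == "hanley_mcneil") {
    a <- auc
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
                  (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  } else {
    if (is.null(scored)) stop("method 'delong' requires the scored records")
    s <- extract_scores(scored)
    psi <- function(x, y) (x > y) + 0.5 * (x == y)
    # placement values: per-positive and per-negative mean pairwise wins
    v10 <- vapply(s$pos, function(x) mean(psi(x, s$neg)), numeric(1))
    v01 <- vapply(s$neg, function(y) mean(psi(s$pos, y)), numeric(1))
    auc <- mean(v10)
    se <- sqrt(stats::var(v10) / length(v10) + stats::var(v01) / length(v01))
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  structure(list(auc = auc, se = se,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 method = method, confidence = confidence),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC = %.2f (%.0f%% CI [%.2f-%.2f], SE %.4f, %s)\n",
              x$auc, 100 * x$confidence, x$ci_low, x$ci_high, x$se,
              x$method))
  invisible(x)
}

#' Youden-optimal criterion of a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the curve's
#' criteria; ties are broken toward the smaller criterion (the more
#' sensitive cutoff).
#'
#' @param curve an `ra_roc`.
#' @return List with `criterion`, `J`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(curve) {
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(curve$criterion[best])]
  list(criterion = curve$criterion[pick], J = j[pick],
       sensitivity = curve$sensitivity[pick],
       specificity = curve$specificity[pick])
}

#' Cross-tabulation of score level by diagnosis
#'
#' The index-test-by-reference-standard table: counts of each score level
#' 0..6 within the RA and NRA groups.
#'
#' @param scored an `ra_scored` data frame; scores must lie in 0..6 and
#'   both groups must be nonempty.
#' @return Data frame of class `ra_crosstab` with columns `score_level`,
#'   `count_ra`, `count_nra`; column sums equal the group sizes.
#' @export
score_crosstab <- function(scored) {
  s <- extract_scores(scored)
  if (length(s$pos) == 0L || length(s$neg) == 0L) {
    stop("both diagnosis groups must be nonempty for a cross-tabulation")
  }
  all_scores <- c(s$pos, s$neg)
  if (any(all_scores < 0 | all_scores > 6 | all_scores != floor(all_scores))) {
    stop("scores must be integers in 0..6")
  }
  lev <- 0:6
  out <- data.frame(
    score_level = lev,
    count_ra = vapply(lev, function(k) sum(s$pos == k), integer(1)),
    count_nra = vapply(lev, function(k) sum(s$neg == k), integer(1)))
  class(out) <- c("ra_crosstab", "data.frame")
  out
}

#' Read / write a score-by-diagnosis cross-tabulation
#'
#' Delimited-text serialization with columns `score_level`, `count_ra`,
#' `count_nra`, one row per score level.
#'
#' @param path file path.
#' @return `read_crosstab` returns an `ra_crosstab`; `write_crosstab`
#'   returns `path` invisibly.
#' @export
read_crosstab <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("score_level", "count_ra", "count_nra")
  if (!all(needed %in% names(df))) {
    stop("cross-tab file needs columns: ", paste(needed, collapse = ", "))
  }
  df <- df[order(df$score_level), needed]
  rownames(df) <- NULL
  class(df) <- c("ra_crosstab", "data.frame")
  df
}

#' @rdname read_crosstab
#' @param crosstab an `ra_crosstab`.
#' @export
write_crosstab <- function(crosstab, path) {
  utils::write.csv(as.data.frame(crosstab), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Expand a cross-tabulation back into scored records
#'
#' Reconstructs an `ra_scored` data frame (with synthetic patient
#' identifiers) from the 2 x k table, so ROC analyses can be run on a
#' published cross-tabulation when patient-level data is unavailable. The
#' score/diagnosis joint distribution is preserved exactly.
#'
#' @param crosstab an `ra_crosstab`.
#' @return An `ra_scored` data frame.
#' @export
scores_from_crosstab <- function(crosstab) {
  rows <- list()
  for (i in seq_len(nrow(crosstab))) {
    k <- crosstab$score_level[i]
    rows[[length(rows) + 1L]] <- data.frame(
      score = rep(k, crosstab$count_ra[i] + crosstab$count_nra[i]),
      diagnosis = rep(c("RA", "NRA"),
                      c(crosstab$count_ra[i], crosstab$count_nra[i])),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  out <- data.frame(patient_id = sprintf("X%04d", seq_len(nrow(df))),
                    score = as.integer(df$score), diagnosis = df$diagnosis,
                    stringsAsFactors = FALSE)
  class(out) <- c("ra_scored", "data.frame")
  out
}

#' Plot an empirical ROC curve
#'
#' @param x an `ra_roc`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ra_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "b", pch = 16,
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}
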