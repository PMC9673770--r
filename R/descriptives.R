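#' Cohort prevalence of the positive reference-standard label
#'
#' @param cohort an `ra_cohort` in which every record carries a diagnosis.
#' @return List with `n_ra`, `n_total`, `proportion`, and `percent` (the
#'   proportion times 100, rounded to two decimals).
#' @export
prevalence <- function(cohort) {
  if (nrow(cohort) == 0L) stop("cannot compute prevalence of an empty cohort")
  if (anyNA(cohort$diagnosis)) {
    stop("every record must have a diagnosis; run apply_inclusion() first")
  }
  n_ra <- sum(cohort$diagnosis == "RA")
  n <- nrow(cohort)
  list(n_ra = n_ra, n_total = n, proportion = n_ra / n,
       percent = round_half_up(100 * n_ra / n, 2))
}

#' Frequency table for a categorical or set-valued cohort variable
#'
#' For single-valued categorical variables, tabulates counts and
#' percentages of each level within each group (percentages of the group
#' size, one decimal). For the set-valued variables (`presentations`,
#' `comorbidities`), each vocabulary item is tabulated as present/absent
#' within the group, so percentages need not sum to 100.
#'
#' @param cohort an `ra_cohort`.
#' @param variable one of the categorical fields (`gender`, `nationality`,
#'   `marital_status`, `residence`, `occupation`, `smoking`) or a set
#'   variable (`presentations`, `comorbidities`).
#' @param by_diagnosis if `TRUE`, adds per-diagnosis-group rows alongside
#'   the whole-cohort rows.
#' @return A data frame of class `ra_freqtab` with columns `variable`,
#'   `group`, `level`, `count`, `pct`.
#' @export
frequency_table <- function(cohort, variable, by_diagnosis = FALSE) {
  valid <- c(names(ra_categorical_levels), "presentations", "comorbidities")
  if (!variable %in% valid) {
    stop("unknown variable '", variable, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  groups <- list(all = rep(TRUE, nrow(cohort)))
  if (by_diagnosis) {
    groups$NRA <- cohort$diagnosis == "NRA" & !is.na(cohort$diagnosis)
    groups$RA <- cohort$diagnosis == "RA" & !is.na(cohort$diagnosis)
  }
  rows <- list()
  for (g in names(groups)) {
    sub <- cohort[groups[[g]], , drop = FALSE]
    n_group <- nrow(sub)
    if (variable %in% c("presentations", "comorbidities")) {
      vocab <- if (variable == "presentations") ra_presentations else ra_comorbidities
      items <- split_items(sub[[variable]])
      counts <- vapply(vocab, function(it)
        sum(vapply(items, function(s) it %in% s, logical(1))), integer(1))
      levels_out <- vocab
    } else {
      levels_out <- ra_categorical_levels[[variable]]
      counts <- vapply(levels_out, function(lv)
        sum(sub[[variable]] == lv, na.rm = TRUE), integer(1))
    }
    rows[[g]] <- data.frame(
      variable = variable, group = g, level = levels_out,
      count = as.integer(counts),
      pct = if (n_group > 0) round_half_up(100 * counts / n_group, 1) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ra_freqtab", "data.frame")
  out
}

#' Co-positivity: share of records with at least k items present
#'
#' @param x either an `ra_scored` data frame (items are indicator column
#'   names) or a character vector of semicolon-delimited item sets, as in
#'   the `presentations`/`comorbidities` cohort columns.
#' @param items item (or column) names to count.
#' @param k minimum number of simultaneously present items.
#' @return Percentage of records with at least `k` of the listed items,
#'   unrounded. `k = 0` is vacuously 100; `k` above the number of items
#'   returns 0 with a warning.
#' @export
copositivity <- function(x, items, k) {
  if (k < 0) stop("k must be nonnegative")
  if (k > length(items)) {
    warning("k = ", k, " exceeds the ", length(items),
            " listed items; co-positivity is 0%")
    return(0)
  }
  if (is.data.frame(x)) {
    missing_cols <- setdiff(items, names(x))
    if (length(missing_cols) > 0L) {
      stop("unknown item column(s): ", paste(missing_cols, collapse = ", "))
    }
    n_present <- rowSums(as.data.frame(x)[, items, drop = FALSE])
  } else {
    sets <- split_items(x)
    n_present <- vapply(sets, function(s) sum(items %in% s), numeric(1))
  }
  if (length(n_present) == 0L) stop("no records supplied")
  100 * mean(n_present >= k)
}

#' Group mean and sample standard deviation of a numeric variable
#'
#' @param cohort an `ra_cohort`.
#' @param variable a numeric field, e.g. `"age"`.
#' @param group optional diagnosis group (`"RA"` or `"NRA"`); `NULL` uses
#'   the whole cohort.
#' @return Named vector `c(mean, sd, n)`. The standard deviation uses the
#'   n - 1 denominator and is `NA` (with a warning) for a single record.
#' @export
group_moments <- function(cohort, variable, group = NULL) {
  if (!variable %in% names(cohort) || !is.numeric(cohort[[variable]])) {
    stop("'", variable, "' is not a numeric cohort variable")
  }
  v <- cohort[[variable]]
  if (!is.null(group)) v <- v[cohort$diagnosis == group]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("group is empty")
  s <- if (length(v) == 1L) {
    warning("single observation: standard deviation undefined")
    NA_real_
  } else stats::sd(v)
  c(mean = mean(v), sd = s, n = length(v))
}

#' Minimum sample size for a specificity-driven diagnostic accuracy study
#'
#' Buderer-type calculation: the number of disease-negative subjects needed
#' to estimate specificity `SP` within half-width `d` at the given
#' confidence is `z^2 * SP * (1 - SP) / d^2`; dividing by `1 - prevalence`
#' inflates it to the total cohort size. The result is reported to the
#' nearest whole participant.
#'
#' @param expected_specificity anticipated specificity, in (0, 1).
#' @param precision half-width of the confidence interval, in (0, 1).
#' @param expected_prevalence anticipated prevalence of the target
#'   condition, in `[0, 1)`.
#' @param confidence confidence level, default 0.95.
#' @return Integer minimum total sample size.
#' @export
required_sample_size <- function(expected_specificity, precision,
                                 expected_prevalence, confidence = 0.95) {
  sp <- expected_specificity; d <- precision; prev <- expected_prevalence
  if (!(sp > 0 && sp < 1)) stop("expected_specificity must be in (0, 1)")
  if (!(d > 0 && d < 1)) stop("precision must be in (0, 1)")
  if (prev >= 1) stop("expected_prevalence must be below 1")
  if (prev < 0) stop("expected_prevalence must be nonnegative")
  if (!(confidence > 0 && confidence < 1)) stop("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n_neg <- z^2 * sp * (1 - sp) / d^2
  as.integer(round_half_up(n_neg / (1 - prev)))
}
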