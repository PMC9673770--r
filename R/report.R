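#' End-to-end analysis of a patient cohort
#'
#' Runs the full validation pipeline: inclusion filtering, marker scoring,
#' descriptive tables (demographics, marker frequencies among RA, clinical
#' presentations, comorbidities), co-positivity summaries, the ROC
#' analysis of the prediction score with AUC confidence interval, the
#' operating characteristics at a fixed criterion, the Youden-optimal
#' criterion, and the score-by-diagnosis cross-tabulation.
#'
#' @param cohort an `ra_cohort` (pre-inclusion; the filter is applied here).
#' @param criterion fixed operating criterion, default 2.5.
#' @param ci_method `"hanley_mcneil"` or `"delong"`.
#' @param confidence confidence level for the AUC interval.
#' @return List of class `ra_report`.
#' @export
analyze_cohort <- function(cohort, criterion = 2.5,
                           ci_method = c("hanley_mcneil", "delong"),
                           confidence = 0.95) {
  ci_method <- match.arg(ci_method)
  inc <- apply_inclusion(cohort)
  retained <- inc$cohort
  scored <- score_cohort(retained)
  ra_scored <- scored[scored$diagnosis == "RA", , drop = FALSE]
  ra_set <- retained[retained$diagnosis == "RA", , drop = FALSE]

  prev <- prevalence(retained)
  demog <- do.call(rbind, lapply(names(ra_categorical_levels), function(v)
    frequency_table(retained, v, by_diagnosis = TRUE)))
  marker_freq <- data.frame(
    marker = ra_markers,
    count = vapply(ra_markers, function(m)
      sum(ra_scored[[m]]), integer(1)),
    stringsAsFactors = FALSE)
  marker_freq$pct <- round_half_up(100 * marker_freq$count /
                                     max(1L, nrow(ra_scored)), 1)

  curve <- roc_curve(scored)
  auc <- auc_trapezoid(curve)
  est <- auc_ci(auc, attr(curve, "n_pos"), attr(curve, "n_neg"),
                confidence = confidence, method = ci_method,
                scored = scored)
  conf <- confusion_at(scored, criterion)
  ss <- sensitivity_specificity(conf)

  structure(list(
    exclusion = inc$report,
    n_analyzed = nrow(retained),
    prevalence = prev,
    age = list(all = group_moments(retained, "age"),
               RA = group_moments(retained, "age", "RA"),
               NRA = group_moments(retained, "age", "NRA")),
    demographics = demog,
    marker_frequencies = marker_freq,
    presentations = frequency_table(retained, "presentations",
                                    by_diagnosis = TRUE),
    comorbidities = frequency_table(retained, "comorbidities",
                                    by_diagnosis = TRUE),
    copositivity = list(
      markers_ge2 = copositivity(ra_scored, ra_markers, 2),
      presentations_ge2 = copositivity(ra_set$presentations,
                                       ra_presentations, 2)),
    roc = as.data.frame(curve),
    auc = est,
    criterion_analysis = list(criterion = criterion,
                              confusion = as.list(conf),
                              sensitivity = unname(ss["sensitivity"]),
                              specificity = unname(ss["specificity"])),
    youden = youden_optimal(curve),
    crosstab = score_crosstab(scored)),
    class = "ra_report")
}

#' @export
print.ra_report <- function(x, ...) {
  cat("== Cohort analysis of the additive RA marker score ==\n\n")
  print(x$exclusion)
  cat(sprintf("\nPrevalence of RA: %d / %d = %.2f%%\n",
              x$prevalence$n_ra, x$prevalence$n_total, x$prevalence$percent))
  cat(sprintf("Age (years), all: %.2f +/- %.2f; RA: %.2f +/- %.2f; NRA: %.2f +/- %.2f\n",
              x$age$all["mean"], x$age$all["sd"], x$age$RA["mean"],
              x$age$RA["sd"], x$age$NRA["mean"], x$age$NRA["sd"]))
  cat("\nDisease-marker frequencies among RA patients:\n")
  for (i in seq_len(nrow(x$marker_frequencies))) {
    cat(sprintf("  %-18s %3d (%.1f%%)\n", x$marker_frequencies$marker[i],
                x$marker_frequencies$count[i], x$marker_frequencies$pct[i]))
  }
  cat(sprintf("\nRA patients with >= 2 markers: %.1f%%\n",
              round_half_up(x$copositivity$markers_ge2, 1)))
  cat(sprintf("RA patients with >= 2 presentations: %.1f%%\n",
              round_half_up(x$copositivity$presentations_ge2, 1)))
  cat("\n"); print(x$auc)
  cat(sprintf("At criterion %.1f: sensitivity %.1f%%, specificity %.1f%%\n",
              x$criterion_analysis$criterion,
              round_half_up(100 * x$criterion_analysis$sensitivity, 1),
              round_half_up(100 * x$criterion_analysis$specificity, 1)))
  cat(sprintf("Youden-optimal criterion %.1f (J = %.3f)\n",
              x$youden$criterion, x$youden$J))
  cat("\nScore-by-diagnosis cross-tabulation:\n")
  print(as.data.frame(x$crosstab), row.names = FALSE)
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes the machine-readable report (JSON, full precision) and, if
#' `text = TRUE`, a plain-text rendering next to it.
#'
#' @param report an `ra_report`.
#' @param path output path for the JSON report.
#' @param text also write `<path without .json>.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, text = TRUE) {
  payload <- report
  payload$exclusion <- unclass(payload$exclusion)
  payload$auc <- unclass(payload$auc)
  payload$crosstab <- as.data.frame(payload$crosstab)
  payload$roc <- as.data.frame(payload$roc)
  jsonlite::write_json(unclass(payload), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (text) {
    txt <- sub("\\.json$", "", path)
    txt <- paste0(txt, ".txt")
    con <- file(txt, open = "wt")
    sink(con); on.exit({ sink(); close(con) }, add = TRUE)
    print(report)
  }
  invisible(path)
}

#' Command-style entry points
#'
#' Thin wrappers used by the shipped `rascore` command-line script
#' (`system.file("cli", "rascore.R", package = "rascore")`):
#' `cli_simulate` writes a synthetic cohort, `cli_analyze` runs
#' [analyze_cohort()] on a cohort file and writes the report pair, and
#' `cli_calibrate` writes a calibration result.
#'
#' @param config_path optional JSON configuration ([write_config()]); the
#'   packaged defaults are used when `NULL`.
#' @param out output file path.
#' @param seed optional seed override.
#' @param n optional cohort-size override.
#' @return The output path, invisibly.
#' @export
cli_simulate <- function(out, config_path = NULL, seed = NULL, n = NULL) {
  cfg <- if (is.null(config_path)) default_config() else read_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(n)) cfg$n <- as.integer(n)
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, out)
  message(sprintf("wrote %d simulated records to %s (seed %d)",
                  nrow(cohort), out, cfg$seed))
  invisible(out)
}

#' @rdname cli_simulate
#' @param cohort_path cohort CSV file.
#' @param criterion,ci_method,confidence passed to [analyze_cohort()].
#' @export
cli_analyze <- function(cohort_path, out, criterion = 2.5,
                        ci_method = "hanley_mcneil", confidence = 0.95) {
  cohort <- read_cohort(cohort_path)
  report <- analyze_cohort(cohort, criterion = criterion,
                           ci_method = ci_method, confidence = confidence)
  write_report(report, out)
  invisible(out)
}

#' @rdname cli_simulate
#' @param targets named targets `c(sens, spec, auc)`.
#' @param p_ra six RA marker rates.
#' @export
cli_calibrate <- function(out,
                          targets = c(sens = 0.673, spec = 0.630, auc = 0.69),
                          p_ra = c(0.690, 0.517, 0.586, 0.379, 0.586, 0.310)) {
  cal <- calibrate_nra_rates(p_ra, targets = targets)
  jsonlite::write_json(unclass(cal), out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
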