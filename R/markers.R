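#' Dichotomize the six disease markers for one patient record
#'
#' Applies the clinical positivity thresholds: ESR positive when
#' strictly above 28 mm/h, CRP when strictly above 8 mg/L, rheumatoid
#' factor when at or above 20 IU/mL; painful and swollen joints are
#' "present" when the respective count is at least 1; the erosive-arthritis
#' flag is copied. Raw values are thresholded as recorded, without rounding.
#'
#' @param record a single patient record: one row of an `ra_cohort`, or a
#'   list/data frame with the marker source fields.
#' @return Named integer vector of six 0/1 indicators, in canonical marker
#'   order (`painful_joints`, `swollen_joints`, `esr_high`, `crp_high`,
#'   `rf_positive`, `erosive_arthritis`).
#' @export
dichotomize_markers <- function(record) {
  record <- as.list(record)
  for (f in ra_marker_sources) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("marker source field '", f, "' is missing; records must pass ",
           "apply_inclusion() first", call. = FALSE)
    }
  }
  c(painful_joints    = as.integer(record$painful_joint_count >= 1),
    swollen_joints    = as.integer(record$swollen_joint_count >= 1),
    esr_high          = as.integer(record$esr > ra_thresholds[["esr"]]),
    crp_high          = as.integer(record$crp > ra_thresholds[["crp"]]),
    rf_positive       = as.integer(record$rf >= ra_thresholds[["rf"]]),
    erosive_arthritis = as.integer(record$erosive_arthritis == 1))
}

#' Additive prediction score from a marker vector
#'
#' The score is the unweighted sum of the six 0/1 marker indicators, an
#' integer between 0 and 6.
#'
#' @param markers named 0/1 vector as returned by [dichotomize_markers()].
#' @return Integer score in `[0, 6]`.
#' @export
prediction_score <- function(markers) {
  if (length(markers) != length(ra_markers) || !all(markers %in% c(0, 1))) {
    stop("markers must be six 0/1 indicators")
  }
  as.integer(sum(markers))
}

#' Score every record of a cohort
#'
#' Dichotomizes the markers of each record and attaches the additive
#' prediction score, preserving record order. The cohort must already have
#' passed [apply_inclusion()]; an incomplete record raises an error citing
#' its `patient_id`.
#'
#' @param cohort an `ra_cohort` of complete records.
#' @return A data frame of class `ra_scored` with `patient_id`, the six
#'   indicator columns, `score`, and `diagnosis`.
#' @export
score_cohort <- function(cohort) {
  df <- as.data.frame(cohort)
  incomplete <- !stats::complete.cases(df[, ra_marker_sources, drop = FALSE])
  if (any(incomplete)) {
    stop("incomplete marker data for patient_id ",
         paste(df$patient_id[which(incomplete)[seq_len(min(3, sum(incomplete)))]],
               collapse = ", "),
         if (sum(incomplete) > 3L) ", ..." else "",
         "; run apply_inclusion() first", call. = FALSE)
  }
  out <- data.frame(
    patient_id        = df$patient_id,
    painful_joints    = as.integer(df$painful_joint_count >= 1),
    swollen_joints    = as.integer(df$swollen_joint_count >= 1),
    esr_high          = as.integer(df$esr > ra_thresholds[["esr"]]),
    crp_high          = as.integer(df$crp > ra_thresholds[["crp"]]),
    rf_positive       = as.integer(df$rf >= ra_thresholds[["rf"]]),
    erosive_arthritis = as.integer(df$erosive_arthritis == 1),
    stringsAsFactors  = FALSE)
  out$score <- as.integer(rowSums(out[, ra_markers]))
  out$diagnosis <- df$diagnosis
  class(out) <- c("ra_scored", "data.frame")
  out
}

#' Write scored records to delimited text
#'
#' @param scored an `ra_scored` data frame.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(scored, path) {
  utils::write.csv(as.data.frame(scored), path, row.names = FALSE, na = "",
                   quote = FALSE)
  invisible(path)
}

#' Read scored records from delimited text
#'
#' @param path file written by [write_scored()].
#' @return An `ra_scored` data frame.
#' @export
read_scored <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", ra_markers, "score", "diagnosis")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("scored file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, needed]
  class(df) <- c("ra_scored", "data.frame")
  df
}
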