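#' Construct a patient cohort
#'
#' A cohort is a data frame with one row per clinic visitor and a fixed
#' column schema: identifier, demographics, raw laboratory values
#' (ESR mm/h, CRP mg/L, RF IU/mL), joint counts, the erosive-arthritis flag,
#' the sets of clinical presentations and comorbidities, and the clinician's
#' reference-standard diagnosis (`"RA"` or `"NRA"`).
#'
#' Missing values are `NA`; set-valued cells (`presentations`,
#' `comorbidities`) hold semicolon-delimited item names drawn from the fixed
#' vocabularies, with the empty string meaning "none recorded". Categorical
#' values are stored lowercase with underscores.
#'
#' @param records data frame with the columns listed in [cohort_schema()].
#' @param provenance `"observed"` or `"simulated"`.
#' @param seed integer seed for simulated cohorts, or `NULL`.
#' @return An object of class `ra_cohort` (a data frame).
#' @export
new_cohort <- function(records, provenance = c("observed", "simulated"),
                       seed = NULL) {
  provenance <- match.arg(provenance)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ra_schema, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[, ra_schema, drop = FALSE]
  validate_cohort(records)
  structure(records, class = c("ra_cohort", "data.frame"),
            provenance = provenance, seed = seed)
}

#' @rdname new_cohort
#' @export
cohort_schema <- function() ra_schema

validate_cohort <- function(records) {
  if (anyDuplicated(records$patient_id)) {
    stop("patient_id values must be unique within a cohort")
  }
  ok_age <- is.na(records$age) | records$age >= 0
  if (!all(ok_age)) stop("age must be nonnegative")
  for (lab in c("esr", "crp", "rf")) {
    v <- records[[lab]]
    if (!all(is.na(v) | v >= 0)) stop(lab, " must be nonnegative when present")
  }
  for (cnt in c("painful_joint_count", "swollen_joint_count")) {
    v <- records[[cnt]]
    if (!all(is.na(v) | (v >= 0 & v == floor(v)))) {
      stop(cnt, " must be a nonnegative integer when present")
    }
  }
  v <- records$erosive_arthritis
  if (!all(is.na(v) | v %in% c(0, 1))) {
    stop("erosive_arthritis must be 0 or 1 when present")
  }
  d <- records$diagnosis
  if (!all(is.na(d) | d %in% c("RA", "NRA"))) {
    stop("diagnosis must be RA or NRA when present")
  }
  check_set <- function(col, vocab) {
    items <- unlist(split_items(records[[col]]))
    bad <- setdiff(items, vocab)
    if (length(bad) > 0L) {
      stop("unknown ", col, " item(s): ", paste(unique(bad), collapse = ", "))
    }
  }
  check_set("presentations", ra_presentations)
  check_set("comorbidities", ra_comorbidities)
  invisible(records)
}

# semicolon-delimited cell -> character vector of items ("" and NA -> none)
split_items <- function(x) {
  lapply(as.character(x), function(cell) {
    if (is.na(cell) || !nzchar(cell)) character(0)
    else trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
  })
}

normalize_categorical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[ -]+", "_", x)
  x[!nzchar(x)] <- NA_character_
  x
}

parse_numeric_column <- function(x, col, strict) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad) > 0L) {
    if (strict) {
      stop(sprintf("unparseable value '%s' in column '%s', row %d",
                   x[bad[1]], col, bad[1]), call. = FALSE)
    }
    warning(sprintf("column '%s': %d unparseable cell(s) set to NA (first at row %d)",
                    col, length(bad), bad[1]), call. = FALSE)
  }
  out
}

#' Read a patient cohort from delimited text
#'
#' Reads a comma-separated, UTF-8 file whose header must match the cohort
#' schema exactly. Empty cells become `NA` (or the empty item set for the
#' set-valued columns); categorical values are case-normalized to lowercase
#' with underscores.
#'
#' @param path path to a CSV file.
#' @param strict if `TRUE` (default) an unparseable numeric cell is an error
#'   naming the row and column; if `FALSE` it becomes `NA` with a warning.
#' @return An [new_cohort()] object with provenance `"observed"`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character(0),
                         fileEncoding = "UTF-8")
  unknown <- setdiff(names(raw), ra_schema)
  if (length(unknown) > 0L) {
    stop("unknown column(s) in cohort file: ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(ra_schema, names(raw))
  if (length(missing_cols) > 0L) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rec <- data.frame(patient_id = trimws(raw$patient_id),
                    stringsAsFactors = FALSE)
  rec$age <- parse_numeric_column(raw$age, "age", strict)
  for (col in names(ra_categorical_levels)) {
    rec[[col]] <- normalize_categorical(raw[[col]])
  }
  for (col in c("esr", "crp", "rf")) {
    rec[[col]] <- parse_numeric_column(raw[[col]], col, strict)
  }
  for (col in c("painful_joint_count", "swollen_joint_count",
                "erosive_arthritis")) {
    rec[[col]] <- parse_numeric_column(raw[[col]], col, strict)
  }
  clean_set <- function(x) {
    items <- split_items(x)
    vapply(items, function(it) paste(normalize_categorical(it), collapse = ";"),
           character(1))
  }
  rec$presentations <- clean_set(raw$presentations)
  rec$comorbidities <- clean_set(raw$comorbidities)
  diag <- toupper(trimws(raw$diagnosis))
  diag[!nzchar(diag)] <- NA_character_
  rec$diagnosis <- diag
  new_cohort(rec, provenance = "observed")
}

#' Write a patient cohort to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(cohort, path))`
#' reproduces the cohort field for field, including missing values, which
#' are written as empty cells (never sentinel numbers).
#'
#' @param cohort an `ra_cohort`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, ra_schema, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Apply the study's inclusion and exclusion rules
#'
#' Retains records with age strictly above the minimum (default 16 years),
#' all six marker source fields present (`esr`, `crp`, `rf`,
#' `painful_joint_count`, `swollen_joint_count`, `erosive_arthritis`), and a
#' reference-standard diagnosis. The age rule is applied first so each
#' excluded record has exactly one recorded reason; a record with missing
#' age counts as incomplete, not as an age exclusion. Demographic gaps do
#' not exclude: only the fields that feed the validated computation do.
#'
#' @param cohort an `ra_cohort`.
#' @param age_min exclusive lower age bound in years; records with
#'   `age <= age_min` are excluded.
#' @return A list with elements `cohort` (the retained records) and
#'   `report`, an `exclusion_report` whose counts always satisfy
#'   `n_input = n_retained + n_excluded_age + n_excluded_incomplete`.
#' @export
apply_inclusion <- function(cohort, age_min = 16) {
  if (nrow(cohort) == 0L) stop("cannot apply inclusion rules to an empty cohort")
  age_known <- !is.na(cohort$age)
  excl_age <- age_known & cohort$age <= age_min
  complete <- !is.na(cohort$age) &
    Reduce(`&`, lapply(ra_marker_sources, function(f) !is.na(cohort[[f]]))) &
    !is.na(cohort$diagnosis)
  excl_incomplete <- !excl_age & !complete
  keep <- !excl_age & !excl_incomplete
  report <- structure(
    list(n_input = nrow(cohort),
         n_retained = sum(keep),
         n_excluded_age = sum(excl_age),
         n_excluded_incomplete = sum(excl_incomplete),
         excluded_ids = cohort$patient_id[!keep]),
    class = "exclusion_report")
  retained <- cohort[keep, , drop = FALSE]
  rownames(retained) <- NULL
  retained <- structure(retained, class = c("ra_cohort", "data.frame"),
                        provenance = attr(cohort, "provenance") %||% "observed",
                        seed = attr(cohort, "seed"))
  list(cohort = retained, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Inclusion filter:", x$n_input, "records in,",
      x$n_retained, "retained\n")
  cat("  excluded by age rule:   ", x$n_excluded_age, "\n")
  cat("  excluded as incomplete: ", x$n_excluded_incomplete, "\n")
  invisible(x)
}

#' @export
print.ra_cohort <- function(x, ...) {
  cat(sprintf("<ra_cohort: %d records, provenance %s%s>\n", nrow(x),
              attr(x, "provenance") %||% "observed",
              if (!is.null(attr(x, "seed")))
                paste0(", seed ", attr(x, "seed")) else ""))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}
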