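#' Controlled vocabularies and marker thresholds
#'
#' Fixed item sets and laboratory cutoffs used throughout the package. The
#' six disease markers are, in canonical order: painful joints, swollen
#' joints, elevated ESR, elevated CRP, positive rheumatoid factor, and
#' erosive arthritis. Laboratory positivity is defined as ESR > 28 mm/h,
#' CRP > 8 mg/L (both strict), and RF >= 20 IU/mL (inclusive).
#'
#' @name rascore-vocab
#' @keywords internal
NULL

# canonical marker order; used by the score, the generator and the reports
ra_markers <- c("painful_joints", "swollen_joints", "esr_high",
                "crp_high", "rf_positive", "erosive_arthritis")

# cohort columns whose absence makes a record "incomplete"
ra_marker_sources <- c("esr", "crp", "rf", "painful_joint_count",
                       "swollen_joint_count", "erosive_arthritis")

ra_thresholds <- c(esr = 28, crp = 8, rf = 20)

ra_presentations <- c("arthritis", "fatigue", "weight_loss",
                      "loss_of_appetite", "fever", "arthralgia",
                      "raynaud_syndrome", "myalgias", "xerophthalmia",
                      "xerostomia")

ra_comorbidities <- c("obesity", "gastritis", "hypertension", "diabetes",
                      "sexual_compromise", "allergy", "depression",
                      "hypothyroidism")

ra_categorical_levels <- list(
  gender         = c("male", "female"),
  nationality    = c("saudi", "non_saudi"),
  marital_status = c("single", "married", "divorced", "widowed"),
  residence      = c("urban", "rural"),
  occupation     = c("working", "non_working", "household_chores"),
  smoking        = c("smoker", "non_smoker")
)

ra_schema <- c("patient_id", "age", "gender", "nationality", "marital_status",
               "residence", "occupation", "smoking", "esr", "crp", "rf",
               "painful_joint_count", "swollen_joint_count",
               "erosive_arthritis", "presentations", "comorbidities",
               "diagnosis")

# round half away from zero, the tabulation convention used in the reports
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
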