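# builders for small hand-made cohorts and scored sets

make_record <- function(patient_id = "P001", age = 48, gender = "female",
                        nationality = "saudi", marital_status = "married",
                        residence = "urban", occupation = "working",
                        smoking = "non_smoker", esr = 10, crp = 2, rf = 5,
                        painful_joint_count = 0, swollen_joint_count = 0,
                        erosive_arthritis = 0, presentations = "",
                        comorbidities = "", diagnosis = "NRA") {
  data.frame(patient_id = patient_id, age = age, gender = gender,
             nationality = nationality, marital_status = marital_status,
             residence = residence, occupation = occupation,
             smoking = smoking, esr = esr, crp = crp, rf = rf,
             painful_joint_count = painful_joint_count,
             swollen_joint_count = swollen_joint_count,
             erosive_arthritis = erosive_arthritis,
             presentations = presentations, comorbidities = comorbidities,
             diagnosis = diagnosis, stringsAsFactors = FALSE)
}

make_cohort <- function(n_ra, n_nra, ...) {
  n <- n_ra + n_nra
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(patient_id = sprintf("P%04d", i),
                diagnosis = if (i <= n_ra) "RA" else "NRA", ...)
  }))
  new_cohort(recs)
}

# scored-record stand-in: ROC functions only need score + diagnosis
scored_set <- function(ra_scores, nra_scores) {
  data.frame(
    patient_id = sprintf("P%04d", seq_len(length(ra_scores) + length(nra_scores))),
    score = c(ra_scores, nra_scores),
    diagnosis = rep(c("RA", "NRA"), c(length(ra_scores), length(nra_scores))),
    stringsAsFactors = FALSE)
}

# brute-force pairwise AUC oracle, independent of the package's rank path
auc_pairwise <- function(ra_scores, nra_scores) {
  wins <- outer(ra_scores, nra_scores, function(x, y) (x > y) + 0.5 * (x == y))
  mean(wins)
}

# brute-force oracle: enumerate all 2^m indicator outcomes
pb_tail_enum <- function(p, k) {
  m <- length(p)
  total <- 0
  for (code in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(code)[1:m])
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
    }
  }
  total
}
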