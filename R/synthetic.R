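#' Poisson-binomial score distribution
#'
#' Distribution of the sum of independent, non-identically distributed 0/1
#' indicators — the prediction score under conditional independence of the
#' markers within a diagnosis class. `dpoisbinom` returns the full
#' probability mass function by the standard convolution dynamic program;
#' `poisson_binomial_tail` returns the exact upper tail `P(S >= k)`.
#'
#' @param p vector of per-indicator success probabilities in `[0, 1]`.
#' @return `dpoisbinom`: numeric vector of length `length(p) + 1`, the
#'   probabilities of sums `0..length(p)`.
#' @export
dpoisbinom <- function(p) {
  if (any(p < 0 | p > 1)) stop("rates must lie in [0, 1]")
  f <- 1
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  f
}

#' @rdname dpoisbinom
#' @param k integer threshold.
#' @return `poisson_binomial_tail`: the probability `P(S >= k)`.
#' @export
poisson_binomial_tail <- function(p, k) {
  if (k <= 0) return(1)
  if (k > length(p)) return(0)
  d <- dpoisbinom(p)
  sum(d[(k + 1):length(d)])
}

#' Model-implied operating characteristics of the score
#'
#' Under conditional independence, the score of each diagnosis class is
#' Poisson-binomial with the class's marker rates, so the exact
#' sensitivity and specificity at every midpoint criterion — and the AUC of
#' the implied ROC polygon — are available in closed form. Used to
#' calibrate the unreported NRA marker rates.
#'
#' @param p_ra,p_nra six class-conditional marker rates.
#' @return List with `points` (data frame `criterion`, `sensitivity`,
#'   `specificity` over criteria -1, 0.5, ..., 5.5, 7) and `auc`.
#' @export
model_roc <- function(p_ra, p_nra) {
  stopifnot(length(p_ra) == 6, length(p_nra) == 6)
  ks <- 0:7
  crit <- c(-1, seq(0.5, 5.5, by = 1), 7)
  sens <- vapply(ks, function(k) poisson_binomial_tail(p_ra, k), numeric(1))
  spec <- vapply(ks, function(k) 1 - poisson_binomial_tail(p_nra, k), numeric(1))
  x <- 1 - spec; y <- sens
  o <- order(x, y)
  auc <- sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
  list(points = data.frame(criterion = crit, sensitivity = sens,
                           specificity = spec),
       auc = auc)
}

#' Calibrate the NRA marker rates against published operating targets
#'
#' The marker positivity rates of the non-RA clinic population are not
#' published, so they are obtained by deterministic calibration: under the
#' scalar-logit-shift parametrization every NRA rate is
#' `plogis(qlogis(p_ra) - delta)` and the single shift `delta` is chosen by
#' one-dimensional minimization of the summed squared error between the
#' model-implied (sensitivity at the criterion, specificity at the
#' criterion, AUC) and the targets. The `per_marker` parametrization
#' refines the scalar solution with six independent shifts (a deterministic
#' quasi-Newton polish from that starting point).
#'
#' @param p_ra six RA marker rates.
#' @param targets named vector `c(sens, spec, auc)` in (0, 1).
#' @param parametrization `"scalar_logit_shift"` (default) or
#'   `"per_marker"`.
#' @param criterion operating criterion at which sensitivity/specificity
#'   targets apply, default 2.5.
#' @param feasible_tol maximum admissible objective (sum of squared target
#'   errors); above it the targets are declared infeasible and the error
#'   reports the objective profile over the shift.
#' @return List of class `calibration_result` with `p_nra`, `delta`,
#'   `achieved`, `target`, `objective`, `parametrization`.
#' @export
calibrate_nra_rates <- function(p_ra,
                                targets = c(sens = 0.673, spec = 0.630,
                                            auc = 0.69),
                                parametrization = c("scalar_logit_shift",
                                                    "per_marker"),
                                criterion = 2.5, feasible_tol = 0.02) {
  parametrization <- match.arg(parametrization)
  if (any(targets <= 0 | targets >= 1)) stop("targets must lie in (0, 1)")
  k_at <- ceiling(criterion)
  implied <- function(q) {
    m <- model_roc(p_ra, q)
    c(sens = poisson_binomial_tail(p_ra, k_at),
      spec = 1 - poisson_binomial_tail(q, k_at),
      auc = m$auc)
  }
  obj_delta <- function(delta) {
    q <- stats::plogis(stats::qlogis(p_ra) - delta)
    sum((implied(q) - targets)^2)
  }
  opt <- stats::optimize(obj_delta, interval = c(-8, 8), tol = 1e-9)
  delta <- opt$minimum
  q <- stats::plogis(stats::qlogis(p_ra) - delta)
  objective <- opt$objective
  if (parametrization == "per_marker") {
    obj_vec <- function(dd) {
      qq <- stats::plogis(stats::qlogis(p_ra) - dd)
      sum((implied(qq) - targets)^2)
    }
    fit <- stats::optim(rep(delta, 6), obj_vec, method = "BFGS",
                        control = list(reltol = 1e-12))
    q <- stats::plogis(stats::qlogis(p_ra) - fit$par)
    objective <- fit$value
  }
  if (objective > feasible_tol) {
    grid <- seq(-6, 6, by = 0.5)
    profile <- vapply(grid, obj_delta, numeric(1))
    stop("calibration targets are infeasible under this marker model ",
         sprintf("(best objective %.4f > %.4f); ", objective, feasible_tol),
         "objective profile over delta: ",
         paste(sprintf("%.1f:%.3f", grid, profile), collapse = " "))
  }
  structure(list(p_nra = unname(q), delta = delta,
                 achieved = implied(q), target = targets,
                 objective = objective, parametrization = parametrization),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("NRA marker-rate calibration (", x$parametrization, ")\n", sep = "")
  cat(sprintf("  delta = %.4f, objective = %.3g\n", x$delta, x$objective))
  cat(sprintf("  achieved sens/spec/auc: %.3f / %.3f / %.3f\n",
              x$achieved["sens"], x$achieved["spec"], x$achieved["auc"]))
  cat("  p_nra:", paste(sprintf("%.3f", x$p_nra), collapse = " "), "\n")
  invisible(x)
}

# calibration is deterministic; cache it for the default configuration
.rascore_cache <- new.env(parent = emptyenv())

#' Default simulation configuration
#'
#' The packaged study conditions: cohort size 401, RA prevalence 14.46%,
#' RA marker rates (painful 0.690, swollen 0.517, ESR 0.586, CRP 0.379,
#' RF 0.586, erosive 0.310), age 49.97 +/- 18.34 years for RA and
#' 48.55 +/- 15.39 for NRA (truncated above 16), per-group demographic
#' rates, RA presentation and comorbidity rates, and NRA marker rates from
#' the packaged calibration (scalar logit shift against sensitivity 67.3%,
#' specificity 63.0%, AUC 0.69 at criterion 2.5). Markers are conditionally
#' independent by default (`rho = 0`); `rho` is a sensitivity-analysis
#' knob, not an estimate.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param rho exchangeable latent (tetrachoric-style) correlation within
#'   the marker block, in `[0, 1)`.
#' @return List of class `ra_simconfig`.
#' @export
default_config <- function(n = 401, seed = 1, rho = 0) {
  if (is.null(.rascore_cache$calibration)) {
    .rascore_cache$calibration <- calibrate_nra_rates(
      p_ra = c(0.690, 0.517, 0.586, 0.379, 0.586, 0.310))
  }
  cal <- .rascore_cache$calibration
  cfg <- list(
    n = n,
    prevalence = 0.1446,
    p_ra = c(0.690, 0.517, 0.586, 0.379, 0.586, 0.310),
    p_nra = cal$p_nra,
    rho = rho,
    age_ra = c(mean = 49.97, sd = 18.34),
    age_nra = c(mean = 48.55, sd = 15.39),
    age_min = 16,
    demographic_rates = list(
      gender = list(RA = c(male = 0.397, female = 0.603),
                    NRA = c(male = 0.236, female = 0.764)),
      nationality = list(RA = c(saudi = 0.897, non_saudi = 0.103),
                         NRA = c(saudi = 0.892, non_saudi = 0.108)),
      marital_status = list(
        RA = c(single = 0.190, married = 0.534, divorced = 0.103,
               widowed = 0.172),
        NRA = c(single = 0.192, married = 0.601, divorced = 0.093,
                widowed = 0.114)),
      residence = list(RA = c(urban = 0.862, rural = 0.138),
                       NRA = c(urban = 0.889, rural = 0.111)),
      occupation = list(
        RA = c(working = 0.293, non_working = 0.483,
               household_chores = 0.224),
        NRA = c(working = 0.391, non_working = 0.373,
                household_chores = 0.237)),
      smoking = list(RA = c(smoker = 0.224, non_smoker = 0.776),
                     NRA = c(smoker = 0.155, non_smoker = 0.845))),
    presentation_rates = list(
      RA = c(arthritis = 0.517, fatigue = 0.466, weight_loss = 0.448,
             loss_of_appetite = 0.414, fever = 0.345, arthralgia = 0.190,
             raynaud_syndrome = 0.172, myalgias = 0.155,
             xerophthalmia = 0.086, xerostomia = 0.017),
      # unreported for the non-RA clinic population; set to half the RA
      # rates (other orthopedic complaints share these symptoms at lower
      # frequency)
      NRA = c(arthritis = 0.2585, fatigue = 0.233, weight_loss = 0.224,
              loss_of_appetite = 0.207, fever = 0.1725, arthralgia = 0.095,
              raynaud_syndrome = 0.086, myalgias = 0.0775,
              xerophthalmia = 0.043, xerostomia = 0.0085)),
    comorbidity_rates = list(
      RA = c(obesity = 0.172, gastritis = 0.500, hypertension = 0.448,
             diabetes = 0.552, sexual_compromise = 0.017, allergy = 0.345,
             depression = 0.172, hypothyroidism = 0.155),
      # unreported for non-RA; chronic conditions of a middle-aged clinic
      # population assumed at 70% of the RA rates
      NRA = c(obesity = 0.1204, gastritis = 0.350, hypertension = 0.3136,
              diabetes = 0.3864, sexual_compromise = 0.0119,
              allergy = 0.2415, depression = 0.1204,
              hypothyroidism = 0.1085)),
    # raw-lab emission, conditional on the indicator state: truncated
    # normals on either side of each clinical threshold, so dichotomizing
    # the emitted value always reproduces the indicator
    lab_emission = list(
      esr = list(threshold = 28, pos = c(mean = 48, sd = 18),
                 neg = c(mean = 16, sd = 8)),
      crp = list(threshold = 8, pos = c(mean = 22, sd = 12),
                 neg = c(mean = 3.5, sd = 2.5)),
      rf = list(threshold = 20, pos = c(mean = 65, sd = 35),
                neg = c(mean = 8, sd = 6))),
    joint_count_lambda = 2,
    seed = as.integer(seed))
  class(cfg) <- "ra_simconfig"
  cfg
}

validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  needed <- c("n", "prevalence", "p_ra", "p_nra", "rho", "age_ra", "age_nra",
              "age_min", "demographic_rates", "presentation_rates",
              "comorbidity_rates", "lab_emission", "joint_count_lambda",
              "seed")
  missing_fields <- setdiff(needed, names(config))
  if (length(missing_fields) > 0L) {
    stop("config is missing field(s): ", paste(missing_fields, collapse = ", "))
  }
  if (config$n < 1) stop("config: n must be positive")
  if (config$prevalence <= 0 || config$prevalence >= 1) {
    stop("config: prevalence must be in (0, 1)")
  }
  for (f in c("p_ra", "p_nra")) {
    if (length(config[[f]]) != 6 || any(config[[f]] < 0 | config[[f]] > 1)) {
      stop("config: ", f, " must be six rates in [0, 1]")
    }
  }
  if (config$rho < 0 || config$rho >= 1) stop("config: rho must be in [0, 1)")
  for (f in c("age_ra", "age_nra")) {
    if (config[[f]][["sd"]] <= 0) stop("config: ", f, " sd must be positive")
  }
  rates <- unlist(c(config$presentation_rates, config$comorbidity_rates,
                    config$demographic_rates))
  if (any(rates < 0 | rates > 1)) stop("config: all rates must be in [0, 1]")
  invisible(config)
}

#' Read / write a simulation configuration as JSON
#'
#' @param path file path.
#' @return `read_config` returns an `ra_simconfig`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n <- as.integer(cfg$n)
  for (f in c("age_ra", "age_nra")) cfg[[f]] <- unlist(cfg[[f]])
  for (grp in c("presentation_rates", "comorbidity_rates")) {
    cfg[[grp]] <- lapply(cfg[[grp]], unlist)
  }
  cfg$demographic_rates <- lapply(cfg$demographic_rates, lapply, unlist)
  cfg$lab_emission <- lapply(cfg$lab_emission, function(l) {
    l$pos <- unlist(l$pos); l$neg <- unlist(l$neg); l
  })
  class(cfg) <- "ra_simconfig"
  validate_config(cfg)
}

#' @rdname read_config
#' @param config an `ra_simconfig`.
#' @export
write_config <- function(config, path) {
  # named numeric vectors must become JSON objects, not bare arrays
  cfg <- unclass(config)
  cfg$age_ra <- as.list(cfg$age_ra)
  cfg$age_nra <- as.list(cfg$age_nra)
  cfg$demographic_rates <- lapply(cfg$demographic_rates, lapply, as.list)
  cfg$presentation_rates <- lapply(cfg$presentation_rates, as.list)
  cfg$comorbidity_rates <- lapply(cfg$comorbidity_rates, as.list)
  cfg$lab_emission <- lapply(cfg$lab_emission, function(l) {
    l$pos <- as.list(l$pos); l$neg <- as.list(l$neg); l
  })
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# inverse-CDF truncated normal draw on (lower, upper)
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

sample_levels <- function(n, rates) {
  p <- rates / sum(rates)
  names(rates)[sample.int(length(rates), n, replace = TRUE, prob = p)]
}

sample_itemsets <- function(n, rates) {
  if (n == 0L) return(character(0))
  draws <- matrix(stats::runif(n * length(rates)), nrow = n) <
    matrix(rates, nrow = n, ncol = length(rates), byrow = TRUE)
  vapply(seq_len(n), function(i)
    paste(names(rates)[draws[i, ]], collapse = ";"), character(1))
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` records under the class-conditional marker model: the
#' diagnosis is Bernoulli with the configured prevalence; given the class,
#' the six marker indicators are drawn from the class rate vector
#' (independently when `rho = 0`, otherwise through an exchangeable
#' latent-Gaussian threshold model); raw ESR/CRP/RF values are emitted from
#' truncated normals on the side of the clinical threshold dictated by the
#' indicator, joint counts are positive exactly when the corresponding
#' indicator is 1, ages come from the group's truncated normal (support
#' above the inclusion age), and demographics, presentations and
#' comorbidities are sampled from their per-group rate tables. Fully
#' reproducible from `config$seed`.
#'
#' @param config an `ra_simconfig`, e.g. [default_config()].
#' @return An `ra_cohort` with provenance `"simulated"`.
#' @export
generate_cohort <- function(config = default_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n
  is_ra <- stats::runif(n) < config$prevalence
  grp <- ifelse(is_ra, "RA", "NRA")

  # marker indicators via latent-Gaussian thresholding (exact Bernoulli
  # marginals; exchangeable correlation rho between latents)
  rho <- config$rho
  z_shared <- stats::rnorm(n)
  lat <- sqrt(rho) * z_shared +
    sqrt(1 - rho) * matrix(stats::rnorm(n * 6), nrow = n)
  pmat <- matrix(config$p_nra, nrow = n, ncol = 6, byrow = TRUE)
  if (any(is_ra)) {
    pmat[is_ra, ] <- matrix(config$p_ra, nrow = sum(is_ra), ncol = 6,
                            byrow = TRUE)
  }
  ind <- (stats::pnorm(lat) < pmat) * 1L
  colnames(ind) <- ra_markers

  # emitted values are rounded to one decimal downstream, so keep a 0.1
  # margin on the open side of each threshold: strict markers (>) emit
  # positives from threshold + margin, the inclusive RF marker (>=) emits
  # negatives up to threshold - margin; dichotomization then reproduces
  # the indicators exactly
  emit_lab <- function(which_lab, positive, strict) {
    em <- config$lab_emission[[which_lab]]
    margin <- 0.1
    v <- numeric(n)
    npos <- sum(positive)
    if (npos > 0) {
      v[positive] <- rtnorm(npos, em$pos[["mean"]], em$pos[["sd"]],
                            lower = em$threshold + if (strict) margin else 0)
    }
    if (npos < n) {
      v[!positive] <- rtnorm(n - npos, em$neg[["mean"]], em$neg[["sd"]],
                             lower = 0,
                             upper = em$threshold - if (strict) 0 else margin)
    }
    v
  }
  esr <- emit_lab("esr", ind[, "esr_high"] == 1L, strict = TRUE)
  crp <- emit_lab("crp", ind[, "crp_high"] == 1L, strict = TRUE)
  rf_raw <- emit_lab("rf", ind[, "rf_positive"] == 1L, strict = FALSE)

  count_for <- function(indicator) {
    k <- integer(n)
    on <- indicator == 1L
    k[on] <- 1L + stats::rpois(sum(on), config$joint_count_lambda)
    k
  }
  painful <- count_for(ind[, "painful_joints"])
  swollen <- count_for(ind[, "swollen_joints"])

  # ages are rounded to one decimal; truncating 0.1 above the inclusion
  # bound keeps every rounded age strictly eligible
  age <- numeric(n)
  age[is_ra] <- rtnorm(sum(is_ra), config$age_ra[["mean"]],
                       config$age_ra[["sd"]], lower = config$age_min + 0.1)
  age[!is_ra] <- rtnorm(sum(!is_ra), config$age_nra[["mean"]],
                        config$age_nra[["sd"]], lower = config$age_min + 0.1)

  demo <- function(var) {
    out <- character(n)
    for (g in c("RA", "NRA")) {
      sel <- grp == g
      out[sel] <- sample_levels(sum(sel), config$demographic_rates[[var]][[g]])
    }
    out
  }
  sets <- function(table) {
    out <- character(n)
    for (g in c("RA", "NRA")) {
      sel <- grp == g
      out[sel] <- sample_itemsets(sum(sel), table[[g]])
    }
    out
  }

  rec <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    age = round(age, 1),
    gender = demo("gender"),
    nationality = demo("nationality"),
    marital_status = demo("marital_status"),
    residence = demo("residence"),
    occupation = demo("occupation"),
    smoking = demo("smoking"),
    esr = round(esr, 1),
    crp = round(crp, 1),
    rf = round(rf_raw, 1),
    painful_joint_count = painful,
    swollen_joint_count = swollen,
    erosive_arthritis = as.integer(ind[, "erosive_arthritis"]),
    presentations = sets(config$presentation_rates),
    comorbidities = sets(config$comorbidity_rates),
    diagnosis = grp,
    stringsAsFactors = FALSE)
  new_cohort(rec, provenance = "simulated", seed = config$seed)
}
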