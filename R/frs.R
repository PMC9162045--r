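#' Load a Framingham risk-function constants file
#'
#' The office-based (non-laboratory) general-CVD coefficients ship with the
#' package as versioned JSON so alternate coefficient sets can be swapped in
#' without touching code. The schema has one block per sex with named
#' log-scale coefficients, the 10-year baseline survival, and the cohort
#' mean linear predictor.
#'
#' @param path optional path to an alternate constants JSON file.
#' @return a named list with elements `female` and `male`.
#' @export
frs_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "frs_office_constants.json",
                        package = "cvdtraj", mustWork = TRUE)
  }
  cn <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("log_age", "log_bmi", "log_sbp_untreated", "log_sbp_treated",
              "smoker", "diabetes", "baseline_survival", "mean_lp")
  for (sx in c("female", "male")) {
    if (!all(needed %in% names(cn[[sx]]))) {
      stop("constants file missing fields for ", sx, ": ",
           paste(setdiff(needed, names(cn[[sx]])), collapse = ", "))
    }
  }
  cn
}

#' Office-based Framingham 10-year general CVD risk
#'
#' Computes `1 - S0 ^ exp(LP - mean_lp)` with the sex-specific linear
#' predictor over log(age), log(BMI), log(SBP) (coefficient chosen by
#' current antihypertensive treatment status), smoking, and diabetes.
#' Vectorized over profiles. The function was derived for ages 30-74;
#' out-of-range ages are evaluated as-is with a warning rather than capped.
#'
#' @param age years, positive.
#' @param sex `"male"`/`"female"` (or a factor/character vector).
#' @param sbp systolic blood pressure, mmHg.
#' @param bp_medication logical/0-1, current antihypertensive treatment.
#' @param bmi body mass index, kg/m^2.
#' @param smoker,diabetes logical/0-1 indicators.
#' @param constants constants list from [frs_constants()].
#' @return numeric vector of 10-year risks, strictly inside (0, 1).
#' @examples
#' frs_risk(55, "male", 125, FALSE, 25, FALSE, FALSE)
#' @export
frs_risk <- function(age, sex, sbp, bp_medication, bmi, smoker, diabetes,
                     constants = frs_constants()) {
  n <- max(length(age), length(sex), length(sbp), length(bp_medication),
           length(bmi), length(smoker), length(diabetes))
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  sbp <- rep_len(as.numeric(sbp), n)
  trt <- rep_len(as.logical(bp_medication), n)
  bmi <- rep_len(as.numeric(bmi), n)
  smoker <- rep_len(as.logical(smoker), n)
  diabetes <- rep_len(as.logical(diabetes), n)

  if (any(!sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  bad <- !is.na(age) & !is.na(sbp) & !is.na(bmi) &
    (age <= 0 | sbp <= 0 | bmi <= 0)
  if (any(bad)) stop("age, sbp, and bmi must all be positive")
  out_of_range <- !is.na(age) & (age < 30 | age > 74)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " age value(s) outside the 30-74 derivation range of the risk",
            " function; evaluated without capping")
  }

  risk <- rep(NA_real_, n)
  for (sx in c("female", "male")) {
    idx <- which(sex == sx)
    if (!length(idx)) next
    cf <- constants[[sx]]
    b_sbp <- ifelse(trt[idx], cf$log_sbp_treated, cf$log_sbp_untreated)
    lp <- cf$log_age * log(age[idx]) + cf$log_bmi * log(bmi[idx]) +
      b_sbp * log(sbp[idx]) + cf$smoker * smoker[idx] +
      cf$diabetes * diabetes[idx]
    risk[idx] <- 1 - cf$baseline_survival^exp(lp - cf$mean_lp)
  }
  risk
}

#' Per-wave FRS series for every subject in a cohort
#'
#' Computes the 10-year risk at each observed wave, excluding waves with any
#' missing risk-factor covariate (run after imputation for complete series)
#' and, for subjects ever diagnosed with dementia, excluding every wave at
#' or after the diagnosis wave: only pre-diagnosis risk enters trajectory
#' estimation.
#'
#' @param cohort long-format cohort data frame (one row per subject-wave)
#'   with the columns written by [generate_cohort()].
#' @param constants constants list from [frs_constants()].
#' @return data frame `subject_id`, `wave`, `years` (since the subject's
#'   first wave), `frs` — one row per usable pre-diagnosis wave. Subjects
#'   with zero usable waves are absent (handled downstream as
#'   unclassified).
#' @export
build_frs_series <- function(cohort, constants = frs_constants()) {
  stopifnot(is.data.frame(cohort))
  cc <- stats::complete.cases(cohort[, c("age", "sex", "sbp_mmHg",
                                         "bp_medication", "bmi_kg_m2",
                                         "smoker", "diabetes")])
  # first dementia wave per subject; risks from there on are not used
  dem <- cohort$state %in% c("AD", "VaD")
  censor <- tapply(ifelse(dem, cohort$wave, Inf), cohort$subject_id, min)
  cw <- censor[as.character(cohort$subject_id)]
  keep <- cc & cohort$wave < cw
  ser <- cohort[keep, c("subject_id", "wave", "age", "sex", "sbp_mmHg",
                        "bp_medication", "bmi_kg_m2", "smoker", "diabetes")]
  first_age <- tapply(ser$age, ser$subject_id, min)
  ser$years <- ser$age - first_age[as.character(ser$subject_id)]
  ser$frs <- frs_risk(ser$age, ser$sex, ser$sbp_mmHg, ser$bp_medication,
                      ser$bmi_kg_m2, ser$smoker, ser$diabetes,
                      constants = constants)
  out <- ser[, c("subject_id", "wave", "years", "frs")]
  rownames(out) <- NULL
  out
}

#' Cross-sectional FRS risk categories
#'
#' Bins one risk value per subject into low / medium / high using the
#' clinical cutpoints, with the boundaries assigned to the middle class:
#' low is risk < 0.06, medium is 0.06 <= risk <= 0.20, high is risk > 0.20.
#'
#' @param risk numeric vector of risks at a reference wave.
#' @param cutpoints length-2 numeric, defaults `c(0.06, 0.20)`.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
frs_cutoff_group <- function(risk, cutpoints = c(0.06, 0.20)) {
  stopifnot(length(cutpoints) == 2, cutpoints[1] < cutpoints[2])
  out <- ifelse(risk < cutpoints[1], "low",
                ifelse(risk > cutpoints[2], "high", "medium"))
  factor(out, levels = c("low", "medium", "high"))
}
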