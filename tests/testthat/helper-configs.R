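# Shared generator scenarios.
# flat_hazards(): no covariate, age, class, or APOE effect on any transition
# unless a class multiplier vector is supplied for the dementia transition.
flat_hazards <- function(dem_base = 0.03, death_base = 0.05,
                         dem_class_mult = c(accelerated = 1, average = 1,
                                            stable = 1),
                         dementia_death_base = 0.2) {
  flat <- function(base, cm = c(accelerated = 1, average = 1, stable = 1)) {
    list(base = base, age_breaks = numeric(0), age_mult = 1,
         class_mult = cm, apoe_mult = 1)
  }
  list(ad = flat(dem_base, dem_class_mult),
       vad = flat(0),
       death = flat(death_base),
       dementia_death = flat(dementia_death_base),
       dementia_min_age = 0)
}

no_dropout <- function() list(rates = rep(0, 6))
no_item_missing <- function() {
  list(rate = c(sbp_mmHg = 0, bmi_kg_m2 = 0, smoker = 0, diabetes = 0,
                bp_medication = 0))
}

# covariate-free old cohort for the BART-vs-nonparametric comparisons
covfree_config <- function(n, seed, dem_class_mult = c(accelerated = 1,
                                                       average = 1,
                                                       stable = 1)) {
  cohort_config(
    n_subjects = n, seed = seed,
    entry_age_range = c(70, 80), entry_age_weights = c(1, 1, 1),
    hazard_params = flat_hazards(dem_class_mult = dem_class_mult),
    dropout_hazard = no_dropout(),
    missingness_rate = no_item_missing())
}

# tight low-noise scenario where covariate slopes carry the class signal
# cleanly into risk units (narrow baseline heterogeneity, no measurement
# noise, no binary factor churn)
lownoise_config <- function(n, seed) {
  cohort_config(
    n_subjects = n, seed = seed,
    entry_age_range = c(55, 65), entry_age_weights = c(1, 1, 1),
    slope_params = list(
      sbp_noise_sd = 0, bmi_noise_sd = 0,
      sbp_sd = c(accelerated = 0.05, average = 0.05, stable = 0.05),
      bmi_sd = c(accelerated = 0.01, average = 0.01, stable = 0.01),
      diabetes_onset = c(accelerated = 0, average = 0, stable = 0),
      bp_med_start = c(accelerated = 0, average = 0, stable = 0),
      smoking_cessation = c(accelerated = 0, average = 0, stable = 0)),
    baseline_covariates = list(
      sbp_sd = c(male = 6, female = 6), bmi_sd = c(male = 1.5, female = 1.5),
      smoker_prev = 0, diabetes_prev = 0, bp_medication_prev = 0),
    dropout_hazard = no_dropout(),
    missingness_rate = no_item_missing())
}

truth_groups <- function(truth) {
  data.frame(subject_id = truth$subject_id, class = truth$class,
             stringsAsFactors = FALSE)
}

gen_quiet <- function(config) {
  suppressWarnings(generate_cohort(config))
}
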