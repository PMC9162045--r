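class_levels <- c("accelerated", "average", "stable")

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds and validates the full parameter set of the generator, which
#' emulates the structure of a Betula-style prospective aging cohort:
#' 5-year waves, entry ages 35-80, a three-component mixture of
#' cardiovascular-risk slope trajectories sharing a common baseline
#' distribution, dementia/death multistate transitions concentrated in old
#' age, outcome-dependent wave dropout, MAR item missingness in individual
#' risk-factor covariates, and age-related episodic-memory decline with
#' excess decline in the accelerated component.
#'
#' Any argument may be partially overridden: supply a list with just the
#' fields to change and the remaining defaults are kept.
#'
#' @param n_subjects number of subjects.
#' @param n_waves number of 5-year waves (at least 2).
#' @param wave_spacing_years years between waves.
#' @param entry_age_range entry ages are drawn from the 5-year grid
#'   spanning this range.
#' @param entry_age_weights sampling weights over the entry-age grid; the
#'   default down-weights the 70+ entry groups (0.6 vs 1), reflecting the
#'   early attrition that thins the oldest recruitment groups of a
#'   prospective aging cohort before they contribute two waves.
#' @param trajectory_mixture named proportions over
#'   accelerated/average/stable; must sum to 1.
#' @param slope_params per-class covariate change rates: normal mean/SD of
#'   annual SBP (mmHg/yr) and BMI (kg/m^2/yr) change, per-wave incidence of
#'   diabetes onset, blood-pressure-medication start, smoking cessation and
#'   initiation, and wave-level measurement noise SDs.
#' @param baseline_covariates per-sex baseline means/SDs for SBP and BMI
#'   (with a BMI-SBP coupling coefficient), prevalences of smoking,
#'   diabetes and medication, and the education distribution. Baselines are
#'   shared across trajectory classes so the classes start from similar
#'   average risk and differ only in slopes.
#' @param apoe4_prevalence carrier proportion.
#' @param hazard_params per-transition discrete-time hazards: each of `ad`,
#'   `vad`, `death`, `dementia_death` has a per-wave baseline probability
#'   `base`, age bands (`age_breaks`/`age_mult`, evaluated at the age the
#'   event would be recorded), per-class multipliers `class_mult`, and an
#'   APOE e4 carrier multiplier `apoe_mult`. `dementia_min_age` suppresses
#'   dementia events at or below that age.
#' @param dropout_hazard per-wave marginal dropout probabilities `rates`
#'   (entry `w` is the probability of not attending wave `w` given
#'   attendance at `w - 1` and survival) and a nonignorability coefficient
#'   `outcome_coef`: subjects with a latent dementia or death anywhere on
#'   their path drop out with `exp(outcome_coef)`-fold higher probability,
#'   rescaled so the marginal per-wave rate stays at `rates[w]`.
#' @param missingness_rate per-covariate MAR masking rates plus age/sex
#'   coefficients; the masking probability depends only on observed age and
#'   sex.
#' @param em_params episodic-memory composite model: population mean/SD,
#'   annual age slope, excess annual decline in the accelerated class,
#'   measurement noise SD, the age at which the population mean applies,
#'   and the shares dividing the composite over the five recall tasks.
#' @param seed integer seed; the whole generated cohort is a deterministic
#'   function of (config, seed).
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 1244,
                          n_waves = 6,
                          wave_spacing_years = 5,
                          entry_age_range = c(35, 80),
                          entry_age_weights = NULL,
                          trajectory_mixture = c(accelerated = 0.18,
                                                 average = 0.60,
                                                 stable = 0.22),
                          slope_params = list(),
                          baseline_covariates = list(),
                          apoe4_prevalence = 0.30,
                          hazard_params = list(),
                          dropout_hazard = list(),
                          missingness_rate = list(),
                          em_params = list(),
                          seed = NULL) {
  merge_defaults <- function(user, def) {
    if (!length(user)) return(def)
    for (nm in names(user)) def[[nm]] <- user[[nm]]
    def
  }
  slope_def <- list(
    sbp_mean = c(accelerated = 1.5, average = 0.5, stable = -0.3),
    sbp_sd = c(accelerated = 0.25, average = 0.20, stable = 0.20),
    bmi_mean = c(accelerated = 0.12, average = 0.04, stable = -0.02),
    bmi_sd = c(accelerated = 0.04, average = 0.03, stable = 0.03),
    sbp_noise_sd = 4, bmi_noise_sd = 0.5,
    diabetes_onset = c(accelerated = 0.040, average = 0.015, stable = 0.005),
    bp_med_start = c(accelerated = 0.06, average = 0.03, stable = 0.01),
    smoking_cessation = c(accelerated = 0.10, average = 0.10, stable = 0.10),
    smoking_initiation = c(accelerated = 0, average = 0, stable = 0))
  base_def <- list(
    sbp_mean = c(male = 130, female = 125),
    sbp_sd = c(male = 15, female = 15),
    sbp_bmi_coupling = 0.8,
    bmi_mean = c(male = 26, female = 25),
    bmi_sd = c(male = 3.5, female = 4),
    smoker_prev = 0.25, diabetes_prev = 0.05, bp_medication_prev = 0.10,
    education_mean = 11, education_sd = 4)
  hz_def <- list(
    ad = list(base = 0.019, age_breaks = c(75, 85), age_mult = c(0, 1, 2),
              class_mult = c(accelerated = 3.5, average = 2.0, stable = 1),
              apoe_mult = 2.5),
    vad = list(base = 0.014, age_breaks = c(75, 85), age_mult = c(0, 1, 2),
               class_mult = c(accelerated = 3.5, average = 2.0, stable = 1),
               apoe_mult = 1.2),
    death = list(base = 0.007, age_breaks = c(70, 80), age_mult = c(1, 4, 8),
                 class_mult = c(accelerated = 1.3, average = 1.1, stable = 1),
                 apoe_mult = 1),
    dementia_death = list(base = 0.20, age_breaks = numeric(0), age_mult = 1,
                          class_mult = c(accelerated = 1, average = 1,
                                         stable = 1),
                          apoe_mult = 1),
    dementia_min_age = 65)
  drop_def <- list(rates = c(0, 0.02, 0.015, 0.06, 0.30, 0.39),
                   outcome_coef = 0.7)
  miss_def <- list(rate = c(sbp_mmHg = 0.05, bmi_kg_m2 = 0.05,
                            smoker = 0.03, diabetes = 0.03,
                            bp_medication = 0.03),
                   age_coef = 0.3, sex_coef = 0.1)
  em_def <- list(mean = 35, sd = 12, between_sd = 10, age_slope = -0.35,
                 excess_decline = -0.35, noise_sd = 3, age_center = 57.5,
                 task_shares = c(0.28, 0.18, 0.22, 0.14, 0.18))

  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_waves = as.integer(n_waves),
    wave_spacing_years = wave_spacing_years,
    entry_age_range = entry_age_range,
    entry_age_weights = entry_age_weights,
    trajectory_mixture = trajectory_mixture,
    slope_params = merge_defaults(slope_params, slope_def),
    baseline_covariates = merge_defaults(baseline_covariates, base_def),
    apoe4_prevalence = apoe4_prevalence,
    hazard_params = merge_defaults(hazard_params, hz_def),
    dropout_hazard = merge_defaults(dropout_hazard, drop_def),
    missingness_rate = merge_defaults(missingness_rate, miss_def),
    em_params = merge_defaults(em_params, em_def),
    seed = seed)

  if (cfg$n_subjects < 1) stop("invalid n_subjects")
  if (cfg$n_waves < 2) stop("invalid n_waves: need at least 2 waves")
  mx <- cfg$trajectory_mixture
  if (!setequal(names(mx), class_levels)) {
    stop("trajectory_mixture must be named over ",
         paste(class_levels, collapse = "/"))
  }
  if (abs(sum(mx) - 1) > 1e-8 || any(mx < 0)) {
    stop("trajectory_mixture must be nonnegative and sum to 1")
  }
  dr <- cfg$dropout_hazard$rates
  if (length(dr) < cfg$n_waves) {
    cfg$dropout_hazard$rates <- c(dr, rep(0, cfg$n_waves - length(dr)))
  }
  if (any(cfg$dropout_hazard$rates < 0 | cfg$dropout_hazard$rates > 1)) {
    stop("dropout_hazard: rates must be probabilities in [0, 1]")
  }
  for (tr in c("ad", "vad", "death", "dementia_death")) {
    h <- cfg$hazard_params[[tr]]
    if (h$base < 0 || h$base > 1) {
      stop("hazard_params$", tr, ": base must be a probability in [0, 1]")
    }
    if (length(h$age_mult) != length(h$age_breaks) + 1) {
      stop("hazard_params$", tr,
           ": age_mult must have length(age_breaks) + 1 entries")
    }
  }
  if (any(cfg$missingness_rate$rate < 0 | cfg$missingness_rate$rate > 1)) {
    stop("missingness_rate: rate must be probabilities in [0, 1]")
  }
  if (cfg$apoe4_prevalence < 0 || cfg$apoe4_prevalence > 1) {
    stop("apoe4_prevalence must be a probability in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

band_mult <- function(age, breaks, mult) {
  if (!length(breaks)) return(rep(mult[1], length(age)))
  idx <- findInterval(age, breaks) + 1L  # age == break falls in upper band
  mult[idx]
}

#' Generate a complete latent synthetic cohort
#'
#' Simulates the full (no-missingness, no-dropout) cohort: baseline
#' covariates, per-class covariate slopes, per-wave discrete-time
#' transitions through the healthy / AD / VaD / dead state space, and
#' episodic-memory task scores. Latent dropout times are drawn (they belong
#' to the ground truth) but are not applied; use [apply_missingness()] for
#' the observed table. Dementia events are only generated above the
#' configured minimum age. The same seed and config reproduce the result
#' byte for byte.
#'
#' @param config a [cohort_config()].
#' @return list with `cohort` (one row per subject-wave up to death) and
#'   `truth` (per-subject trajectory class, true slopes, applied hazard
#'   multipliers, latent event, death, and dropout waves).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  K <- config$n_waves
  sp <- config$wave_spacing_years
  bc <- config$baseline_covariates
  sl <- config$slope_params
  hz <- config$hazard_params

  age_grid <- seq(config$entry_age_range[1], config$entry_age_range[2], by = 5)
  wts <- config$entry_age_weights
  if (is.null(wts)) wts <- ifelse(age_grid >= 70, 0.6, 1)
  if (length(wts) != length(age_grid)) {
    stop("entry_age_weights must have one weight per entry-age grid value")
  }
  entry_age <- age_grid[sample.int(length(age_grid), n, replace = TRUE,
                                   prob = wts)]
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  apoe4 <- as.integer(stats::runif(n) < config$apoe4_prevalence)
  education <- pmax(0, stats::rnorm(n, bc$education_mean, bc$education_sd))
  cls <- sample(class_levels, n, replace = TRUE,
                prob = config$trajectory_mixture[class_levels])

  bmi0 <- stats::rnorm(n, bc$bmi_mean[sex], bc$bmi_sd[sex])
  bmi0 <- pmax(bmi0, 15)
  sbp0 <- stats::rnorm(n, bc$sbp_mean[sex] +
                          bc$sbp_bmi_coupling * (bmi0 - bc$bmi_mean[sex]),
                       bc$sbp_sd[sex])
  sbp0 <- pmax(sbp0, 80)
  smoker0 <- stats::runif(n) < bc$smoker_prev
  diabetes0 <- stats::runif(n) < bc$diabetes_prev
  bpmed0 <- stats::runif(n) < bc$bp_medication_prev

  sbp_slope <- stats::rnorm(n, sl$sbp_mean[cls], sl$sbp_sd[cls])
  bmi_slope <- stats::rnorm(n, sl$bmi_mean[cls], sl$bmi_sd[cls])

  em <- config$em_params
  em_u <- stats::rnorm(n, 0, em$between_sd)

  # wave-by-wave covariate paths and binary factor transitions
  smoker <- matrix(NA, n, K); diabetes <- matrix(NA, n, K)
  bpmed <- matrix(NA, n, K)
  smoker[, 1] <- smoker0; diabetes[, 1] <- diabetes0; bpmed[, 1] <- bpmed0
  for (w in 2:K) {
    quit <- stats::runif(n) < sl$smoking_cessation[cls]
    start <- stats::runif(n) < sl$smoking_initiation[cls]
    smoker[, w] <- ifelse(smoker[, w - 1], !quit, start)
    diabetes[, w] <- diabetes[, w - 1] |
      (stats::runif(n) < sl$diabetes_onset[cls])
    bpmed[, w] <- bpmed[, w - 1] | (stats::runif(n) < sl$bp_med_start[cls])
  }
  tyears <- (seq_len(K) - 1) * sp
  sbp <- outer(sbp0, rep(1, K)) + outer(sbp_slope, tyears) +
    matrix(stats::rnorm(n * K, 0, sl$sbp_noise_sd), n, K)
  bmi <- outer(bmi0, rep(1, K)) + outer(bmi_slope, tyears) +
    matrix(stats::rnorm(n * K, 0, sl$bmi_noise_sd), n, K)
  sbp <- pmax(sbp, 80); bmi <- pmax(bmi, 15)

  # multistate path: healthy -> AD | VaD | dead; dementia -> dead
  state <- matrix("healthy", n, K)
  cmul <- function(h) h$class_mult[cls] * ifelse(apoe4 == 1, h$apoe_mult, 1)
  m_ad <- cmul(hz$ad); m_vad <- cmul(hz$vad); m_death <- cmul(hz$death)
  m_dd <- cmul(hz$dementia_death)
  for (w in 1:(K - 1)) {
    age_next <- entry_age + w * sp
    healthy <- state[, w] == "healthy"
    p_ad <- hz$ad$base * band_mult(age_next, hz$ad$age_breaks,
                                   hz$ad$age_mult) * m_ad
    p_vad <- hz$vad$base * band_mult(age_next, hz$vad$age_breaks,
                                     hz$vad$age_mult) * m_vad
    p_de <- hz$death$base * band_mult(age_next, hz$death$age_breaks,
                                      hz$death$age_mult) * m_death
    young <- age_next <= hz$dementia_min_age
    p_ad[young] <- 0; p_vad[young] <- 0
    tot <- p_ad + p_vad + p_de
    over <- tot > 1
    if (any(over)) {  # defensive cap; default hazards never reach this
      p_ad[over] <- p_ad[over] / tot[over]
      p_vad[over] <- p_vad[over] / tot[over]
      p_de[over] <- p_de[over] / tot[over]
    }
    u <- stats::runif(n)
    nxt <- ifelse(u < p_ad, "AD",
                  ifelse(u < p_ad + p_vad, "VaD",
                         ifelse(u < p_ad + p_vad + p_de, "dead", "healthy")))
    state[healthy, w + 1] <- nxt[healthy]
    dem <- state[, w] %in% c("AD", "VaD")
    p_dd <- pmin(1, hz$dementia_death$base *
                    band_mult(age_next, hz$dementia_death$age_breaks,
                              hz$dementia_death$age_mult) * m_dd)
    dies <- stats::runif(n) < p_dd
    state[dem, w + 1] <- ifelse(dies[dem], "dead", state[dem, w])
    dead <- state[, w] == "dead"
    state[dead, w + 1] <- "dead"
  }
  death_wave <- apply(state, 1, function(s) {
    i <- which(s == "dead"); if (length(i)) min(i) else NA_integer_
  })
  event_wave <- apply(state, 1, function(s) {
    i <- which(s %in% c("AD", "VaD")); if (length(i)) min(i) else NA_integer_
  })
  event_type <- ifelse(is.na(event_wave), "none",
                       state[cbind(seq_len(n),
                                   ifelse(is.na(event_wave), 1, event_wave))])

  # episodic memory: linear age trend + subject level + class excess decline
  excess <- ifelse(cls == "accelerated", em$excess_decline, 0)
  emlat <- em$mean + outer(em$age_slope * (entry_age - em$age_center) + em_u,
                           rep(1, K)) +
    em$age_slope * outer(rep(1, n), tyears) + outer(excess, tyears) +
    matrix(stats::rnorm(n * K, 0, em$noise_sd), n, K)
  emcomp <- pmin(pmax(round(emlat), 0), 76)
  shares <- em$task_shares / sum(em$task_shares)

  # latent dropout times (ground truth; applied by apply_missingness).
  # rates are marginal: the nonignorability multiplier shifts dropout toward
  # subjects with a latent dementia/death path without changing the
  # per-wave marginal rate among those at risk.
  rates <- config$dropout_hazard$rates
  mfac <- exp(config$dropout_hazard$outcome_coef)
  path_flag <- !is.na(event_wave) | !is.na(death_wave)
  dropout_wave <- rep(NA_integer_, n)
  for (w in 2:K) {
    if (rates[w] <= 0) next
    at_risk <- is.na(dropout_wave) &
      (is.na(death_wave) | death_wave > w)
    if (!any(at_risk)) next
    phi <- mean(path_flag[at_risk])
    p_no <- min(1, rates[w] / (1 - phi + phi * mfac))
    p_yes <- min(1, mfac * p_no)
    p <- ifelse(path_flag, p_yes, p_no)
    drops <- at_risk & stats::runif(n) < p
    dropout_wave[drops] <- w
  }

  last_wave <- ifelse(is.na(death_wave), K, death_wave)
  rows <- sequence(last_wave)
  sid <- rep(seq_len(n), last_wave)
  idx <- cbind(sid, rows)
  tasks <- vapply(seq_along(shares), function(j) {
    hi <- round(cumsum(shares)[j] * emcomp[idx])
    lo <- if (j == 1) 0 else round(cumsum(shares)[j - 1] * emcomp[idx])
    hi - lo
  }, numeric(length(sid)))
  cohort <- data.frame(
    subject_id = sid,
    wave = rows,
    age = entry_age[sid] + (rows - 1) * sp,
    sex = sex[sid],
    education_years = education[sid],
    apoe4 = apoe4[sid],
    sbp_mmHg = sbp[idx],
    bp_medication = as.integer(bpmed[idx]),
    bmi_kg_m2 = bmi[idx],
    smoker = as.integer(smoker[idx]),
    diabetes = as.integer(diabetes[idx]),
    em1 = tasks[, 1], em2 = tasks[, 2], em3 = tasks[, 3],
    em4 = tasks[, 4], em5 = tasks[, 5],
    em_composite = emcomp[idx],
    state = state[idx],
    stringsAsFactors = FALSE)

  truth <- data.frame(
    subject_id = seq_len(n),
    class = cls,
    entry_age = entry_age,
    sbp_slope = sbp_slope,
    bmi_slope = bmi_slope,
    mult_ad = m_ad, mult_vad = m_vad, mult_death = m_death,
    mult_dementia_death = m_dd,
    event_type = event_type,
    event_wave = event_wave,
    death_wave = death_wave,
    dropout_wave = dropout_wave,
    stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Apply wave dropout and item-level MAR missingness
#'
#' Truncates each subject's rows at their latent dropout wave (dropout is
#' monotone: once out, no later waves) and masks individual risk-factor
#' covariates with probabilities that depend only on observed age and sex.
#' The ground-truth table is not modified.
#'
#' @param cohort complete cohort from [generate_cohort()].
#' @param truth matching `truth` table (carries the latent dropout waves).
#' @param config the same [cohort_config()].
#' @return the observed cohort data frame with rows removed after dropout
#'   and `NA` in masked covariate cells.
#' @export
apply_missingness <- function(cohort, truth, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  dw <- truth$dropout_wave[match(cohort$subject_id, truth$subject_id)]
  out <- cohort[is.na(dw) | cohort$wave < dw, , drop = FALSE]
  mr <- config$missingness_rate
  male <- as.numeric(out$sex == "male")
  for (v in names(mr$rate)) {
    if (mr$rate[[v]] <= 0) next
    p <- pmin(0.9, mr$rate[[v]] *
                exp(mr$age_coef * (out$age - 60) / 10 + mr$sex_coef * male))
    out[[v]][stats::runif(nrow(out)) < p] <- NA
  }
  rownames(out) <- NULL
  out
}

#' Write / read the cohort CSV dialect
#'
#' Long format, one row per subject-wave, fixed header (the column set of
#' [generate_cohort()]), missing entries encoded as empty fields. The truth
#' table round-trips through the same dialect keyed by `subject_id`.
#'
#' @param x cohort or truth data frame.
#' @param path file path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = "", check.names = FALSE)
}
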