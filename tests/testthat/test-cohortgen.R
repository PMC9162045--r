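test_that("same seed and config give a byte-identical cohort", {
  cfg <- cohort_config(n_subjects = 300, seed = 21)
  g1 <- gen_quiet(cfg)
  g2 <- gen_quiet(cfg)
  expect_identical(g1, g2)
  o1 <- apply_missingness(g1$cohort, g1$truth, cfg)
  o2 <- apply_missingness(g2$cohort, g2$truth, cfg)
  expect_identical(o1, o2)
  # and the CSV dialect round-trips
  p <- tempfile(fileext = ".csv")
  write_cohort_csv(o1, p)
  back <- read_cohort_csv(p)
  expect_equal(nrow(back), nrow(o1))
  expect_equal(back$sbp_mmHg, o1$sbp_mmHg, tolerance = 1e-12)
  unlink(p)
})

test_that("trajectory mixture proportions match the configured defaults", {
  g <- gen_quiet(cohort_config(n_subjects = 2000, seed = 22))
  p <- table(g$truth$class) / 2000
  expect_lt(abs(p[["accelerated"]] - 0.18), 0.02)
  expect_lt(abs(p[["average"]] - 0.60), 0.02)
  expect_lt(abs(p[["stable"]] - 0.22), 0.02)
})

test_that("structural invariants hold for every generated row", {
  g <- gen_quiet(cohort_config(n_subjects = 500, seed = 23))
  co <- g$cohort
  sp <- split(co, co$subject_id)
  rank <- c(healthy = 1, AD = 2, VaD = 2, dead = 3)
  for (d in sp) {
    d <- d[order(d$wave), ]
    expect_equal(diff(d$age), rep(5, nrow(d) - 1))
    r <- rank[d$state]
    expect_true(all(diff(r) >= 0))                      # no resurrection
    dem <- d$state[d$state %in% c("AD", "VaD")]
    expect_lte(length(unique(dem)), 1)                  # no type switch
  }
  tasks <- as.matrix(co[, paste0("em", 1:5)])
  expect_true(all(rowSums(tasks) == co$em_composite))
  expect_true(all(co$em_composite >= 0 & co$em_composite <= 76))
  expect_true(all(tasks >= 0))
  # dementia events only above the configured minimum age
  ev <- g$truth[!is.na(g$truth$event_wave), ]
  expect_true(all(ev$entry_age + (ev$event_wave - 1) * 5 > 65))
})

test_that("single-hazard cohort reproduces the geometric incidence curve", {
  h <- 0.08
  cfg <- cohort_config(
    n_subjects = 4000, seed = 24,
    entry_age_range = c(70, 70), entry_age_weights = 1,
    hazard_params = flat_hazards(dem_base = h, death_base = 0),
    dropout_hazard = no_dropout(), missingness_rate = no_item_missing())
  cfg$hazard_params$vad$base <- 0
  g <- gen_quiet(cfg)
  for (k in 2:6) {
    expected <- 1 - (1 - h)^(k - 1)
    observed <- mean(!is.na(g$truth$event_wave) & g$truth$event_wave <= k)
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(observed - expected), 4 * se)
  }
})

test_that("null generator yields class-independent event proportions", {
  cfg <- cohort_config(
    n_subjects = 5000, seed = 25,
    entry_age_range = c(70, 80), entry_age_weights = c(1, 1, 1),
    slope_params = list(
      sbp_mean = c(accelerated = 0.5, average = 0.5, stable = 0.5),
      sbp_sd = c(accelerated = 0.2, average = 0.2, stable = 0.2),
      bmi_mean = c(accelerated = 0.04, average = 0.04, stable = 0.04),
      bmi_sd = c(accelerated = 0.03, average = 0.03, stable = 0.03),
      diabetes_onset = c(accelerated = 0.02, average = 0.02, stable = 0.02),
      bp_med_start = c(accelerated = 0.03, average = 0.03, stable = 0.03)),
    hazard_params = flat_hazards(dem_base = 0.04),
    dropout_hazard = no_dropout(), missingness_rate = no_item_missing())
  g <- gen_quiet(cfg)
  tab <- table(g$truth$class, g$truth$event_type != "none")
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})

test_that("zero-rate missingness is the identity", {
  cfg <- cohort_config(
    n_subjects = 200, seed = 26,
    dropout_hazard = list(rates = rep(0, 6)),
    missingness_rate = no_item_missing())
  g <- gen_quiet(cfg)
  expect_identical(apply_missingness(g$cohort, g$truth, cfg), g$cohort)
})

test_that("realized per-wave dropout matches the configured marginals", {
  cfg <- cohort_config(n_subjects = 4000, seed = 27)
  g <- gen_quiet(cfg)
  tr <- g$truth
  target <- c(NA, NA, 0.015, 0.06, 0.30, 0.39)
  for (w in 3:6) {
    at_risk <- (is.na(tr$dropout_wave) | tr$dropout_wave >= w) &
      (is.na(tr$death_wave) | tr$death_wave > w)
    realized <- mean(!is.na(tr$dropout_wave[at_risk]) &
                       tr$dropout_wave[at_risk] == w)
    expect_lt(abs(realized - target[w]), 0.02)
  }
})

test_that("dropout is enriched among subjects on a dementia/death path", {
  cfg <- cohort_config(n_subjects = 5000, seed = 28)
  g <- gen_quiet(cfg)
  tr <- g$truth
  dem <- !is.na(tr$event_wave)
  never <- !dem & is.na(tr$death_wave)
  # per-wave conditioning: deaths truncate the opportunity to drop out, so
  # the comparison is among subjects at risk of dropping at each wave
  drops <- c(dem = 0, never = 0); risk <- c(dem = 0, never = 0)
  for (w in 2:6) {
    at <- (is.na(tr$dropout_wave) | tr$dropout_wave >= w) &
      (is.na(tr$death_wave) | tr$death_wave > w)
    out <- !is.na(tr$dropout_wave) & tr$dropout_wave == w
    drops <- drops + c(sum(out[at & dem]), sum(out[at & never]))
    risk <- risk + c(sum(at & dem), sum(at & never))
  }
  expect_gt(drops[1] / risk[1], drops[2] / risk[2])
  test <- prop.test(drops, risk, alternative = "greater")
  expect_lt(test$p.value, 0.01)
})

test_that("item missingness is MAR in observed age", {
  cfg <- cohort_config(n_subjects = 4000, seed = 29,
                       dropout_hazard = no_dropout())
  g <- gen_quiet(cfg)
  obs <- apply_missingness(g$cohort, g$truth, cfg)
  old <- obs$age >= 70
  expect_gt(mean(is.na(obs$sbp_mmHg[old])), mean(is.na(obs$sbp_mmHg[!old])))
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(cohort_config(trajectory_mixture = c(accelerated = 0.5,
                                                    average = 0.5,
                                                    stable = 0.5)),
               "trajectory_mixture")
  expect_error(cohort_config(n_waves = 1), "n_waves")
  expect_error(cohort_config(dropout_hazard = list(rates = c(0, 1.4))),
               "dropout_hazard")
  expect_error(cohort_config(apoe4_prevalence = 2), "apoe4_prevalence")
  expect_error(
    cohort_config(hazard_params = list(
      ad = list(base = 2, age_breaks = numeric(0), age_mult = 1,
                class_mult = c(accelerated = 1, average = 1, stable = 1),
                apoe_mult = 1))),
    "hazard_params")
})
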