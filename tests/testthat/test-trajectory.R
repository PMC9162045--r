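series_df <- function(id, years, frs, wave = seq_along(years)) {
  data.frame(subject_id = id, wave = wave, years = years, frs = frs)
}

test_that("per-subject OLS slopes match closed forms", {
  s <- series_df(1, c(0, 5, 10), c(0.10, 0.15, 0.20))
  expect_equal(fit_frs_slopes(s)$raw_slope, 0.01)
  s2 <- series_df(2, c(0, 5, 10, 15), rep(0.12, 4))
  expect_equal(fit_frs_slopes(s2)$raw_slope, 0)
  # noisy 5-point series vs the textbook OLS oracle
  set.seed(31)
  yrs <- c(0, 5, 10, 15, 20)
  frs <- 0.08 + 0.002 * yrs + rnorm(5, 0, 0.01)
  oracle <- unname(coef(lm(frs ~ yrs))[2])
  expect_equal(fit_frs_slopes(series_df(3, yrs, frs))$raw_slope, oracle,
               tolerance = 1e-10)
  # below min_waves: unclassified marker, no exception
  one <- fit_frs_slopes(rbind(series_df(4, 0, 0.1), series_df(5, yrs, frs)))
  expect_true(is.na(one$raw_slope[one$subject_id == 4]))
  expect_equal(nrow(one), 2)  # kept, not dropped
})

test_that("pattern-mixture moments obey the law of total variance", {
  # one pattern: plain mean and SD
  sl <- data.frame(adjusted_slope = c(1, 2, 3, 6), pattern = 6)
  m <- pattern_mixture_moments(sl)
  expect_equal(m$mean, 3)
  expect_equal(m$sd, sd(c(1, 2, 3, 6)))
  # two equal patterns, zero within-variance
  sl2 <- data.frame(adjusted_slope = c(1, 1, 5, 5), pattern = c(3, 3, 6, 6))
  m2 <- pattern_mixture_moments(sl2)
  expect_equal(m2$mean, 3)
  expect_equal(m2$sd, 2)  # sqrt(((1-5)/2)^2)
  expect_error(pattern_mixture_moments(
    data.frame(adjusted_slope = NA_real_, pattern = 6)), "classifiable")
})

test_that("classification applies the strict 1-SD rule", {
  sl <- data.frame(adjusted_slope = c(-3, -2, 0, 2, 3), pattern = 6)
  m <- pattern_mixture_moments(sl)
  expect_equal(m$mean, 0)
  expect_equal(m$sd, sd(c(-3, -2, 0, 2, 3)))  # ~2.55
  cl <- classify_trajectories(sl, m)
  expect_equal(as.character(cl$class),
               c("stable", "average", "average", "average", "accelerated"))
  # a slope exactly at mean + 1 SD stays average (strict inequality)
  sl2 <- data.frame(adjusted_slope = c(0, m$sd), pattern = 6)
  cl2 <- classify_trajectories(sl2, m)
  expect_equal(as.character(cl2$class[2]), "average")
})

test_that("classes are invariant to a consistent time rescaling", {
  set.seed(32)
  sl <- data.frame(adjusted_slope = rnorm(200), pattern = sample(3:6, 200,
                                                                 TRUE))
  m <- pattern_mixture_moments(sl)
  cl <- classify_trajectories(sl, m)
  scaled <- sl
  scaled$adjusted_slope <- sl$adjusted_slope * 5  # per-wave instead of /yr
  ms <- pattern_mixture_moments(scaled)
  cls <- classify_trajectories(scaled, ms)
  expect_identical(cl$class, cls$class)
})

test_that("true classes are recovered on a low-noise cohort", {
  g <- gen_quiet(lownoise_config(1500, 33))
  obs <- apply_missingness(g$cohort, g$truth, lownoise_config(1500, 33))
  tr <- suppressWarnings(frs_trajectory(obs))
  lab <- tr$labels[tr$labels$class != "unclassified", ]
  agree <- mean(as.character(lab$class) ==
                  g$truth$class[match(lab$subject_id, g$truth$subject_id)])
  expect_gte(agree, 0.9)
})

test_that("subjects censored below min_waves are unclassified, not lost", {
  g <- gen_quiet(cohort_config(n_subjects = 400, seed = 34))
  obs <- apply_missingness(g$cohort, g$truth, cohort_config(
    n_subjects = 400, seed = 34))
  tr <- suppressWarnings(frs_trajectory(obs))
  expect_setequal(tr$labels$subject_id, unique(obs$subject_id))
  # diagnosed at wave 2 -> a single pre-diagnosis value -> unclassified
  early <- g$truth$subject_id[!is.na(g$truth$event_wave) &
                                g$truth$event_wave == 2]
  early <- intersect(early, tr$labels$subject_id)
  if (length(early)) {
    expect_true(all(tr$labels$class[tr$labels$subject_id %in% early] ==
                      "unclassified"))
  }
})

test_that("pattern-mixture mean resists slope-linked dropout", {
  # constructed scenario: linear individual risk trajectories whose slope
  # drives dropout; steep subjects (20%, slope 0.010/yr) mostly leave after
  # two waves, flat subjects (slope 0.003/yr) mostly complete
  set.seed(35)
  n <- 2000
  steep <- runif(n) < 0.20
  b <- ifelse(steep, 0.010, 0.003)
  a <- rnorm(n, 0.08, 0.02)
  truth_mean <- mean(b)
  last_wave <- ifelse(steep & runif(n) < 0.85,
                      sample(2:3, n, replace = TRUE),
                      ifelse(runif(n) < 0.10,
                             sample(3:5, n, replace = TRUE), 6))
  ser <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- seq_len(last_wave[i])
    data.frame(subject_id = i, wave = w, years = (w - 1) * 5,
               frs = a[i] + b[i] * (w - 1) * 5)
  }))
  slopes <- fit_frs_slopes(ser)
  pm <- pattern_mixture_moments(slopes, value = "raw_slope")
  cc <- mean(slopes$raw_slope[slopes$pattern == 6])

  expect_lt(abs(pm$mean - truth_mean) / truth_mean, 0.10)
  expect_gt(abs(cc - truth_mean) / truth_mean, 0.10)
  expect_gt(pm$mean, cc)  # dropouts carry the steeper slopes
})
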