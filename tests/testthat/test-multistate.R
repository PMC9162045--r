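toy_subject <- function(id, states, entry_age = 72) {
  w <- seq_along(states)
  data.frame(subject_id = id, wave = w, age = entry_age + (w - 1) * 5,
             sex = "female", education_years = 10, apoe4 = 0,
             sbp_mmHg = 130, bp_medication = 0, bmi_kg_m2 = 25,
             smoker = 0, diabetes = 0, em1 = 7, em2 = 7, em3 = 7,
             em4 = 7, em5 = 7, em_composite = 35, state = states,
             stringsAsFactors = FALSE)
}
toy_groups <- function(ids, cls = "average") {
  data.frame(subject_id = ids, class = cls, stringsAsFactors = FALSE)
}

test_that("person-period expansion follows the worked examples", {
  co <- rbind(
    toy_subject(1, rep("healthy", 6)),
    toy_subject(2, c("healthy", "healthy", "AD", "AD", "dead")),
    toy_subject(3, c("healthy", "healthy", "healthy")))  # drops after T3
  pp <- person_period(co, toy_groups(1:3), model = "illness_death")
  hd <- pp$healthy_dementia
  # healthy throughout: 5 rows per healthy-origin transition, no events
  expect_equal(sum(hd$subject_id == 1), 5)
  expect_equal(sum(pp$healthy_death$subject_id == 1), 5)
  expect_equal(sum(hd$event[hd$subject_id == 1]), 0)
  # AD at wave 3, dead at wave 5: healthy rows for intervals 1-2 with the
  # event at 2; dementia-death rows for intervals 3-4 with the event at 4
  expect_equal(hd$interval[hd$subject_id == 2], 1:2)
  expect_equal(hd$event[hd$subject_id == 2], c(0, 1))
  dd <- pp$dementia_death
  expect_equal(dd$interval[dd$subject_id == 2], 3:4)
  expect_equal(dd$event[dd$subject_id == 2], c(0, 1))
  # dropout censors at the last observed wave
  expect_equal(hd$interval[hd$subject_id == 3], 1:2)
})

test_that("expansion event totals equal raw state-change counts", {
  g <- gen_quiet(covfree_config(600, 41))
  pp <- person_period(g$cohort, truth_groups(g$truth),
                      model = "illness_death")
  truth_dem <- sum(!is.na(g$truth$event_wave))
  truth_death_healthy <- sum(!is.na(g$truth$death_wave) &
                               is.na(g$truth$event_wave))
  truth_death_dem <- sum(!is.na(g$truth$death_wave) &
                           !is.na(g$truth$event_wave))
  expect_equal(sum(pp$healthy_dementia$event), truth_dem)
  expect_equal(sum(pp$healthy_death$event), truth_death_healthy)
  expect_equal(sum(pp$dementia_death$event), truth_death_dem)
  # competing transitions share their risk set row for row
  expect_equal(pp$healthy_dementia[, c("subject_id", "interval")],
               pp$healthy_death[, c("subject_id", "interval")])
})

test_that("inconsistent state sequences are rejected with the subject id", {
  co <- rbind(toy_subject(7, c("healthy", "dead", "healthy")))
  expect_error(person_period(co, toy_groups(7), model = "illness_death"),
               "7")
})

test_that("recursion honors closed forms and conserves mass", {
  # all hazards zero: everyone stays healthy
  zero <- list(healthy_dementia = matrix(0, 4, 5),
               healthy_death = matrix(0, 4, 5),
               dementia_death = matrix(0, 4, 5))
  res <- cvdtraj:::occupancy_recursion(zero, "illness_death", 6)
  expect_true(all(res$occupancy$healthy == 1))
  expect_true(all(res$incidence$dementia == 0))
  # single transition, constant hazard: geometric cumulative incidence
  h <- 0.07
  one <- list(healthy_event = matrix(h, 1, 5))
  res2 <- cvdtraj:::occupancy_recursion(one, "binary", 6)
  expect_equal(res2$incidence$event[1, ], 1 - (1 - h)^(0:5),
               tolerance = 1e-12)
  # stochastic hazards: occupancy rows always sum to one
  set.seed(42)
  rnd <- list(healthy_dementia = matrix(runif(20, 0, 0.3), 4, 5),
              healthy_death = matrix(runif(20, 0, 0.3), 4, 5),
              dementia_death = matrix(runif(20, 0, 0.5), 4, 5))
  res3 <- cvdtraj:::occupancy_recursion(rnd, "illness_death", 6)
  total <- res3$occupancy$healthy + res3$occupancy$dementia +
    res3$occupancy$dead
  expect_true(all(abs(total - 1) < 1e-9))
  # absorbing-state mass never decreases
  expect_true(all(apply(res3$occupancy$dead, 1, function(r)
    all(diff(r) >= -1e-12))))
})

test_that("fitted transition hazards are probabilities and class effects
           track the generator", {
  g <- gen_quiet(covfree_config(
    1500, 43, dem_class_mult = c(accelerated = 3, average = 1.7,
                                 stable = 1)))
  fit <- msbart(g$cohort, truth_groups(g$truth), model = "illness_death",
                n_trees = 15, n_burn = 80, n_draws = 120)
  prof <- fit$baseline[1, , drop = FALSE]
  haz_acc <- cvdtraj:::transition_hazards(fit, prof, "accelerated")
  haz_sta <- cvdtraj:::transition_hazards(fit, prof, "stable")
  for (h in haz_acc) expect_true(all(h > 0 & h < 1))
  # accelerated dementia hazard exceeds stable at every interval
  expect_true(all(colMeans(haz_acc$healthy_dementia) >
                    colMeans(haz_sta$healthy_dementia)))
})

test_that("zero-event transitions raise a named error", {
  co <- rbind(toy_subject(1, rep("healthy", 6)),
              toy_subject(2, rep("healthy", 6)))
  expect_error(msbart(co, toy_groups(1:2), model = "illness_death",
                      n_trees = 5, n_burn = 10, n_draws = 10),
               "healthy_dementia")
})

test_that("null-effect fits show no class separation in the hazards", {
  g <- gen_quiet(covfree_config(1500, 44))
  fit <- msbart(g$cohort, truth_groups(g$truth), model = "illness_death",
                n_trees = 15, n_burn = 80, n_draws = 120)
  prof <- fit$baseline[1, , drop = FALSE]
  h_acc <- colMeans(cvdtraj:::transition_hazards(fit, prof,
                                                 "accelerated")$healthy_dementia)
  h_sta <- colMeans(cvdtraj:::transition_hazards(fit, prof,
                                                 "stable")$healthy_dementia)
  expect_true(all(abs(h_acc - h_sta) < 0.03))
})
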