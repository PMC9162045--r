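#' Episodic-memory composite scores
#'
#' The composite is the exact sum of the five recall-task scores
#' (range 0-76); a wave with any missing task has a missing composite.
#'
#' @param cohort cohort data frame with task columns `em1`..`em5`.
#' @return data frame `subject_id`, `wave`, `composite`.
#' @export
em_composite <- function(cohort) {
  tasks <- as.matrix(cohort[, paste0("em", 1:5)])
  if (any(tasks < 0, na.rm = TRUE)) {
    stop("negative episodic-memory task score")
  }
  comp <- rowSums(tasks)  # NA propagates when any task is missing
  if (any(comp > 76, na.rm = TRUE)) {
    stop("episodic-memory composite above 76: invalid task scores")
  }
  data.frame(subject_id = cohort$subject_id, wave = cohort$wave,
             composite = comp)
}

#' Relative episodic-memory decline events
#'
#' Operational decline definition for the younger stratum: at each wave a
#' subject's composite is residualized against the mean composite of
#' same-wave peers within `age_window` years of age; the decline event is
#' the first wave at which the residualized score falls at least
#' `threshold_sd` pooled SDs below the subject's own baseline residualized
#' score. Subjects without an event are censored at their last observed
#' composite. Events are monotone in the threshold: lowering
#' `threshold_sd` never removes an event.
#'
#' @param cohort observed cohort data frame.
#' @param threshold_sd drop threshold in pooled SDs (default 1).
#' @param age_window half-width of the age-norm window in years
#'   (default 5).
#' @param min_waves minimum observed composites to be evaluable
#'   (default 2).
#' @param max_entry_age eligibility ceiling on age at first observed wave
#'   (default 65, the pre-dementia stratum).
#' @return data frame `subject_id`, `event` (0/1), `wave` (event wave or
#'   censoring wave), `entry_age`.
#' @export
em_decline_events <- function(cohort, threshold_sd = 1, age_window = 5,
                              min_waves = 2, max_entry_age = 65) {
  stopifnot(threshold_sd > 0)
  comp <- em_composite(cohort)
  comp$age <- cohort$age
  comp <- comp[!is.na(comp$composite), ]
  # age norms: mean composite of peers of similar age at the same wave
  comp$resid <- NA_real_
  for (w in unique(comp$wave)) {
    at <- comp$wave == w
    ages <- comp$age[at]
    vals <- comp$composite[at]
    peer_mean <- vapply(ages, function(a) {
      mean(vals[abs(ages - a) <= age_window])
    }, numeric(1))
    comp$resid[at] <- vals - peer_mean
  }
  pooled_sd <- stats::sd(comp$resid)

  sp <- split(comp, comp$subject_id)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$wave), ]
    entry_age <- d$age[1]
    if (entry_age > max_entry_age || nrow(d) < min_waves) return(NULL)
    drop_by <- d$resid - d$resid[1]
    hit <- which(drop_by <= -threshold_sd * pooled_sd)
    hit <- hit[hit > 1]
    data.frame(subject_id = d$subject_id[1],
               event = as.integer(length(hit) > 0),
               wave = if (length(hit)) d$wave[min(hit)] else max(d$wave),
               entry_age = entry_age)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no evaluable subjects for memory decline")
  rownames(out) <- NULL
  out
}

#' Two-state cohort for the memory-decline multistate analysis
#'
#' Converts decline events into the state sequences of the binary
#' (no-decline to decline) model so they feed the same person-period,
#' BART, and standardization machinery as the dementia models: each
#' subject is `healthy` up to the wave before the event, `event` from the
#' event wave, and simply censored at the last pre-event observation
#' otherwise.
#'
#' @param cohort observed cohort (source of covariates).
#' @param events event table from [em_decline_events()].
#' @return cohort-shaped data frame with a two-level `state` column.
#' @export
decline_cohort <- function(cohort, events) {
  keep <- cohort$subject_id %in% events$subject_id
  co <- cohort[keep, c("subject_id", "wave", "age", "sex",
                       "education_years", "apoe4")]
  ev <- events[match(co$subject_id, events$subject_id), ]
  co <- co[co$wave <= ev$wave, ]
  ev <- events[match(co$subject_id, events$subject_id), ]
  co$state <- ifelse(ev$event == 1 & co$wave >= ev$wave, "event", "healthy")
  rownames(co) <- NULL
  co
}
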