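#' Transition structure of the supported multistate models
#'
#' Three discrete-time models over 5-year waves, all with death absorbing:
#' `illness_death` pools AD and VaD into one dementia state
#' (healthy -> dementia, healthy -> dead, dementia -> dead); `ad_vad`
#' keeps them separate with their own post-diagnosis death intensities;
#' `binary` is the two-state no-event -> event model used for
#' episodic-memory decline.
#'
#' @param model model name.
#' @return data frame with columns `name`, `from`, `to`.
#' @export
msbart_transitions <- function(model = c("illness_death", "ad_vad",
                                         "binary")) {
  model <- match.arg(model)
  switch(model,
    illness_death = data.frame(
      name = c("healthy_dementia", "healthy_death", "dementia_death"),
      from = c("healthy", "healthy", "dementia"),
      to = c("dementia", "dead", "dead"),
      stringsAsFactors = FALSE),
    ad_vad = data.frame(
      name = c("healthy_ad", "healthy_vad", "healthy_death",
               "ad_death", "vad_death"),
      from = c("healthy", "healthy", "healthy", "AD", "VaD"),
      to = c("AD", "VaD", "dead", "dead", "dead"),
      stringsAsFactors = FALSE),
    binary = data.frame(
      name = "healthy_event",
      from = "healthy", to = "event",
      stringsAsFactors = FALSE))
}

model_states <- function(model) {
  switch(model,
    illness_death = c("healthy", "dementia", "dead"),
    ad_vad = c("healthy", "AD", "VaD", "dead"),
    binary = c("healthy", "event"))
}

map_state <- function(state, model) {
  if (model == "illness_death") {
    state[state %in% c("AD", "VaD")] <- "dementia"
  }
  state
}

class_code <- function(cls) {
  # ordinal coding: stable 0, average 1, accelerated 2
  unname(c(stable = 0, average = 1, accelerated = 2)[as.character(cls)])
}

#' Expand a cohort into person-period transition tables
#'
#' Discrete-time expansion with the half-open interval convention: interval
#' `k` covers (wave k, wave k+1]. A subject contributes a row to a
#' transition for every interval spent under observation in its origin
#' state; the event indicator marks the state recorded at the interval's
#' closing wave. A subject first seen demented at wave `k + 1` therefore
#' has their dementia event in interval `k` and enters the
#' dementia-to-death risk set at interval `k + 1`. Dropout censors at the
#' last observed wave. Covariates are frozen at each subject's first
#' observed wave; the interval index is carried as a feature so fitted
#' hazards are freely time-varying (nonproportional).
#'
#' @param cohort observed cohort data frame.
#' @param groups per-subject trajectory labels: an `frs_trajectory` object,
#'   or a data frame with `subject_id` and `class`. Unclassified subjects
#'   are excluded.
#' @param model multistate model, see [msbart_transitions()].
#' @param covariates baseline covariate columns to carry
#'   (subset of `age_baseline`, `sex`, `education_years`, `apoe4`).
#' @param entry_age_min,entry_age_max optional restriction on age at the
#'   first observed wave (the dementia analyses use `entry_age_min = 70`,
#'   the memory analyses `entry_age_max = 65`).
#' @return named list of person-period data frames, one per transition,
#'   each with `subject_id`, `interval`, the feature columns, and `event`.
#' @export
person_period <- function(cohort, groups,
                          model = c("illness_death", "ad_vad", "binary"),
                          covariates = c("age_baseline", "sex",
                                         "education_years", "apoe4"),
                          entry_age_min = NULL, entry_age_max = NULL) {
  model <- match.arg(model)
  labels <- extract_labels(groups)
  ord <- order(cohort$subject_id, cohort$wave)
  co <- cohort[ord, ]
  co$state <- map_state(co$state, model)

  states <- model_states(model)
  if (!all(co$state %in% states)) {
    stop("cohort contains states outside the '", model, "' state space: ",
         paste(setdiff(unique(co$state), states), collapse = ", "))
  }
  validate_monotone(co, states)

  first <- !duplicated(co$subject_id)
  base_age <- co$age[first][match(co$subject_id, co$subject_id[first])]
  co$age_baseline <- base_age
  keep_subj <- rep(TRUE, nrow(co))
  if (!is.null(entry_age_min)) keep_subj <- keep_subj & base_age >= entry_age_min
  if (!is.null(entry_age_max)) keep_subj <- keep_subj & base_age <= entry_age_max
  co <- co[keep_subj, ]

  cls <- labels$class[match(co$subject_id, labels$subject_id)]
  co$class <- class_code(cls)
  co <- co[!is.na(co$class), ]

  n <- nrow(co)
  if (!n) stop("no subjects left after restriction/classification")
  same <- co$subject_id[-1] == co$subject_id[-n] &
    co$wave[-1] == co$wave[-n] + 1
  i_from <- which(same)          # row of the opening wave
  from_state <- co$state[i_from]
  to_state <- co$state[i_from + 1]

  feat <- co[i_from, c("subject_id", "wave", covariates, "class"),
             drop = FALSE]
  names(feat)[names(feat) == "wave"] <- "interval"
  if ("sex" %in% covariates) feat$sex <- as.numeric(feat$sex == "male")

  specs <- msbart_transitions(model)
  out <- list()
  for (r in seq_len(nrow(specs))) {
    sel <- from_state == specs$from[r]
    tab <- feat[sel, , drop = FALSE]
    tab$event <- as.integer(to_state[sel] == specs$to[r])
    rownames(tab) <- NULL
    out[[specs$name[r]]] <- tab
  }
  attr(out, "model") <- model
  attr(out, "covariates") <- covariates
  out
}

extract_labels <- function(groups) {
  if (inherits(groups, "frs_trajectory")) groups <- groups$labels
  stopifnot(is.data.frame(groups),
            all(c("subject_id", "class") %in% names(groups)))
  groups$class <- as.character(groups$class)
  groups$class[!groups$class %in% c(class_levels, "event")] <- NA
  groups
}

validate_monotone <- function(co, states) {
  rank <- stats::setNames(seq_along(states), states)
  n <- nrow(co)
  if (n < 2) return(invisible(TRUE))
  same <- co$subject_id[-1] == co$subject_id[-n]
  prev <- co$state[-n][same]
  cur <- co$state[-1][same]
  sid <- co$subject_id[-1][same]
  bad <- (prev == "dead" & cur != "dead") |
    (prev %in% c("AD", "VaD", "dementia", "event") &
       !(cur == prev | cur == "dead"))
  if (any(bad)) {
    stop("non-monotone state sequence for subject(s): ",
         paste(unique(sid[bad])[1:min(5, length(unique(sid[bad])))],
               collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit a BART multistate survival model
#'
#' The central model of the package: the multistate model is decoupled
#' into its permitted transitions, each fitted as a separate discrete-time
#' probit-BART intensity on the person-period expansion (features: interval
#' index, baseline confounders, trajectory class), with risk sets adjusted
#' per transition. Hazards are freely time-varying because the interval
#' index is an ordinary feature of the tree ensemble.
#'
#' @inheritParams person_period
#' @param n_trees,n_burn,n_draws,k BART settings shared by every transition
#'   fit (see [bart()]).
#' @param ... further arguments passed to [bart()].
#' @return object of class `"msbart"` with the per-transition posteriors,
#'   the person-period tables, and the baseline covariate table used for
#'   standardization.
#' @seealso [standardize()], [predict.msbart()], [cuminc_nonparametric()]
#' @export
msbart <- function(cohort, groups,
                   model = c("illness_death", "ad_vad", "binary"),
                   covariates = c("age_baseline", "sex", "education_years",
                                  "apoe4"),
                   entry_age_min = NULL, entry_age_max = NULL,
                   n_trees = 50, n_burn = 250, n_draws = 1000, k = 2, ...) {
  model <- match.arg(model)
  tables <- person_period(cohort, groups, model = model,
                          covariates = covariates,
                          entry_age_min = entry_age_min,
                          entry_age_max = entry_age_max)
  feature_cols <- c("interval", covariates, "class")
  fits <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    n_events <- sum(tab$event)
    if (nrow(tab) == 0 || n_events == 0 || n_events == nrow(tab)) {
      stop("transition '", nm, "' has ", n_events, " events in ",
           nrow(tab), " at-risk rows; both classes are required ",
           "(increase the synthetic hazard or pool states)")
    }
    fits[[nm]] <- bart(tab[, feature_cols, drop = FALSE], tab$event,
                       type = "probit", n_trees = n_trees, n_burn = n_burn,
                       n_draws = n_draws, k = k, ...)
  }
  # baseline confounder table (one row per analyzed subject)
  first_tab <- tables[[1]]
  base <- first_tab[!duplicated(first_tab$subject_id),
                    c("subject_id", covariates, "class"), drop = FALSE]
  rownames(base) <- NULL
  structure(list(model = model, fits = fits, tables = tables,
                 covariates = covariates, feature_cols = feature_cols,
                 baseline = base,
                 n_waves = max(vapply(tables, function(t)
                   max(t$interval), numeric(1))) + 1,
                 n_draws = n_draws,
                 renormalized = 0L,
                 call = match.call()),
            class = "msbart")
}

#' @export
print.msbart <- function(x, ...) {
  cat("BART multistate model (", x$model, ")\n", sep = "")
  cat("  subjects:", nrow(x$baseline), " waves:", x$n_waves,
      " posterior draws:", x$n_draws, "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-18s %6d at-risk rows, %5d events\n", nm,
                nrow(x$tables[[nm]]), sum(x$tables[[nm]]$event)))
  }
  invisible(x)
}

#' @export
summary.msbart <- function(object, ...) {
  print(object)
  cat("covariates:", paste(object$covariates, collapse = ", "), "\n")
  invisible(object)
}

# Forward recursion moving occupancy mass through the transition graph.
# hazards: named list of transition -> matrix (units x intervals).
# Competing exits from one origin are renormalized within an interval only
# when a draw's summed exit probability exceeds 1 (counted in attr).
occupancy_recursion <- function(hazards, model, n_waves) {
  trans <- msbart_transitions(model)
  states <- model_states(model)
  nu <- nrow(hazards[[1]])
  K <- n_waves
  occ <- lapply(states, function(s) matrix(0, nu, K))
  names(occ) <- states
  inc <- occ
  occ[[states[1]]][, 1] <- 1
  n_renorm <- 0L
  for (k in seq_len(K - 1)) {
    out_by_state <- list()
    for (s in states) {
      idx <- which(trans$from == s)
      if (!length(idx)) next
      probs <- lapply(idx, function(r) hazards[[trans$name[r]]][, k])
      tot <- Reduce(`+`, probs)
      over <- tot > 1
      if (any(over)) {
        n_renorm <- n_renorm + sum(over)
        probs <- lapply(probs, function(p) {
          p[over] <- p[over] / tot[over]; p
        })
        tot <- pmin(tot, 1)
      }
      out_by_state[[s]] <- list(idx = idx, probs = probs, tot = tot)
    }
    for (s in states) {
      o <- out_by_state[[s]]
      occ[[s]][, k + 1] <- if (is.null(o)) occ[[s]][, k]  # absorbing
        else occ[[s]][, k] * (1 - o$tot)
      inc[[s]][, k + 1] <- inc[[s]][, k]
    }
    for (s in states) {
      o <- out_by_state[[s]]
      if (is.null(o)) next
      for (j in seq_along(o$idx)) {
        dest <- trans$to[o$idx[j]]
        flow <- occ[[s]][, k] * o$probs[[j]]
        occ[[dest]][, k + 1] <- occ[[dest]][, k + 1] + flow
        inc[[dest]][, k + 1] <- inc[[dest]][, k + 1] + flow
      }
    }
  }
  structure(list(occupancy = occ, incidence = inc, states = states),
            n_renormalized = n_renorm)
}

#' Predict occupation and cumulative-incidence curves for one profile
#'
#' Runs the forward recursion through every posterior draw's transition
#' probabilities for a single covariate profile with the trajectory group
#' held fixed, giving per-draw, per-wave probabilities of occupying each
#' state and the cumulative incidence (accumulated inflow) of each state.
#'
#' @param object an [msbart()] fit.
#' @param newdata one-row data frame with the model's baseline covariates.
#' @param group trajectory group to hold fixed
#'   (`"accelerated"`/`"average"`/`"stable"`).
#' @param ... unused.
#' @return list with `occupancy` and `incidence`: named lists of
#'   `n_draws x n_waves` matrices, one per state.
#' @export
predict.msbart <- function(object, newdata, group, ...) {
  stopifnot(nrow(newdata) == 1)
  K <- object$n_waves
  hazards <- transition_hazards(object, newdata, group)
  occupancy_recursion(hazards, object$model, K)
}

# hazard matrices (draws*rows x intervals blocks) for arbitrary pseudodata
transition_hazards <- function(object, rows, group, fits = NULL) {
  K <- object$n_waves
  covs <- object$covariates
  if (is.null(fits)) fits <- object$fits
  nr <- nrow(rows)
  X <- rows[rep(seq_len(nr), K - 1), covs, drop = FALSE]
  X$interval <- rep(seq_len(K - 1), each = nr)
  X$class <- class_code(group)
  X <- X[, object$feature_cols, drop = FALSE]
  lapply(fits, function(f) predict(f, X, type = "draws"))
}

#' Nonparametric discrete-time cumulative incidence
#'
#' Aalen-Johansen-type estimator on the person-period expansion: each
#' transition's interval hazard is the event count over the at-risk count,
#' and the same forward recursion that serves the BART fit composes the
#' state-occupation and cumulative-incidence curves. Serves as the
#' model-free benchmark for the BART intensities on covariate-free data.
#'
#' @param tables person-period tables from [person_period()].
#' @param n_waves number of waves spanned.
#' @return list with `occupancy` and `incidence` (single-row matrices per
#'   state) plus the raw hazard table.
#' @export
cuminc_nonparametric <- function(tables, n_waves) {
  model <- attr(tables, "model")
  K <- n_waves
  haz <- lapply(tables, function(tab) {
    h <- vapply(seq_len(K - 1), function(k) {
      at <- tab$interval == k
      if (!any(at)) return(0)
      mean(tab$event[at])
    }, numeric(1))
    matrix(h, 1)
  })
  res <- occupancy_recursion(haz, model, K)
  res$hazards <- haz
  res
}
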