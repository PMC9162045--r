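imputable_binary <- c("smoker", "diabetes", "bp_medication")
imputable_continuous <- c("sbp_mmHg", "bmi_kg_m2")

#' BART multiple imputation of missing risk-factor covariates
#'
#' Chained-equations scheme under the missing-at-random assumption:
#' missing entries are initialized from marginal draws of the observed
#' values, then the variables are cycled over for `n_cycles` rounds; each
#' round fits a BART model (continuous or probit per variable type) of the
#' variable on every other risk-factor covariate plus age, sex, education,
#' APOE e4, and wave, and replaces the missing entries with
#' posterior-predictive draws. After the cycles one completed table is
#' emitted per imputation. Observed cells are never altered.
#'
#' @param cohort observed cohort with `NA` in masked covariate cells.
#' @param variables ordered covariates to impute (subset of `sbp_mmHg`,
#'   `bmi_kg_m2`, `smoker`, `diabetes`, `bp_medication`).
#' @param m number of completed datasets (default 5). Downstream analyses
#'   run once per completed dataset and posterior draws are pooled by
#'   simple mixing.
#' @param n_cycles chained-equation rounds per imputation (default 5).
#' @param n_trees,n_burn,n_draws BART settings for the imputation models.
#' @param seed optional seed; each imputation advances the stream.
#' @return list of `m` completed cohort data frames.
#' @export
impute_covariates <- function(cohort,
                              variables = c(imputable_continuous,
                                            imputable_binary),
                              m = 5, n_cycles = 5,
                              n_trees = 30, n_burn = 100, n_draws = 100,
                              seed = NULL) {
  stopifnot(m >= 1, n_cycles >= 1)
  if (!is.null(seed)) set.seed(seed)
  variables <- intersect(variables,
                         c(imputable_continuous, imputable_binary))
  miss <- lapply(variables, function(v) which(is.na(cohort[[v]])))
  names(miss) <- variables
  for (v in variables) {
    if (length(miss[[v]]) == nrow(cohort)) {
      stop("variable '", v, "' has zero observed values; cannot impute")
    }
  }
  active <- variables[vapply(miss, length, integer(1)) > 0]
  if (!length(active)) {
    return(replicate(m, cohort, simplify = FALSE))
  }
  aux <- data.frame(age = cohort$age,
                    sex = as.numeric(cohort$sex == "male"),
                    education_years = cohort$education_years,
                    apoe4 = cohort$apoe4,
                    wave = cohort$wave)

  out <- vector("list", m)
  for (imp in seq_len(m)) {
    work <- cohort
    for (v in active) {  # marginal initialization
      obs <- work[[v]][-miss[[v]]]
      work[[v]][miss[[v]]] <- sample(obs, length(miss[[v]]), replace = TRUE)
    }
    for (cyc in seq_len(n_cycles)) {
      for (v in active) {
        idx <- miss[[v]]
        X <- cbind(aux, work[, setdiff(variables, v), drop = FALSE])
        fit <- bart(X[-idx, , drop = FALSE], cohort[[v]][-idx],
                    type = if (v %in% imputable_binary) "probit"
                           else "continuous",
                    n_trees = n_trees, n_burn = n_burn, n_draws = n_draws)
        pd <- predict(fit, X[idx, , drop = FALSE], type = "draws")
        d <- sample.int(nrow(pd), 1)  # one posterior draw per cycle
        if (v %in% imputable_binary) {
          work[[v]][idx] <- stats::rbinom(length(idx), 1, pd[d, ])
        } else {
          work[[v]][idx] <- pd[d, ] +
            stats::rnorm(length(idx), 0, bart_sigma(fit)[d])
        }
      }
    }
    out[[imp]] <- work
  }
  out
}
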