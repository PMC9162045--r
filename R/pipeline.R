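#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates generation, missingness, optional imputation, FRS scoring
#' and trajectory classification, the dementia multistate fit on the older
#' stratum, regression standardization with risk ratios / ARR / NNT, and
#' the memory-decline analysis on the younger stratum. Every enabled stage
#' writes its artifact into `outdir` and the run closes with a manifest
#' (seed, configuration snapshot, artifact hashes), so a run is fully
#' reproducible: the same configuration and seed give byte-identical
#' outputs.
#'
#' @param outdir output directory (created if needed).
#' @param seed global seed; stage seeds are derived from it.
#' @param n_subjects cohort size.
#' @param stages stages to run, in order, from `generate`, `missingness`,
#'   `impute`, `classify`, `dementia`, `em`. Later stages require the
#'   earlier ones.
#' @param cohort_overrides named list of [cohort_config()] overrides.
#' @param bart_settings list of BART settings (`n_trees`, `n_burn`,
#'   `n_draws`) shared by all transition fits.
#' @param std_settings list with `size` (pseudodata rows) and
#'   `n_curve_draws`.
#' @param impute_settings list with `m` and `n_cycles` for
#'   [impute_covariates()]; only used when the `impute` stage is enabled
#'   (downstream stages then use the first completed dataset for tables
#'   and pool across completions for the dementia risk ratios).
#' @param dementia_age_min entry-age floor of the dementia analysis
#'   (default 70).
#' @param em_age_max entry-age ceiling of the memory analysis
#'   (default 65).
#' @param verbose emit structured progress lines.
#' @return invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(outdir, seed = 1, n_subjects = 1244,
                         stages = c("generate", "missingness", "classify",
                                    "dementia", "em"),
                         cohort_overrides = list(),
                         bart_settings = list(n_trees = 50, n_burn = 250,
                                              n_draws = 1000),
                         std_settings = list(size = 10000,
                                             n_curve_draws = NULL),
                         impute_settings = list(m = 5, n_cycles = 5),
                         dementia_age_min = 70, em_age_max = 65,
                         verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()
  artifacts <- character()

  cfg_args <- c(list(n_subjects = n_subjects, seed = seed),
                cohort_overrides)
  config <- do.call(cohort_config, cfg_args)

  if ("generate" %in% stages) {
    res$gen <- run_stage("generate", generate_cohort(config))
    write_cohort_csv(res$gen$cohort, file.path(outdir, "cohort.csv"))
    write_cohort_csv(res$gen$truth, file.path(outdir, "truth.csv"))
    artifacts <- c(artifacts, "cohort.csv", "truth.csv")
    log_line("generate", nrow(res$gen$cohort), " rows, ",
             n_subjects, " subjects, seed ", seed)
  }
  if ("missingness" %in% stages) {
    res$observed <- run_stage("missingness",
      apply_missingness(res$gen$cohort, res$gen$truth, config))
    write_cohort_csv(res$observed, file.path(outdir, "observed.csv"))
    artifacts <- c(artifacts, "observed.csv")
    log_line("missingness", nrow(res$observed), " observed rows (",
             nrow(res$gen$cohort) - nrow(res$observed),
             " removed by dropout)")
  }
  analysis <- if (!is.null(res$observed)) res$observed else res$gen$cohort
  completed <- list(analysis)
  if ("impute" %in% stages) {
    set.seed(seed + 2L)
    completed <- run_stage("impute",
      impute_covariates(analysis, m = impute_settings$m,
                        n_cycles = impute_settings$n_cycles,
                        seed = seed + 2L))
    log_line("impute", impute_settings$m, " completed datasets")
  }
  if ("classify" %in% stages) {
    res$trajectory <- run_stage("classify", frs_trajectory(completed[[1]]))
    write_trajectory_csv(res$trajectory,
                         file.path(outdir, "trajectory_labels.csv"))
    tab1 <- trajectory_table1(completed[[1]], res$trajectory)
    utils::write.csv(tab1, file.path(outdir, "table1.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, "trajectory_labels.csv", "table1.csv")
    cls <- table(res$trajectory$labels$class)
    log_line("classify", paste(names(cls), cls, sep = "=", collapse = " "))
  }
  if ("dementia" %in% stages) {
    res$dementia <- run_stage("dementia", {
      set.seed(seed + 3L)
      fit <- msbart(completed[[1]], res$trajectory,
                    model = "illness_death",
                    entry_age_min = dementia_age_min,
                    n_trees = bart_settings$n_trees,
                    n_burn = bart_settings$n_burn,
                    n_draws = bart_settings$n_draws)
      curves <- lapply(c(accelerated = "accelerated", average = "average",
                         stable = "stable"), function(g) {
        set.seed(seed + 4L)
        standardize(fit, g, size = std_settings$size,
                    n_curve_draws = std_settings$n_curve_draws)
      })
      rr_as <- risk_ratio(curves$accelerated, curves$stable)
      rr_vs <- risk_ratio(curves$average, curves$stable)
      write_rr_csv(rr_as,
                   file.path(outdir, "rr_dementia_accelerated_vs_stable.csv"))
      write_rr_csv(rr_vs,
                   file.path(outdir, "rr_dementia_average_vs_stable.csv"))
      eff <- list(
        average_vs_accelerated = arr_nnt(curves$average, curves$accelerated),
        stable_vs_accelerated = arr_nnt(curves$stable, curves$accelerated))
      jsonlite::write_json(eff, file.path(outdir, "arr_nnt.json"),
                           auto_unbox = TRUE, digits = NA)
      # APOE e4 subgroup standardization: condition the pseudodata
      rr_apoe <- lapply(c(carrier = 1, noncarrier = 0), function(a) {
        cs <- lapply(c("accelerated", "stable"), function(g) {
          set.seed(seed + 5L)
          standardize(fit, g, size = std_settings$size,
                      n_curve_draws = std_settings$n_curve_draws,
                      condition = list(apoe4 = a))
        })
        risk_ratio(cs[[1]], cs[[2]])
      })
      write_rr_csv(rr_apoe$carrier,
                   file.path(outdir, "rr_dementia_apoe4_carrier.csv"))
      write_rr_csv(rr_apoe$noncarrier,
                   file.path(outdir, "rr_dementia_apoe4_noncarrier.csv"))
      list(fit = fit, curves = curves, rr_accelerated_vs_stable = rr_as,
           rr_average_vs_stable = rr_vs, rr_apoe = rr_apoe, effects = eff)
    })
    artifacts <- c(artifacts, "rr_dementia_accelerated_vs_stable.csv",
                   "rr_dementia_average_vs_stable.csv", "arr_nnt.json",
                   "rr_dementia_apoe4_carrier.csv",
                   "rr_dementia_apoe4_noncarrier.csv")
    for (nm in names(res$dementia$fit$tables)) {
      log_line("dementia", nm, ": ",
               sum(res$dementia$fit$tables[[nm]]$event), " events")
    }
  }
  if ("em" %in% stages) {
    res$em <- run_stage("em", {
      set.seed(seed + 6L)
      events <- em_decline_events(analysis, max_entry_age = em_age_max)
      write_cohort_csv(events, file.path(outdir, "em_decline_events.csv"))
      dc <- decline_cohort(analysis, events)
      fit <- msbart(dc, res$trajectory, model = "binary",
                    n_trees = bart_settings$n_trees,
                    n_burn = bart_settings$n_burn,
                    n_draws = bart_settings$n_draws)
      cs <- lapply(c("accelerated", "stable"), function(g) {
        set.seed(seed + 7L)
        standardize(fit, g, size = std_settings$size,
                    n_curve_draws = std_settings$n_curve_draws)
      })
      rr <- risk_ratio(cs[[1]], cs[[2]])
      write_rr_csv(rr, file.path(outdir, "rr_em_accelerated_vs_stable.csv"))
      list(events = events, fit = fit, rr = rr)
    })
    artifacts <- c(artifacts, "em_decline_events.csv",
                   "rr_em_accelerated_vs_stable.csv")
    log_line("em", sum(res$em$events$event), " decline events among ",
             nrow(res$em$events), " evaluable subjects")
  }

  manifest <- list(
    package = "cvdtraj",
    seed = seed,
    n_subjects = n_subjects,
    stages = stages,
    dementia_age_min = dementia_age_min,
    em_age_max = em_age_max,
    bart_settings = bart_settings,
    std_settings = std_settings,
    cohort_overrides = cohort_overrides,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, artifacts))), artifacts)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

trajectory_table1 <- function(cohort, trajectory) {
  labels <- trajectory$labels
  base <- cohort[!duplicated(cohort$subject_id), ]
  cls <- labels$class[match(base$subject_id, labels$subject_id)]
  grp <- split(base, cls)
  do.call(rbind, lapply(names(grp), function(g) {
    b <- grp[[g]]
    if (!nrow(b)) return(NULL)
    data.frame(group = g,
               n = nrow(b),
               age_mean = mean(b$age),
               pct_female = 100 * mean(b$sex == "female"),
               education_mean = mean(b$education_years),
               pct_apoe4 = 100 * mean(b$apoe4),
               sbp_mean = mean(b$sbp_mmHg, na.rm = TRUE),
               bmi_mean = mean(b$bmi_kg_m2, na.rm = TRUE),
               pct_smoker = 100 * mean(b$smoker, na.rm = TRUE),
               pct_diabetes = 100 * mean(b$diabetes, na.rm = TRUE))
  }))
}
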