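#' Per-subject FRS slope by ordinary least squares
#'
#' Fits, for every subject with at least `min_waves` usable pre-diagnosis
#' risk values, the OLS slope of 10-year risk against years since the
#' subject's first observed wave. Subjects below the minimum are kept with
#' an `NA` slope (unclassified), never dropped.
#'
#' @param series FRS series from [build_frs_series()].
#' @param min_waves minimum usable risk values (default 2).
#' @return data frame `subject_id`, `n_waves_used`, `raw_slope`
#'   (risk units per year), `pattern` (last wave with a usable value),
#'   `baseline_frs`, `baseline_age_years` (years column at first usable
#'   wave is 0 by construction, so baseline age is recovered upstream).
#' @export
fit_frs_slopes <- function(series, min_waves = 2) {
  stopifnot(min_waves >= 2)
  sp <- split(series, series$subject_id)
  out <- lapply(sp, function(d) {
    d <- d[order(d$wave), ]
    slope <- NA_real_
    if (nrow(d) >= min_waves) {
      xc <- d$years - mean(d$years)
      slope <- sum(xc * d$frs) / sum(xc^2)
    }
    data.frame(subject_id = d$subject_id[1],
               n_waves_used = nrow(d),
               raw_slope = slope,
               pattern = max(d$wave),
               baseline_frs = d$frs[1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Residualize slopes on baseline age and baseline risk
#'
#' Operationalizes classification "in relation to age and individual
#' baseline risk" as cross-subject residualization: raw slopes are
#' regressed on baseline age and baseline FRS, and the residuals carry the
#' trajectory information with the mechanical age- and level-dependence of
#' risk growth removed.
#'
#' @param slopes output of [fit_frs_slopes()].
#' @param baseline_age named (by subject id) or aligned vector of ages at
#'   each subject's first usable wave.
#' @return `slopes` with an `adjusted_slope` column (`NA` where the raw
#'   slope is `NA`).
#' @export
adjust_slopes <- function(slopes, baseline_age) {
  if (!is.null(names(baseline_age))) {
    baseline_age <- baseline_age[as.character(slopes$subject_id)]
  }
  slopes$baseline_age <- as.numeric(baseline_age)
  ok <- !is.na(slopes$raw_slope)
  fit <- stats::lm(raw_slope ~ baseline_age + baseline_frs,
                   data = slopes[ok, ])
  slopes$adjusted_slope <- NA_real_
  slopes$adjusted_slope[ok] <- stats::residuals(fit)
  slopes
}

#' Pattern-mixture population moments of the slope distribution
#'
#' Accounts for nonignorable dropout by stratifying subjects on their
#' dropout pattern (last observed wave), estimating the slope mean and
#' variance within each pattern, and recombining with pattern frequencies
#' as weights: the population mean is the frequency-weighted pattern mean
#' and the population variance follows the law of total variance (weighted
#' within-pattern variance plus between-pattern dispersion). With a single
#' pattern this reduces exactly to the ordinary mean and SD.
#'
#' @param slopes data frame with `adjusted_slope` (or `raw_slope` if no
#'   adjustment was run) and `pattern` columns; `NA` slopes are excluded.
#' @param value column to use, default `"adjusted_slope"`.
#' @return list with `mean`, `sd`, and the per-pattern table.
#' @export
pattern_mixture_moments <- function(slopes, value = "adjusted_slope") {
  x <- slopes[[value]]
  keep <- !is.na(x)
  if (!any(keep)) stop("no classifiable subjects: all slopes are missing")
  x <- x[keep]
  pat <- slopes$pattern[keep]
  tab <- do.call(rbind, lapply(split(x, pat), function(v) {
    data.frame(n = length(v), mean = mean(v),
               var = if (length(v) > 1) stats::var(v) else 0)
  }))
  tab$pattern <- as.integer(rownames(tab))
  w <- tab$n / sum(tab$n)
  m <- sum(w * tab$mean)
  v <- sum(w * tab$var) + sum(w * (tab$mean - m)^2)
  list(mean = m, sd = sqrt(v), patterns = tab[, c("pattern", "n", "mean",
                                                  "var")])
}

#' Classify trajectories as accelerated / average / stable
#'
#' Applies the 1-SD rule to adjusted slopes: strictly above
#' `mean + sd_threshold * SD` is accelerated, strictly below
#' `mean - sd_threshold * SD` is stable, everything else (including the
#' boundaries) is average. Subjects without a usable slope are
#' `unclassified`.
#'
#' @param slopes data frame with `adjusted_slope`.
#' @param moments population moments from [pattern_mixture_moments()].
#' @param sd_threshold threshold in population SDs (default 1).
#' @return `slopes` with a `class` factor
#'   (`accelerated`/`average`/`stable`/`unclassified`).
#' @export
classify_trajectories <- function(slopes, moments, sd_threshold = 1) {
  stopifnot(sd_threshold > 0)
  if (moments$sd <= 0) {
    message("zero slope dispersion; every classified subject is 'average'")
  }
  up <- moments$mean + sd_threshold * moments$sd
  lo <- moments$mean - sd_threshold * moments$sd
  x <- slopes$adjusted_slope
  cls <- ifelse(is.na(x), "unclassified",
                ifelse(x > up, "accelerated",
                       ifelse(x < lo, "stable", "average")))
  slopes$class <- factor(cls, levels = c(class_levels, "unclassified"))
  slopes
}

#' Fit FRS trajectory groups for a cohort
#'
#' End-to-end wrapper: builds per-wave pre-diagnosis FRS series, fits
#' per-subject OLS slopes, residualizes on baseline age and baseline risk,
#' estimates pattern-mixture population moments under the monotone-dropout
#' pattern (last observed wave), and classifies subjects with the
#' `sd_threshold`-SD rule.
#'
#' @param cohort observed cohort data frame.
#' @param sd_threshold classification threshold in SDs (default 1).
#' @param min_waves minimum usable FRS values to classify (default 2).
#' @param constants risk-function constants, see [frs_constants()].
#' @return object of class `"frs_trajectory"`: the per-subject label table
#'   plus the population moments.
#' @export
frs_trajectory <- function(cohort, sd_threshold = 1, min_waves = 2,
                           constants = frs_constants()) {
  series <- build_frs_series(cohort, constants = constants)
  slopes <- fit_frs_slopes(series, min_waves = min_waves)
  base_age <- tapply(cohort$age, cohort$subject_id, min)
  slopes <- adjust_slopes(slopes, base_age)
  moments <- pattern_mixture_moments(slopes)
  labels <- classify_trajectories(slopes, moments,
                                  sd_threshold = sd_threshold)
  # subjects present in the cohort but without any usable FRS series
  missing_ids <- setdiff(unique(cohort$subject_id), labels$subject_id)
  if (length(missing_ids)) {
    pad <- labels[rep(NA_integer_, length(missing_ids)), ]
    pad$subject_id <- missing_ids
    pad$class <- factor("unclassified",
                        levels = levels(labels$class))
    labels <- rbind(labels, pad)
  }
  labels <- labels[order(labels$subject_id), ]
  rownames(labels) <- NULL
  structure(list(labels = labels, moments = moments,
                 sd_threshold = sd_threshold, min_waves = min_waves),
            class = "frs_trajectory")
}

#' @export
print.frs_trajectory <- function(x, ...) {
  cat("FRS trajectory classification\n")
  cat("  population slope mean:", signif(x$moments$mean, 4),
      " SD:", signif(x$moments$sd, 4),
      " (pattern-mixture, threshold", x$sd_threshold, "SD)\n")
  print(table(x$labels$class))
  invisible(x)
}

#' @export
summary.frs_trajectory <- function(object, ...) {
  tab <- table(object$labels$class)
  cat("FRS trajectory groups\n")
  print(round(100 * tab / sum(tab), 1))
  invisible(list(counts = tab, moments = object$moments))
}

#' Per-subject trajectory label CSV
#' @param x an [frs_trajectory()] object.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "frs_trajectory"))
  cols <- c("subject_id", "raw_slope", "adjusted_slope", "pattern", "class")
  utils::write.csv(x$labels[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
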