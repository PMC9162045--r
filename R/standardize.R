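#' Sample pseudodata from the empirical baseline-confounder distribution
#'
#' Resamples rows with replacement from the observed joint distribution of
#' the baseline confounders, preserving their dependence. An optional
#' condition restricts the source rows (used for subgroup standardization:
#' standardize over the observed distribution conditioning on a covariate).
#'
#' @param baseline per-subject baseline covariate data frame.
#' @param size number of pseudodata rows.
#' @param condition optional named list, e.g. `list(apoe4 = 1)`; only
#'   source rows matching every entry are resampled.
#' @return data frame of `size` resampled rows.
#' @export
sample_pseudodata <- function(baseline, size = 10000, condition = NULL) {
  src <- baseline
  if (!is.null(condition)) {
    for (nm in names(condition)) {
      src <- src[src[[nm]] == condition[[nm]], , drop = FALSE]
    }
    if (!nrow(src)) {
      stop("no source rows satisfy the condition: ",
           paste(names(condition), unlist(condition), sep = "=",
                 collapse = ", "))
    }
  }
  out <- src[sample.int(nrow(src), size, replace = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regression standardization of a BART multistate model
#'
#' @description
#' Bayesian g-computation: for each retained posterior draw, every
#' pseudodata row's trajectory group is set to the fixed `group`, the
#' forward recursion produces that row's occupation and cumulative
#' incidence curves under the draw's transition probabilities, and the
#' average over rows is the draw's standardized curve — a marginal
#' (confounder-standardized) incidence trajectory whose spread over draws
#' carries the posterior uncertainty.
#'
#' @param x an [msbart()] fit.
#' @param ... passed to methods.
#' @export
standardize <- function(x, ...) UseMethod("standardize")

#' @rdname standardize
#' @param group trajectory group held fixed for all pseudodata rows.
#' @param size pseudodata rows resampled from the fit's baseline table.
#' @param n_curve_draws posterior draws retained for the curves (evenly
#'   thinned from the fit); default all draws.
#' @param condition optional subgroup condition, see [sample_pseudodata()].
#' @param chunk pseudodata rows processed per prediction block (memory
#'   control only; no effect on results).
#' @return object of class `"std_curves"`: per-state `draws x waves`
#'   matrices of standardized cumulative incidence and occupancy.
#' @export
standardize.msbart <- function(x, group, size = 10000,
                               n_curve_draws = NULL, condition = NULL,
                               chunk = 2000, ...) {
  K <- x$n_waves
  states <- model_states(x$model)
  fits <- x$fits
  nd <- x$n_draws
  if (!is.null(n_curve_draws) && n_curve_draws < nd) {
    sel <- unique(round(seq(1, nd, length.out = n_curve_draws)))
    fits <- lapply(fits, subset_bart_draws, sel)
    nd <- length(sel)
  }
  pseudo <- sample_pseudodata(x$baseline, size, condition)
  inc <- lapply(states, function(s) matrix(0, nd, K))
  names(inc) <- states
  occ <- inc
  done <- 0
  while (done < size) {
    take <- min(chunk, size - done)
    rows <- pseudo[done + seq_len(take), , drop = FALSE]
    haz_flat <- transition_hazards(x, rows, group, fits = fits)
    for (d in seq_len(nd)) {
      haz_d <- lapply(haz_flat, function(h) matrix(h[d, ], take, K - 1))
      res <- occupancy_recursion(haz_d, x$model, K)
      w <- take / size
      for (s in states) {
        inc[[s]][d, ] <- inc[[s]][d, ] + w * colMeans(res$incidence[[s]])
        occ[[s]][d, ] <- occ[[s]][d, ] + w * colMeans(res$occupancy[[s]])
      }
    }
    done <- done + take
  }
  structure(list(incidence = inc, occupancy = occ, group = group,
                 model = x$model, states = states, n_waves = K,
                 n_draws = nd, size = size, condition = condition),
            class = "std_curves")
}

subset_bart_draws <- function(fit, sel) {
  keep <- fit$forest[, "draw"] %in% sel
  fo <- fit$forest[keep, , drop = FALSE]
  fo[, "draw"] <- match(fo[, "draw"], sel)
  fit$forest <- fo
  fit$sigma <- fit$sigma[sel]
  if (!is.null(fit$trainfit)) {
    fit$trainfit <- fit$trainfit[sel, , drop = FALSE]
  }
  fit$n_draws <- length(sel)
  fit
}

#' @export
print.std_curves <- function(x, ...) {
  cat("standardized curves (", x$model, "), group = ", x$group,
      ", ", x$n_draws, " draws over ", x$size, " pseudodata rows\n",
      sep = "")
  ev <- setdiff(x$states, "healthy")[1]
  cat("posterior-mean cumulative incidence of ", ev, " by wave:\n", sep = "")
  print(round(colMeans(x$incidence[[ev]]), 4))
  invisible(x)
}

default_event_state <- function(model) {
  switch(model, illness_death = "dementia", binary = "event",
         ad_vad = stop("state must be given explicitly for the ad_vad model"))
}

#' Standardized risk ratio over waves
#'
#' Contrasts two standardized curves draw by draw:
#' `RR(wave) = incidence_num(wave) / incidence_den(wave)`, summarized by
#' the posterior mean and the equal-tailed credible interval. Waves where
#' a draw's denominator incidence is zero yield an undefined ratio for
#' that draw and are reported as missing, never as infinity.
#'
#' @param num,den `std_curves` objects on the same wave grid and draw
#'   count, paired by draw (fit them from the same [msbart()] object).
#' @param state event state to contrast; defaults to the model's dementia
#'   or decline state.
#' @param ci credible level (equal-tailed), default 0.95.
#' @return object of class `"effect_summary"`: data frame `wave`,
#'   `rr_mean`, `ci_lower`, `ci_upper`, with the draw matrix in
#'   `attr(, "draws")`.
#' @export
risk_ratio <- function(num, den, state = NULL, ci = 0.95) {
  stopifnot(inherits(num, "std_curves"), inherits(den, "std_curves"),
            num$n_waves == den$n_waves, num$n_draws == den$n_draws)
  if (is.null(state)) state <- default_event_state(num$model)
  a <- num$incidence[[state]]
  b <- den$incidence[[state]]
  rr <- a / b
  rr[b == 0] <- NA
  alpha <- (1 - ci) / 2
  summ <- data.frame(
    wave = seq_len(ncol(rr)),
    rr_mean = colMeans(rr),
    ci_lower = apply(rr, 2, function(v)
      if (all(is.na(v))) NA_real_ else stats::quantile(v, alpha,
                                                       na.rm = TRUE)),
    ci_upper = apply(rr, 2, function(v)
      if (all(is.na(v))) NA_real_ else stats::quantile(v, 1 - alpha,
                                                       na.rm = TRUE)))
  rownames(summ) <- NULL
  structure(summ, draws = rr, state = state, ci = ci,
            contrast = paste(num$group, "vs", den$group),
            class = c("effect_summary", "data.frame"))
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("standardized risk ratios,", attr(x, "contrast"),
      "(", attr(x, "state"), "), ",
      100 * attr(x, "ci"), "% equal-tailed CrI\n")
  print.data.frame(round(as.data.frame(x), 3))
  invisible(x)
}

#' Absolute risk reduction and number needed to treat
#'
#' `ARR = posterior-mean incidence(higher) - posterior-mean
#' incidence(lower)` at the reference wave, and `NNT` is the nearest
#' integer to `1 / ARR`. A nonpositive ARR reports `NNT = NA`
#' (not applicable).
#'
#' @param lower,higher `std_curves` for the lower- and higher-risk groups.
#' @param state event state, defaulting as in [risk_ratio()].
#' @param wave reference wave; default the final wave.
#' @return list with `arr`, `nnt`, `wave`, `state`, `contrast`.
#' @export
arr_nnt <- function(lower, higher, state = NULL, wave = NULL) {
  stopifnot(inherits(lower, "std_curves"), inherits(higher, "std_curves"))
  if (is.null(state)) state <- default_event_state(lower$model)
  if (is.null(wave)) wave <- lower$n_waves
  arr <- mean(higher$incidence[[state]][, wave]) -
    mean(lower$incidence[[state]][, wave])
  list(arr = arr, nnt = nnt_from_arr(arr), wave = wave, state = state,
       contrast = paste(higher$group, "vs", lower$group))
}

#' Number needed to treat from an absolute risk reduction
#'
#' Nearest integer to the reciprocal ARR; `NA` when the ARR is not
#' positive.
#'
#' @param arr absolute risk reduction on the probability scale.
#' @return integer NNT or `NA`.
#' @examples
#' nnt_from_arr(0.027)  # 37
#' nnt_from_arr(0.025)  # 40
#' @export
nnt_from_arr <- function(arr) {
  ifelse(is.na(arr) | arr <= 0, NA_integer_, as.integer(round(1 / arr)))
}

#' Incidence proportion as a percentage
#' @param events event count.
#' @param n analyzed sample size.
#' @return `100 * events / n`.
#' @export
incidence_percent <- function(events, n) 100 * events / n

#' Write a tidy risk-ratio table
#' @param x an `effect_summary`.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_rr_csv <- function(x, path) {
  df <- as.data.frame(x)
  df$contrast <- attr(x, "contrast")
  df$state <- attr(x, "state")
  utils::write.csv(df[, c("contrast", "state", "wave", "rr_mean",
                          "ci_lower", "ci_upper")],
                   path, row.names = FALSE)
  invisible(path)
}
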