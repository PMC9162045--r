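#' Fit a Bayesian additive regression trees model
#'
#' Self-contained sum-of-trees sampler with the canonical regularization
#' prior: split probability \eqn{\alpha (1+d)^{-\beta}} at depth \eqn{d},
#' conjugate normal leaves scaled by `k`, and a scaled inverse chi-squared
#' error-variance prior for continuous outcomes. Binary outcomes use probit
#' latent-variable augmentation, so predicted probabilities are mapped
#' through the standard normal CDF and lie strictly inside (0, 1). Trees are
#' updated by backfitting MCMC with grow, prune, and change proposals
#' accepted via Metropolis-Hastings on the integrated leaf likelihood.
#'
#' All randomness flows through R's RNG: a call preceded by `set.seed()` is
#' exactly reproducible given the same data and settings.
#'
#' @param x numeric matrix or data frame of features (logicals are coerced;
#'   factors are not accepted — code them numerically first).
#' @param y numeric outcome; a 0/1 vector selects probit mode under
#'   `type = "auto"`.
#' @param type outcome model: `"continuous"`, `"probit"`, or `"auto"`.
#' @param n_trees number of trees in the ensemble.
#' @param n_burn,n_draws burn-in and retained posterior draws.
#' @param base,power tree prior: split probability `base * (1+depth)^-power`.
#' @param k leaf shrinkage; larger values shrink individual tree
#'   contributions harder.
#' @param nu,q error-variance prior degrees of freedom and the quantile at
#'   which the naive estimate of the outcome SD is placed (continuous only).
#' @param move_probs length-3 proposal mix over grow/prune/change.
#' @param n_cutpoints maximum cutpoints per continuous feature
#'   (quantile-based grid; binary features split once).
#' @param min_node smallest number of training rows allowed in a leaf.
#'
#' @return An object of class `"bart"` holding the stored forest draws,
#'   error-SD draws (continuous), in-sample fit draws, and the scaling
#'   metadata needed for prediction.
#' @seealso [predict.bart()], [bart_trace()], [bart_write_json()]
#' @export
bart <- function(x, y, type = c("auto", "continuous", "probit"),
                 n_trees = 50, n_burn = 250, n_draws = 1000,
                 base = 0.95, power = 2, k = 2,
                 nu = 3, q = 0.90,
                 move_probs = c(grow = 0.25, prune = 0.25, change = 0.50),
                 n_cutpoints = 100, min_node = 5) {
  type <- match.arg(type)
  X <- as_feature_matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(x)")
  if (anyNA(X)) stop("features contain missing values; impute upstream")
  if (anyNA(y)) stop("outcome contains missing values")
  if (nrow(X) < 10) stop("need at least 10 rows to fit")
  if (type == "auto") {
    type <- if (all(y %in% c(0, 1))) "probit" else "continuous"
  }
  move_probs <- move_probs / sum(move_probs)

  if (type == "probit") {
    if (!all(y %in% c(0, 1))) stop("probit outcome must be 0/1")
    if (length(unique(y)) < 2L) {
      stop("outcome has a single class; probit BART needs both classes")
    }
    offset <- stats::qnorm(mean(y))
    tau2 <- (3 / (k * sqrt(n_trees)))^2
    res <- bart_mcmc_cpp(X, y, 1L, n_trees, n_burn, n_draws,
                         base, power, tau2, nu, 1, 1,
                         move_probs[[1]], move_probs[[2]],
                         n_cutpoints, min_node, offset)
    scale <- list(offset = offset)
  } else {
    ymin <- min(y); ymax <- max(y)
    if (ymax == ymin) {
      fit <- structure(list(type = "constant", constant = ymin,
                            n_draws = n_draws,
                            feature_names = colnames(X), call = match.call()),
                       class = "bart")
      message("constant outcome; returning degenerate posterior")
      return(fit)
    }
    ys <- (y - ymin) / (ymax - ymin) - 0.5
    tau2 <- (0.5 / (k * sqrt(n_trees)))^2
    sighat <- stats::sd(ys)
    lambda <- sighat^2 * stats::qchisq(1 - q, nu) / nu
    res <- bart_mcmc_cpp(X, ys, 0L, n_trees, n_burn, n_draws,
                         base, power, tau2, nu, lambda, sighat^2,
                         move_probs[[1]], move_probs[[2]],
                         n_cutpoints, min_node, 0)
    scale <- list(ymin = ymin, ymax = ymax)
  }

  structure(list(
    type = type,
    forest = res$forest,
    sigma = res$sigma,
    trainfit = res$trainfit,
    scale = scale,
    n_trees = n_trees, n_draws = n_draws,
    feature_names = colnames(X),
    settings = list(base = base, power = power, k = k, nu = nu, q = q,
                    n_burn = n_burn, move_probs = move_probs,
                    n_cutpoints = n_cutpoints, min_node = min_node),
    call = match.call()
  ), class = "bart")
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    bad <- vapply(x, function(col) is.factor(col) || is.character(col),
                  logical(1))
    if (any(bad)) {
      stop("non-numeric feature column(s): ",
           paste(names(x)[bad], collapse = ", "))
    }
    x <- vapply(x, as.numeric, numeric(nrow(x)))
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Predict from a fitted BART model
#'
#' @param object a [bart()] fit.
#' @param newdata feature matrix/data frame with the training columns.
#' @param type `"draws"` returns the full `n_draws` x `nrow(newdata)`
#'   prediction matrix on the outcome scale (probabilities for probit);
#'   `"mean"` returns posterior-mean predictions; `"ppd"` (continuous only)
#'   returns posterior-predictive draws including observation noise.
#' @param ... unused.
#' @return matrix of draws or a numeric vector of posterior means.
#' @export
predict.bart <- function(object, newdata,
                         type = c("draws", "mean", "ppd"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (object$type == "constant") {
    out <- matrix(object$constant, object$n_draws, nrow(X))
    return(if (type == "mean") colMeans(out) else out)
  }
  missing <- setdiff(object$feature_names, colnames(X))
  extra <- setdiff(colnames(X), object$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] unexpected: [",
         paste(extra, collapse = ", "), "]")
  }
  X <- X[, object$feature_names, drop = FALSE]
  G <- forest_predict_cpp(object$forest, X, object$n_draws)
  out <- switch(object$type,
    probit = stats::pnorm(G + object$scale$offset),
    continuous = (G + 0.5) * (object$scale$ymax - object$scale$ymin) +
      object$scale$ymin)
  if (type == "ppd") {
    if (object$type != "continuous") stop("ppd draws are for continuous fits")
    out <- out + matrix(stats::rnorm(length(out)), nrow(out)) *
      bart_sigma(object)
  }
  if (type == "mean") colMeans(out) else out
}

#' Error-SD draws on the outcome scale (continuous fits)
#' @param object a [bart()] fit.
#' @return numeric vector of length `n_draws`.
#' @export
bart_sigma <- function(object) {
  stopifnot(inherits(object, "bart"))
  if (object$type != "continuous") stop("sigma is defined for continuous fits")
  object$sigma * (object$scale$ymax - object$scale$ymin)
}

#' Extract an MCMC trace from a BART fit
#'
#' Returns the per-draw trace of a scalar summary, for convergence and
#' mixing checks. `what = "sigma"` traces the error SD (continuous fits);
#' `what = "mean_fit"` traces the mean in-sample prediction; `fn` traces any
#' user summary of the in-sample prediction vector of each draw.
#'
#' @param object a [bart()] fit.
#' @param what `"sigma"` or `"mean_fit"`.
#' @param fn optional function applied to each draw's in-sample fit vector
#'   (outcome scale); overrides `what`.
#' @return numeric vector with one entry per retained draw.
#' @export
bart_trace <- function(object, what = c("sigma", "mean_fit"), fn = NULL) {
  stopifnot(inherits(object, "bart"))
  fits <- train_draws(object)
  if (!is.null(fn)) return(apply(fits, 1, fn))
  what <- match.arg(what)
  if (what == "sigma") return(bart_sigma(object))
  rowMeans(fits)
}

train_draws <- function(object) {
  G <- object$trainfit
  switch(object$type,
    probit = stats::pnorm(G + object$scale$offset),
    continuous = (G + 0.5) * (object$scale$ymax - object$scale$ymin) +
      object$scale$ymin)
}

#' @export
print.bart <- function(x, ...) {
  cat("BART fit (", x$type, " outcome)\n", sep = "")
  if (x$type == "constant") {
    cat("  degenerate posterior at constant outcome", x$constant, "\n")
    return(invisible(x))
  }
  cat("  trees:", x$n_trees, " draws:", x$n_draws,
      " burn-in:", x$settings$n_burn, "\n")
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  if (x$type == "continuous") {
    cat("  posterior mean error SD:",
        signif(mean(bart_sigma(x)), 4), "\n")
  }
  invisible(x)
}

#' Serialize a BART posterior to JSON
#'
#' The stored container holds the forest node table, sigma draws, and the
#' scaling metadata at full floating-point precision, so predictions from a
#' reloaded posterior are bit-identical to the in-memory ones.
#'
#' @param object a [bart()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
bart_write_json <- function(object, path) {
  stopifnot(inherits(object, "bart"))
  payload <- list(
    container = "cvdtraj-bart-posterior",
    version = 1L,
    type = object$type,
    n_trees = object$n_trees,
    n_draws = object$n_draws,
    feature_names = object$feature_names,
    scale = lapply(object$scale, function(v) sprintf("%.17g", v)),
    settings = object$settings,
    sigma = sprintf("%.17g", object$sigma),
    forest = list(dim = dim(object$forest),
                  colnames = colnames(object$forest),
                  # doubles as %.17g strings: exact decimal round-trip
                  data = sprintf("%.17g", as.numeric(object$forest)))
  )
  if (object$type == "constant") payload$constant <- object$constant
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Load a BART posterior serialized by [bart_write_json()]
#' @param path file written by [bart_write_json()].
#' @return an object of class `"bart"` (without in-sample fit draws).
#' @export
bart_read_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "cvdtraj-bart-posterior")) {
    stop("not a cvdtraj BART posterior container: ", path)
  }
  forest <- matrix(as.numeric(p$forest$data),
                   p$forest$dim[1], p$forest$dim[2])
  colnames(forest) <- p$forest$colnames
  structure(list(
    type = p$type, forest = forest, sigma = as.numeric(p$sigma),
    trainfit = NULL,
    scale = lapply(p$scale, as.numeric),
    n_trees = p$n_trees, n_draws = p$n_draws,
    constant = p$constant,
    feature_names = p$feature_names, settings = p$settings,
    call = NULL
  ), class = "bart")
}
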