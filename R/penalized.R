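#' Seeded cross-validation fold assignment
#'
#' Folds are a uniform random partition; for survival outcomes the partition
#' is stratified on event status so that every fold contains at least one
#' event whenever the number of events is at least `nfolds`.
#'
#' @param n Number of samples.
#' @param nfolds Number of folds (2..n).
#' @param seed Integer seed; identical seeds give identical folds.
#' @param status Optional event indicator for event-stratified folds.
#' @return Integer vector of fold labels in `1..nfolds`.
#' @export
make_folds <- function(n, nfolds, seed, status = NULL) {
  pl_assert(is_count(nfolds) && nfolds >= 2 && nfolds <= n, "invalid_folds",
            "nfolds must lie in 2..n")
  withr::with_seed(as.integer(seed), {
    if (is.null(status)) {
      foldid <- sample(rep_len(seq_len(nfolds), n))
    } else {
      pl_assert(length(status) == n, "length_mismatch",
                "status must have length n")
      if (sum(status == 1) < nfolds)
        pl_error("degenerate_fold",
                 "fewer events than folds: every fold needs >= 1 event")
      foldid <- integer(n)
      ev <- which(status == 1)
      ce <- which(status == 0)
      foldid[ev] <- sample(rep_len(seq_len(nfolds), length(ev)))
      if (length(ce))
        foldid[ce] <- sample(rep_len(seq_len(nfolds), length(ce)))
    }
    foldid
  })
}

# glmnet needs >= 2 columns; pad single-feature blocks with an excluded
# zero column whose coefficient is identically 0
pad_matrix <- function(x) {
  if (ncol(x) >= 2L) return(list(x = x, exclude = integer(0)))
  xp <- cbind(x, `..pad..` = 0)
  list(x = xp, exclude = 2L)
}

new_lasso_path <- function(lambda, beta, a0, df, family, penalized,
                           glmnet_fit = NULL, pad = FALSE) {
  structure(list(lambda = lambda, beta = beta, a0 = a0, df = df,
                 family = family, penalized = penalized,
                 glmnet_fit = glmnet_fit, pad = pad),
            class = "lasso_path")
}

#' Fit an L1 penalty path for one covariate block with a fixed offset
#'
#' Minimises the family loss (squared error, logistic deviance, or Cox
#' partial likelihood) plus \eqn{\lambda \sum_j |\beta_j|} over a decreasing
#' grid of penalties, the supplied offset entering the linear predictor with
#' coefficient fixed to 1. With `penalized = FALSE` a single unpenalized fit
#' (\eqn{\lambda = 0}, requires `p < n`) is returned instead, via ordinary
#' linear / logistic / Cox regression.
#'
#' Features are standardized to unit variance internally (disable with
#' `standardize = FALSE`); coefficients are always reported on the original
#' covariate scale.
#'
#' @param x Numeric matrix (samples x block features).
#' @param outcome A `pl_outcome`.
#' @param offset Per-sample offset (default all zero).
#' @param penalized Logical.
#' @param standardize Logical, see above.
#' @param ... Further arguments passed to [glmnet::glmnet()].
#' @return A `lasso_path`: `lambda` (decreasing; at the largest value all
#'   penalized coefficients are exactly zero), `beta` (p x n_lambda),
#'   `a0` (intercepts; `NULL` for survival), `df` (non-zero counts).
#' @export
fit_path <- function(x, outcome, offset = NULL, penalized = TRUE,
                     standardize = TRUE, ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  pl_assert(n_samples(outcome) == n, "length_mismatch",
            "outcome length must equal nrow(x)")
  offset <- offset %||% rep(0, n)
  pl_assert(length(offset) == n && all(is.finite(offset)), "invalid_offset",
            "offset must be a finite vector of length n")
  fam <- as_glmnet_family(outcome$family)
  if (!penalized) {
    pl_assert(ncol(x) < n, "block_too_large",
              "unpenalized fit requires p < n in the block")
    return(fit_unpenalized(x, outcome, offset))
  }
  pm <- pad_matrix(x)
  fit <- glmnet::glmnet(pm$x, as_glmnet_y(outcome), family = fam,
                        offset = offset, standardize = standardize,
                        exclude = pm$exclude, ...)
  beta <- as.matrix(fit$beta)
  if (length(pm$exclude)) beta <- beta[1L, , drop = FALSE]
  rownames(beta) <- colnames(x)
  a0 <- if (fam == "cox") NULL else as.numeric(fit$a0)
  df <- colSums(beta != 0)
  new_lasso_path(fit$lambda, beta, a0, df, outcome$family, TRUE,
                 glmnet_fit = fit, pad = length(pm$exclude) > 0)
}

fit_unpenalized <- function(x, outcome, offset) {
  fam <- outcome$family
  if (fam == "survival") {
    fit <- survival::coxph(as_glmnet_y(outcome) ~ x + offset(offset),
                           ties = "breslow")
    beta <- matrix(unname(stats::coef(fit)), ncol = 1L,
                   dimnames = list(colnames(x), NULL))
    a0 <- NULL
  } else {
    glm_fam <- if (fam == "binary") stats::binomial() else stats::gaussian()
    fit <- stats::glm.fit(cbind(1, x), outcome$y, offset = offset,
                          family = glm_fam)
    cf <- fit$coefficients
    beta <- matrix(unname(cf[-1L]), ncol = 1L,
                   dimnames = list(colnames(x), NULL))
    a0 <- unname(cf[1L])
  }
  if (anyNA(beta))
    pl_error("singular_fit",
             "unpenalized block fit is rank deficient; reduce the block")
  new_lasso_path(0, beta, a0, sum(beta != 0), fam, FALSE)
}

# coefficients (and intercept) at one lambda of a path
path_coef <- function(path, lambda) {
  i <- which.min(abs(path$lambda - lambda))
  pl_assert(abs(path$lambda[i] - lambda) <=
              1e-8 * max(lambda, path$lambda[i], 1e-12), "unknown_lambda",
            "lambda is not on the fitted path")
  list(beta = path$beta[, i], a0 = if (is.null(path$a0)) 0 else path$a0[i],
       lambda = path$lambda[i])
}

# linear score of one block at one lambda (intercept included except Cox)
path_score <- function(path, lambda, x) {
  cf <- path_coef(path, lambda)
  drop(as.matrix(x) %*% cf$beta) +
    if (path$family == "survival") 0 else cf$a0
}

#' K-fold cross-validation error curve along a penalty path
#'
#' Fits the path on each training fold (with the supplied offset) and
#' evaluates the held-out fold, averaging the family deviance: squared error
#' (continuous), binomial deviance (binary), cross-validated partial
#' likelihood deviance (survival).
#'
#' @inheritParams fit_path
#' @param nfolds Number of folds (>= 2).
#' @param seed Seed for the fold assignment ([make_folds()]).
#' @param foldid Optional explicit fold labels overriding `nfolds`/`seed`.
#' @param ... Passed to [glmnet::cv.glmnet()].
#' @return A `cv_curve`: `lambda`, `cvm` (mean CV error), `cvsd` (its
#'   standard error), `nzero`, `foldid`, and `path`, the full-data
#'   `lasso_path`.
#' @export
cv_error <- function(x, outcome, offset = NULL, nfolds = 10L, seed = 1L,
                     foldid = NULL, standardize = TRUE, ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  offset <- offset %||% rep(0, n)
  fam <- as_glmnet_family(outcome$family)
  if (is.null(foldid)) {
    foldid <- make_folds(n, nfolds, seed,
                         status = if (fam == "cox") outcome$status else NULL)
  } else if (fam == "cox") {
    tab <- tapply(outcome$status, foldid, sum)
    if (any(tab == 0))
      pl_error("degenerate_fold", "a supplied fold contains no events")
  }
  if (outcome$family == "binary") {
    both <- vapply(sort(unique(foldid)), function(k)
      length(unique(outcome$y[foldid != k])) == 2L, TRUE)
    if (!all(both))
      pl_error("degenerate_fold",
               "a training fold contains only one outcome class")
  }
  pm <- pad_matrix(x)
  tm <- switch(fam, gaussian = "mse", binomial = "deviance",
               cox = "deviance")
  cvfit <- suppressWarnings(
    glmnet::cv.glmnet(pm$x, as_glmnet_y(outcome), family = fam,
                      offset = offset, foldid = foldid,
                      type.measure = tm, standardize = standardize,
                      exclude = pm$exclude,
                      grouped = all(tabulate(foldid) >= 3L), ...))
  gfit <- cvfit$glmnet.fit
  beta <- as.matrix(gfit$beta)
  if (length(pm$exclude)) beta <- beta[1L, , drop = FALSE]
  rownames(beta) <- colnames(x)
  keep <- match(cvfit$lambda, gfit$lambda)
  path <- new_lasso_path(cvfit$lambda, beta[, keep, drop = FALSE],
                         if (fam == "cox") NULL else
                           as.numeric(gfit$a0)[keep],
                         colSums(beta[, keep, drop = FALSE] != 0),
                         outcome$family, TRUE, glmnet_fit = gfit,
                         pad = length(pm$exclude) > 0)
  structure(list(lambda = cvfit$lambda, cvm = cvfit$cvm, cvsd = cvfit$cvsd,
                 nzero = path$df, foldid = foldid, path = path,
                 family = outcome$family),
            class = "cv_curve")
}

#' Select the penalty from a cross-validation curve
#'
#' `rule = "min"` returns the penalty of minimal mean CV error; `rule =
#' "1se"` the largest penalty whose mean error is within one standard error
#' of that minimum (the sparser choice). Ties are broken towards the larger
#' penalty.
#'
#' @param curve A `cv_curve` (or any list with decreasing `lambda`, `cvm`,
#'   `cvsd`).
#' @param rule `"min"` or `"1se"`.
#' @return The selected lambda (scalar).
#' @export
select_lambda <- function(curve, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  pl_assert(length(curve$lambda) >= 1L, "empty_curve",
            "cross-validation curve is empty")
  select_lambda_idx(curve$lambda, curve$cvm, curve$cvsd, rule,
                    seq_along(curve$lambda))
}

# shared kernel: lambdas assumed decreasing; admissible = index subset
select_lambda_idx <- function(lambda, cvm, cvsd, rule, admissible) {
  cvm_a <- cvm[admissible]
  i_min <- admissible[which(cvm_a <= min(cvm_a) + 1e-12)[1L]]
  if (rule == "min") return(lambda[i_min])
  thr <- cvm[i_min] + cvsd[i_min]
  lambda[admissible[which(cvm[admissible] <= thr + 1e-12)[1L]]]
}

#' Penalty selection under a cap on non-zero coefficients
#'
#' Restricts [select_lambda()] to path points whose number of non-zero
#' coefficients does not exceed `max_nonzero`; if no point qualifies, the
#' largest penalty (all-zero block) is returned.
#'
#' @param curve A `cv_curve`.
#' @param max_nonzero Nonnegative cap (may be `Inf`).
#' @param rule `"min"` or `"1se"`.
#' @return The selected lambda.
#' @export
constrain_nonzero <- function(curve, max_nonzero, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  pl_assert(is.numeric(max_nonzero) && length(max_nonzero) == 1L &&
              max_nonzero >= 0, "invalid_options",
            "max_nonzero must be a nonnegative scalar")
  adm <- which(curve$nzero <= max_nonzero)
  if (!length(adm)) return(curve$lambda[1L])
  select_lambda_idx(curve$lambda, curve$cvm, curve$cvsd, rule, adm)
}
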