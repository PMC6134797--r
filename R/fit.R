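#' Fit a prioritized block-wise Lasso model
#'
#' Blocks are fitted in priority order. Step 1 fits an L1-penalized model
#' (or, with `penalize_first_block = FALSE`, an unpenalized one) to the block
#' of highest priority. Each later step fits a Lasso to its block with the
#' accumulated linear score of all previous steps entering as an offset with
#' coefficient fixed to 1, so a block of lower priority can only pick up
#' outcome variability not already explained by blocks of higher priority.
#' For a continuous outcome this is equivalent to fitting each block to the
#' residuals of the previous step.
#'
#' With `cv_offsets = TRUE` the offset handed to the next step is
#' cross-validated: the data are split into `nfolds_offset` parts and each
#' sample's block contribution is computed from coefficients estimated with
#' that sample's fold left out. This counteracts the over-optimism of
#' in-sample scores, which would otherwise understate the conditional
#' influence of lower-priority blocks. The coefficients reported for every
#' step (and used by [linear_score()] on new data) are always the full-data
#' estimates; cross-validation only changes what downstream steps condition
#' on.
#'
#' Each step's penalty is chosen by `nfolds_lambda`-fold cross-validation
#' under `lambda_rule`, subject to the per-block `max_nonzero` cap. The whole
#' procedure is deterministic given `options$seed`.
#'
#' @param dataset A [pl_dataset()].
#' @param options A [fit_options()].
#' @return An object of class `priority_model`: `step_fits` (per block, in
#'   priority order: coefficients, chosen lambda, rule, offset used,
#'   non-zero count), `spec`, `options`, `family`, `intercept` (summed step
#'   intercepts; 0 for survival), `coefficients` (full named vector),
#'   `train_score` (final full-data linear predictor), `n_train`.
#' @examples
#' sim <- simulate_dataset(sim_config(n = 80, block_sizes = c(3, 5),
#'                                    beta = list(c(1, -1, 0), rep(0, 5)),
#'                                    family = "continuous", seed = 7))
#' fit <- priority_lasso(sim$dataset, fit_options(seed = 7))
#' coef(fit)
#' @export
priority_lasso <- function(dataset, options = fit_options()) {
  pl_assert(inherits(dataset, "pl_dataset"), "invalid_dataset",
            "`dataset` must be a pl_dataset")
  pl_assert(inherits(options, "fit_options"), "invalid_options",
            "`options` must be fit_options()")
  spec <- dataset$spec
  M <- n_blocks(spec)
  n <- nrow(dataset$X)
  outcome <- dataset$outcome
  if (!options$penalize_first_block)
    pl_assert(length(spec$blocks[[spec$priority[1L]]]) < n,
              "block_too_large",
              "unpenalized top block requires p < n in that block")

  step_fits <- vector("list", M)
  offset_next <- rep(0, n)       # what the next step conditions on
  score_full <- rep(0, n)        # accumulated full-data linear predictor
  intercept <- 0
  for (m in seq_len(M)) {
    xb <- block_matrix(dataset, m)
    offset_in <- offset_next
    unpen <- (m == 1L && !options$penalize_first_block)
    if (unpen) {
      path <- fit_path(xb, outcome, offset = offset_in, penalized = FALSE)
      lambda <- 0
      curve <- NULL
    } else {
      curve <- cv_error(xb, outcome, offset = offset_in,
                        nfolds = options$nfolds_lambda,
                        seed = options$seed + m,
                        standardize = options$standardize)
      path <- curve$path
      cap <- max_nonzero_at(options, m, M)
      lambda <- if (is.finite(cap)) {
        constrain_nonzero(curve, cap, options$lambda_rule)
      } else {
        select_lambda(curve, options$lambda_rule)
      }
    }
    cf <- path_coef(path, lambda)
    step_score <- path_score(path, lambda, xb)
    intercept <- intercept + cf$a0
    score_full <- score_full + step_score

    cv_rec <- NULL
    if (m < M) {
      if (options$cv_offsets) {
        cv_rec <- compute_cv_offsets(dataset, m, offset_in, options)
        offset_next <- cv_rec$offsets
      } else {
        offset_next <- offset_in + step_score
      }
    }
    step_fits[[m]] <- structure(list(
      block = spec$priority[m], position = m, lambda = lambda,
      rule = if (unpen) "unpenalized" else options$lambda_rule,
      unpenalized = unpen, coefficients = cf$beta, intercept = cf$a0,
      offset_used = offset_in, nonzero = sum(cf$beta != 0),
      cvm = if (is.null(curve)) NA_real_ else
        curve$cvm[which.min(abs(curve$lambda - lambda))],
      cv_offset_record = cv_rec), class = "pl_step_fit")
  }
  coefs <- unlist(lapply(step_fits, `[[`, "coefficients"))
  names(coefs) <- unlist(lapply(step_fits,
                                function(s) names(s$coefficients)))
  structure(list(step_fits = step_fits, spec = spec, options = options,
                 family = outcome$family, intercept = intercept,
                 coefficients = coefs, train_score = score_full,
                 n_train = n),
            class = "priority_model")
}

#' @export
coef.priority_model <- function(object, ...) object$coefficients

#' @export
print.priority_model <- function(x, ...) {
  cat(sprintf("prioritized block-wise Lasso (%s outcome, n = %d)\n",
              x$family, x$n_train))
  cat(sprintf("  cross-validated offsets: %s; lambda rule: %s\n",
              x$options$cv_offsets, x$options$lambda_rule))
  for (s in x$step_fits)
    cat(sprintf("  step %d [%s]: lambda = %.4g (%s), %d non-zero%s\n",
                s$position, s$block, s$lambda, s$rule, s$nonzero,
                if (is.na(s$cvm)) "" else sprintf(", cv error %.4g", s$cvm)))
  cat(sprintf("  total non-zero coefficients: %d\n",
              sum(x$coefficients != 0)))
  invisible(x)
}

#' Cross-validated offset contributions for one step
#'
#' Splits the samples into `nfolds_offset` approximately equal parts (event
#' stratified for survival). For each fold `k` the step's block is refitted
#' on the remaining folds -- with the same penalty-selection procedure the
#' main fit uses, cross-validating lambda within the training part -- and
#' the held-out samples are scored with those fold-external coefficients.
#' The returned offsets are `prior_offsets + fold-external block score`
#' (fold-specific intercepts included for continuous and binary families).
#'
#' @param dataset A `pl_dataset`.
#' @param step Priority position (1-based) of the block.
#' @param prior_offsets Accumulated offsets entering this step.
#' @param options [fit_options()].
#' @param foldid Optional explicit fold assignment.
#' @return A `cv_offset_record`: `step`, `foldid`, `fold_lambda`,
#'   `fold_coefficients` (list), `fold_intercepts`, `contribution`
#'   (per-sample fold-external block score) and `offsets`.
#' @export
compute_cv_offsets <- function(dataset, step, prior_offsets, options,
                               foldid = NULL) {
  pl_assert(step >= 1L && step <= n_blocks(dataset$spec), "invalid_step",
            "step out of range")
  n <- nrow(dataset$X)
  pl_assert(length(prior_offsets) == n, "length_mismatch",
            "prior_offsets must have length n")
  outcome <- dataset$outcome
  surv <- outcome$family == "survival"
  foldid <- foldid %||% make_folds(n, options$nfolds_offset,
                                   options$seed + 100L * step,
                                   status = if (surv) outcome$status)
  xb <- block_matrix(dataset, step)
  K <- max(foldid)
  contribution <- numeric(n)
  fold_lambda <- numeric(K)
  fold_coefficients <- vector("list", K)
  fold_intercepts <- numeric(K)
  fold_inner_foldid <- vector("list", K)
  unpen <- (step == 1L && !options$penalize_first_block)
  for (k in seq_len(K)) {
    tr <- which(foldid != k)
    te <- which(foldid == k)
    out_tr <- subset_outcome(outcome, tr)
    if (unpen) {
      path <- fit_path(xb[tr, , drop = FALSE], out_tr,
                       offset = prior_offsets[tr], penalized = FALSE)
      lam <- 0
    } else {
      inner <- make_folds(length(tr), options$nfolds_lambda,
                          options$seed + 100L * step + k,
                          status = if (surv) outcome$status[tr])
      fold_inner_foldid[[k]] <- inner
      curve <- cv_error(xb[tr, , drop = FALSE], out_tr,
                        offset = prior_offsets[tr],
                        foldid = inner,
                        standardize = options$standardize)
      path <- curve$path
      cap <- max_nonzero_at(options, step, n_blocks(dataset$spec))
      lam <- if (is.finite(cap)) {
        constrain_nonzero(curve, cap, options$lambda_rule)
      } else {
        select_lambda(curve, options$lambda_rule)
      }
    }
    cf <- path_coef(path, lam)
    fold_lambda[k] <- lam
    fold_coefficients[[k]] <- cf$beta
    fold_intercepts[k] <- cf$a0
    contribution[te] <- path_score(path, lam, xb[te, , drop = FALSE])
  }
  structure(list(step = step, foldid = foldid, fold_lambda = fold_lambda,
                 fold_inner_foldid = fold_inner_foldid,
                 fold_coefficients = fold_coefficients,
                 fold_intercepts = fold_intercepts,
                 contribution = contribution,
                 offsets = prior_offsets + contribution),
            class = "cv_offset_record")
}

#' Choose among candidate priority orders by cross-validated error
#'
#' Each candidate order is scored by K-fold cross-validation of the *whole*
#' fitting pipeline: for every outer fold the model is refitted on the
#' remaining folds (inner lambda folds are nested and distinct from the
#' outer partition) and the held-out prediction loss is recorded -- squared
#' error (continuous), binomial deviance (binary) or the
#' Verweij-van-Houwelingen cross-validated partial likelihood deviance
#' (survival). The candidate of minimal mean loss wins; ties are broken by
#' candidate list order.
#'
#' @param dataset A `pl_dataset`.
#' @param orders List of candidate priority orders (character vectors of
#'   block names or integer permutations).
#' @param options [fit_options()].
#' @param nfolds_outer Outer scoring folds (default 5).
#' @return List with `best_order`, `model` (fitted on the full data with the
#'   winning order), `cv_error` (named per-candidate mean loss).
#' @export
choose_order <- function(dataset, orders, options = fit_options(),
                         nfolds_outer = 5L) {
  pl_assert(is.list(orders) && length(orders) >= 1L, "invalid_orders",
            "`orders` must be a non-empty list of priority orders")
  spec <- dataset$spec
  norm_orders <- lapply(orders, function(o) {
    if (is.numeric(o)) o <- names(spec$blocks)[o]
    pl_assert(setequal(o, names(spec$blocks)) &&
                length(o) == length(spec$blocks), "invalid_priority",
              "each candidate must be a permutation of the block names")
    as.character(o)
  })
  outcome <- dataset$outcome
  surv <- outcome$family == "survival"
  n <- nrow(dataset$X)
  foldid <- make_folds(n, nfolds_outer, options$seed + 7777L,
                       status = if (surv) outcome$status)
  losses <- vapply(seq_along(norm_orders), function(ci) {
    ord <- norm_orders[[ci]]
    ds <- pl_dataset(dataset$X, block_spec(spec$blocks, priority = ord),
                     outcome, sample_ids = dataset$sample_ids)
    fold_loss <- vapply(seq_len(max(foldid)), function(k) {
      tr <- which(foldid != k)
      opts_k <- options
      opts_k$seed <- options$seed + 131L * k
      fit_k <- priority_lasso(dataset_subset(ds, tr), opts_k)
      held_out_loss(fit_k, ds, tr)
    }, 1)
    mean(fold_loss)
  }, 1)
  labels <- vapply(norm_orders, paste, "", collapse = ">")
  names(losses) <- labels
  best <- which.min(losses)  # first minimum: candidate list order
  best_ds <- pl_dataset(dataset$X,
                        block_spec(spec$blocks,
                                   priority = norm_orders[[best]]),
                        outcome, sample_ids = dataset$sample_ids)
  list(best_order = norm_orders[[best]],
       model = priority_lasso(best_ds, options),
       cv_error = losses)
}

# prediction loss of a model fitted on `tr` rows of `ds`, on the complement
held_out_loss <- function(model, ds, tr) {
  te <- setdiff(seq_len(nrow(ds$X)), tr)
  eta_all <- linear_score(model, ds$X)$score
  o <- ds$outcome
  if (o$family == "continuous")
    return(mean((o$y[te] - eta_all[te])^2))
  if (o$family == "binary") {
    p <- stats::plogis(eta_all[te])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    return(mean(-2 * (o$y[te] * log(p) + (1 - o$y[te]) * log1p(-p))))
  }
  # survival: Verweij & van Houwelingen CV partial likelihood deviance
  pl_full <- cox_partial_loglik(o$time, o$status, eta_all)
  pl_train <- cox_partial_loglik(o$time[tr], o$status[tr], eta_all[tr])
  -2 * (pl_full - pl_train) / length(te)
}

# Breslow-ties Cox partial log-likelihood of a fixed linear score
cox_partial_loglik <- function(time, status, eta) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; eta <- eta[ord]
  # risk-set denominators via reverse cumulative sums of exp(eta)
  rev_cum <- rev(cumsum(rev(exp(eta))))
  ev <- which(status == 1)
  if (!length(ev)) return(0)
  # for ties: denominator is the risk set at the first index with that time
  first_idx <- match(time, time)
  sum(eta[ev] - log(rev_cum[first_idx[ev]]))
}
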