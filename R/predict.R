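#' Linear score of a fitted model on new samples
#'
#' Computes the final linear predictor
#' \eqn{\hat\eta_i = a + \sum_m \sum_j \hat\beta_j^{(m)} x_{ij}^{(m)}}
#' (no intercept `a` for survival) together with its exact per-block
#' decomposition.
#'
#' @param model A `priority_model` or `portable_model` ([import_model()]).
#' @param X Numeric matrix whose columns include all model features (matched
#'   by name; extra columns are ignored).
#' @return List with `score` (length n), `by_block` (n x M matrix of block
#'   contributions, priority order; `score = intercept + rowSums(by_block)`)
#'   and `intercept`.
#' @export
linear_score <- function(model, X) {
  UseMethod("linear_score")
}

score_from_parts <- function(X, spec, coefs, intercept, family) {
  X <- as.matrix(X)
  missing <- setdiff(names(coefs), colnames(X))
  if (length(missing))
    pl_error("unknown_feature",
             paste0("matrix lacks model features: ",
                    paste(utils::head(missing, 5L), collapse = ", ")))
  M <- length(spec$priority)
  by_block <- matrix(0, nrow(X), M,
                     dimnames = list(rownames(X), spec$priority))
  for (m in seq_len(M)) {
    fe <- spec$blocks[[spec$priority[m]]]
    fe <- fe[fe %in% names(coefs)]
    if (length(fe))
      by_block[, m] <- drop(X[, fe, drop = FALSE] %*% coefs[fe])
  }
  a <- if (family == "survival") 0 else intercept
  list(score = a + rowSums(by_block), by_block = by_block, intercept = a)
}

#' @export
linear_score.priority_model <- function(model, X) {
  score_from_parts(X, model$spec, model$coefficients, model$intercept,
                   model$family)
}

#' @export
linear_score.portable_model <- function(model, X) {
  score_from_parts(X, model$spec, model$coefficients, model$intercept,
                   model$family)
}

#' @export
predict.priority_model <- function(object, newx,
                                   type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- linear_score(object, newx)$score
  if (type == "link") return(eta)
  switch(object$family,
         continuous = eta,
         binary = stats::plogis(eta),
         survival = exp(eta))
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' Given training survival data and the fitted linear scores, the cumulative
#' baseline hazard gains, at each distinct event time t, an increment
#' (number of events at t) / (sum of exp(score) over subjects still at
#' risk). Tied event times share the denominator (Breslow tie handling).
#' With all-zero scores this reduces to the Nelson-Aalen estimator.
#'
#' @param time,status Training survival outcome.
#' @param scores Per-sample linear scores from the fitted model.
#' @return Object of class `breslow_baseline`: `time` (sorted distinct event
#'   times) and `hazard` (nondecreasing cumulative baseline hazard).
#' @export
breslow_baseline <- function(time, status, scores) {
  out <- outcome_survival(time, status)
  pl_assert(length(scores) == length(time), "length_mismatch",
            "scores must match the outcome length")
  ord <- order(time)
  t_o <- time[ord]; d_o <- status[ord]; e_o <- exp(scores[ord])
  rev_cum <- rev(cumsum(rev(e_o)))       # risk-set sums at each sorted index
  first_idx <- match(t_o, t_o)
  et <- sort(unique(t_o[d_o == 1]))
  inc <- vapply(et, function(tt) {
    i <- first_idx[match(tt, t_o)]
    sum(d_o[t_o == tt]) / rev_cum[i]
  }, 1)
  structure(list(time = et, hazard = cumsum(inc)),
            class = "breslow_baseline")
}

# cumulative baseline hazard evaluated at arbitrary times (right-continuous
# step function; 0 before the first event)
baseline_at <- function(baseline, times) {
  idx <- findInterval(times, baseline$time)
  c(0, baseline$hazard)[idx + 1L]
}

#' Predicted survival curves
#'
#' Individual predicted survival probabilities
#' \eqn{S(t \mid x) = \exp(-H_0(t)\, e^{\eta})}, evaluated as
#' right-continuous step functions between the baseline's jump times.
#'
#' @param baseline A [breslow_baseline()].
#' @param scores Per-sample linear scores.
#' @param times Nonnegative evaluation times.
#' @return Matrix (samples x times) of survival probabilities in `[0, 1]`,
#'   nonincreasing along each row.
#' @export
predict_survival <- function(baseline, scores, times) {
  pl_assert(all(times >= 0), "invalid_times",
            "evaluation times must be nonnegative")
  H0 <- baseline_at(baseline, times)
  S <- exp(-outer(exp(scores), H0))
  dimnames(S) <- list(names(scores), NULL)
  S
}
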