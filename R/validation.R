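#' @importFrom survival Surv coxph coxph.control survfit survdiff
NULL

# Kaplan-Meier estimate of the censoring distribution G(t), with left-limit
# evaluation G(t-). Ties between events and censorings are treated
# event-first: the censoring KM is built from flipped status via survfit,
# whose convention keeps tied events in the censoring risk set.
km_censor <- function(time, status) {
  sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  knots <- sf$time
  vals <- c(1, sf$surv)
  list(
    G = function(t) vals[findInterval(t, knots) + 1L],
    G_minus = function(t) vals[findInterval(t, knots,
                                            left.open = TRUE) + 1L]
  )
}

#' Uno's censoring-adjusted C-index
#'
#' Inverse-probability-of-censoring-weighted concordance, truncated at
#' horizon `tau`: over pairs (i, j) with an observed event time
#' \eqn{T_i < \min(T_j, \tau)}, concordant score orderings (higher score,
#' shorter survival) are counted with weight \eqn{1/\hat G(T_i-)^2}, where
#' \eqn{\hat G} is the Kaplan-Meier estimate of the censoring distribution.
#' Score ties count 1/2.
#'
#' @param scores Risk scores (higher = shorter expected survival).
#' @param time,status Survival outcome.
#' @param tau Truncation horizon; defaults to the largest observed event
#'   time.
#' @return Concordance in `[0, 1]`.
#' @export
uno_c <- function(scores, time, status, tau = NULL) {
  out <- outcome_survival(time, status)
  pl_assert(length(scores) == length(time), "length_mismatch",
            "scores must match the outcome length")
  tau <- tau %||% max(time[status == 1])
  km <- km_censor(time, status)
  idx <- which(status == 1 & time < tau)
  num <- 0; den <- 0
  for (i in idx) {
    comp <- which(time > time[i])
    if (!length(comp)) next
    w <- 1 / km$G_minus(time[i])^2
    conc <- sum(scores[i] > scores[comp]) +
      0.5 * sum(scores[i] == scores[comp])
    num <- num + w * conc
    den <- den + w * length(comp)
  }
  if (den == 0)
    pl_error("no_comparable_pairs",
             "no comparable pairs below the horizon tau")
  num / den
}

#' IPCW Brier score curve and integrated Brier score
#'
#' The Brier score at t averages, with inverse-probability-of-censoring
#' weights, the squared difference between the predicted survival
#' probability and the observed status: subjects with an event by t
#' contribute \eqn{\hat S(t|x)^2 / \hat G(T_i-)}, subjects still under
#' observation after t contribute \eqn{(1-\hat S(t|x))^2 / \hat G(t)};
#' subjects censored by t contribute 0.
#'
#' @param surv_pred Matrix (samples x `eval_times`) of predicted survival
#'   probabilities.
#' @param time,status Observed survival outcome.
#' @param eval_times Evaluation grid (nonnegative, increasing; should start
#'   at 0 if the curve is to be integrated from 0).
#' @return `brier_curve`: a data frame with columns `time`, `brier`.
#' @export
brier_curve <- function(surv_pred, time, status, eval_times) {
  out <- outcome_survival(time, status)
  surv_pred <- as.matrix(surv_pred)
  pl_assert(nrow(surv_pred) == length(time) &&
              ncol(surv_pred) == length(eval_times), "length_mismatch",
            "surv_pred must be samples x eval_times")
  km <- km_censor(time, status)
  bs <- vapply(seq_along(eval_times), function(j) {
    t <- eval_times[j]
    S <- surv_pred[, j]
    died <- time <= t & status == 1
    alive <- time > t
    w_died <- ifelse(died, 1 / km$G_minus(time), 0)
    g_t <- km$G(t)
    if (any(alive) && g_t == 0)
      pl_error("zero_censoring_weight",
               "censoring survival reaches 0 before the horizon")
    w_alive <- ifelse(alive, 1 / g_t, 0)
    mean(S^2 * w_died + (1 - S)^2 * w_alive)
  }, 1)
  structure(data.frame(time = eval_times, brier = bs),
            class = c("brier_curve", "data.frame"))
}

#' @rdname brier_curve
#' @param curve A `brier_curve`.
#' @param t_max Upper end of the integration window (defaults to the last
#'   grid time).
#' @return `integrated_brier`: the time-average
#'   \eqn{(1/t_{max}) \int_0^{t_{max}} BS(t)\,dt} by the trapezoidal rule
#'   over the grid.
#' @export
integrated_brier <- function(curve, t_max = max(curve$time)) {
  keep <- curve$time <= t_max + 1e-12
  tt <- curve$time[keep]; bb <- curve$brier[keep]
  pl_assert(length(tt) >= 2L, "invalid_times",
            "need at least two grid points below t_max")
  sum(diff(tt) * (utils::head(bb, -1) + utils::tail(bb, -1)) / 2) / t_max
}

#' Calibration slope of a risk score
#'
#' Coefficient of the score entered as the sole covariate of an unpenalized
#' Cox model. For the linear predictor of an unpenalized Cox model evaluated
#' on its own training data the slope is exactly 1; on external data a slope
#' below 1 indicates over-fitted (too extreme) risk estimates.
#'
#' @param score Risk score (non-constant).
#' @param time,status Survival outcome.
#' @return The slope (scalar).
#' @export
calibration_slope <- function(score, time, status) {
  out <- outcome_survival(time, status)
  pl_assert(stats::sd(score) > 0, "constant_score",
            "calibration slope requires a non-constant score")
  fit <- survival::coxph(survival::Surv(time, status) ~ score,
                         ties = "breslow",
                         control = survival::coxph.control(
                           eps = 1e-12, toler.chol = 1e-14,
                           iter.max = 100))
  unname(stats::coef(fit))
}

#' @rdname calibration_slope
#' @param slope_train,slope_val Calibration slopes on training and
#'   validation data.
#' @return `optimism`: `slope_train - slope_val`, the over-optimism of the
#'   in-sample assessment.
#' @export
optimism <- function(slope_train, slope_val) slope_train - slope_val

#' Three risk groups by the maximal three-group logrank statistic
#'
#' Searches all ordered pairs of candidate cutpoints (midpoints between
#' consecutive distinct score values) and returns the pair maximising the
#' three-group logrank chi-square, subject to every group containing at
#' least `min_frac` of the samples. Among statistic ties the most balanced
#' pair wins, then the smaller lower cutpoint. The partition is invariant
#' under strictly increasing transforms of the score.
#'
#' @param score Risk score on the data that define the cutpoints (training
#'   data, by convention).
#' @param time,status Survival outcome of the same data.
#' @param min_frac Minimum group size as a fraction of n (default 0.10).
#' @return Object of class `risk_groups`: `cut1 < cut2`, `chi2`, and
#'   `groups`, the factor (`low`/`intermediate`/`high`) for the supplied
#'   scores. Apply to new scores with [assign_risk_groups()].
#' @export
logrank_cutpoints <- function(score, time, status, min_frac = 0.1) {
  out <- outcome_survival(time, status)
  n <- length(score)
  pl_assert(length(time) == n, "length_mismatch",
            "score and outcome lengths differ")
  min_size <- max(1L, floor(min_frac * n))
  pl_assert(n >= 3L * min_size, "too_few_samples",
            "need at least 3 x minimum group size samples")
  ord <- order(score)
  s_s <- score[ord]; t_s <- time[ord]; d_s <- status[ord]
  et <- sort(unique(t_s[d_s == 1]))
  D <- length(et)
  # prefix counts over the score order, per event time
  Y <- outer(t_s, et, ">=")                    # at risk
  E <- outer(t_s, et, "==") & (d_s == 1)       # event at that time
  A <- apply(Y, 2, cumsum)
  B <- apply(E, 2, cumsum)
  nd <- A[n, ]; dd <- B[n, ]
  v <- ifelse(nd > 1, dd * (nd - dd) / (nd - 1), 0)
  cand <- which(diff(s_s) > 0)                 # cut after rank r
  adm1 <- cand[cand >= min_size]
  best <- list(chi2 = -Inf)
  for (r1 in adm1) {
    r2s <- cand[cand >= r1 + min_size & cand <= n - min_size]
    if (!length(r2s)) next
    n1 <- A[r1, ]; d1 <- B[r1, ]
    for (r2 in r2s) {
      n2 <- A[r2, ] - n1; d2 <- B[r2, ] - d1
      f1 <- n1 / nd; f2 <- n2 / nd
      u1 <- sum(d1) - sum(dd * f1)
      u2 <- sum(d2) - sum(dd * f2)
      V11 <- sum(v * f1 * (1 - f1))
      V22 <- sum(v * f2 * (1 - f2))
      V12 <- -sum(v * f1 * f2)
      det <- V11 * V22 - V12^2
      if (det <= 1e-300) next
      chi2 <- (u1^2 * V22 - 2 * u1 * u2 * V12 + u2^2 * V11) / det
      if (chi2 > best$chi2 + 1e-9) {
        best <- list(chi2 = chi2, r1 = r1, r2 = r2)
      } else if (abs(chi2 - best$chi2) <= 1e-9) {
        # tie: prefer balanced sizes, then smaller lower cutpoint
        spread <- function(a, b) {
          sz <- c(a, b - a, n - b); max(sz) - min(sz)
        }
        if (spread(r1, r2) < spread(best$r1, best$r2) ||
            (spread(r1, r2) == spread(best$r1, best$r2) &&
             s_s[r1] < s_s[best$r1]))
          best <- list(chi2 = chi2, r1 = r1, r2 = r2)
      }
    }
  }
  if (!is.finite(best$chi2))
    pl_error("no_admissible_cutpoints",
             "no cutpoint pair satisfies the group-size constraint")
  cut1 <- (s_s[best$r1] + s_s[best$r1 + 1L]) / 2
  cut2 <- (s_s[best$r2] + s_s[best$r2 + 1L]) / 2
  rg <- structure(list(cut1 = cut1, cut2 = cut2, chi2 = best$chi2,
                       min_frac = min_frac),
                  class = "risk_groups")
  rg$groups <- assign_risk_groups(rg, score)
  rg
}

#' @rdname logrank_cutpoints
#' @param rg A `risk_groups` object.
#' @return `assign_risk_groups`: factor with levels
#'   `low`, `intermediate`, `high` (higher score = higher risk).
#' @export
assign_risk_groups <- function(rg, score) {
  cut(score, breaks = c(-Inf, rg$cut1, rg$cut2, Inf),
      labels = c("low", "intermediate", "high"), right = TRUE)
}

#' @export
print.risk_groups <- function(x, ...) {
  cat(sprintf("risk groups: cutpoints %.4g / %.4g (logrank chi2 = %.2f)\n",
              x$cut1, x$cut2, x$chi2))
  if (!is.null(x$groups)) print(table(x$groups))
  invisible(x)
}

#' Hazard ratios across risk groups
#'
#' Unpenalized Cox regression on indicators for the low and high risk
#' groups, the intermediate group serving as the baseline, with Wald 95%
#' confidence intervals and the likelihood-ratio test against the null
#' model.
#'
#' @param groups Factor with levels `low`, `intermediate`, `high` (each with
#'   at least one event).
#' @param time,status Survival outcome.
#' @return List: `hr_low`, `ci_low`, `hr_high`, `ci_high`, `lr_p`.
#' @export
group_hazard_ratios <- function(groups, time, status) {
  out <- outcome_survival(time, status)
  groups <- factor(groups, levels = c("low", "intermediate", "high"))
  ev <- tapply(status, groups, sum)
  if (any(is.na(ev)) || any(ev == 0))
    pl_error("empty_group_events",
             "every risk group needs at least one event")
  g <- stats::relevel(groups, ref = "intermediate")
  fit <- survival::coxph(survival::Surv(time, status) ~ g,
                         ties = "breslow")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  ci <- function(i) exp(cf[i] + c(-1, 1) * z * se[i])
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  list(hr_low = unname(exp(cf["glow"])), ci_low = unname(ci("glow")),
       hr_high = unname(exp(cf["ghigh"])), ci_high = unname(ci("ghigh")),
       lr_stat = lr,
       lr_p = stats::pchisq(lr, df = 2, lower.tail = FALSE))
}

#' Sensitivity, specificity and AUC of a score at a fixed horizon
#'
#' Cases are subjects with an observed event by the horizon; controls are
#' subjects observed beyond it. Subjects censored before the horizon are,
#' by default, excluded (complete-case definition); with `ipcw = TRUE`
#' cases and controls are instead weighted by the inverse probability of
#' remaining uncensored (\eqn{1/\hat G(T_i-)} and \eqn{1/\hat G(t_h)}).
#' TPR/TNR dichotomise the score at `cutoff` (default: its median over the
#' scored subjects); the AUC is the rank statistic of the score for the
#' same case/control definition.
#'
#' @param score Risk score (higher = higher risk).
#' @param time,status Survival outcome.
#' @param horizon Evaluation time (within follow-up).
#' @param cutoff `"median"` or a numeric threshold.
#' @param ipcw Logical; see above.
#' @return List: `tpr`, `tnr`, `auc`, `cutoff`, `n_cases`, `n_controls`.
#' @export
binary_metrics_at <- function(score, time, status, horizon,
                              cutoff = "median", ipcw = FALSE) {
  out <- outcome_survival(time, status)
  pl_assert(horizon > 0 && horizon <= max(time), "invalid_times",
            "horizon must lie within follow-up")
  cut_val <- if (identical(cutoff, "median")) {
    stats::median(score)
  } else {
    pl_assert(is.numeric(cutoff), "invalid_options",
              "cutoff must be \"median\" or numeric")
    cutoff
  }
  case <- status == 1 & time <= horizon
  control <- time > horizon
  if (!any(case) || !any(control))
    pl_error("degenerate_horizon", "no cases or no controls at the horizon")
  if (ipcw) {
    km <- km_censor(time, status)
    w <- numeric(length(score))
    w[case] <- 1 / km$G_minus(time[case])
    w[control] <- 1 / km$G(horizon)
  } else {
    w <- as.numeric(case | control)
  }
  pos <- score > cut_val
  tpr <- sum(w[case & pos]) / sum(w[case])
  tnr <- sum(w[control & !pos]) / sum(w[control])
  ci <- which(case); co <- which(control)
  cmp <- outer(score[ci], score[co], function(a, b)
    (a > b) + 0.5 * (a == b))
  wm <- outer(w[ci], w[co])
  auc <- sum(cmp * wm) / sum(wm)
  list(tpr = tpr, tnr = tnr, auc = auc, cutoff = cut_val,
       n_cases = sum(case), n_controls = sum(control))
}

#' External validation report for a fitted survival model
#'
#' Computes the full external-validation bundle on an independent validation
#' dataset: Uno's C-index, IPCW Brier curves and integrated Brier scores
#' over two horizons (`horizon` and the last validation event), TPR/TNR/AUC
#' at `horizon` with the median-score cutoff, calibration slopes on training
#' and validation data and their difference (optimism), risk groups from the
#' maximal-logrank cutpoints on the *training* scores, validation hazard
#' ratios across those groups (intermediate baseline, likelihood-ratio
#' test), and observed vs. average-predicted Kaplan-Meier curves per group.
#'
#' @param model A fitted `priority_model` (survival family).
#' @param train,validation `pl_dataset`s with survival outcomes; `train`
#'   must be the data the model was fitted on (it anchors the Breslow
#'   baseline, the cutpoints and the training calibration slope).
#' @param horizon Clinical horizon for TPR/TNR/AUC and the first IBS window
#'   (default 2, in the study's time unit).
#' @param min_frac Minimum risk-group size fraction for the cutpoint search.
#' @param ipcw Use the IPCW variant of the horizon metrics.
#' @return Object of class `validation_report`.
#' @export
validate_model <- function(model, train, validation, horizon = 2,
                           min_frac = 0.1, ipcw = FALSE) {
  pl_assert(model$family == "survival", "invalid_family",
            "validation report is defined for survival models")
  otr <- train$outcome; ova <- validation$outcome
  pl_assert(otr$family == "survival" && ova$family == "survival",
            "invalid_family", "datasets must carry survival outcomes")
  sc_tr <- linear_score(model, train$X)$score
  sc_va <- linear_score(model, validation$X)$score

  base <- breslow_baseline(otr$time, otr$status, sc_tr)
  t_last <- max(ova$time[ova$status == 1])
  grid <- sort(unique(c(0, ova$time[ova$status == 1], horizon, t_last)))
  grid <- grid[grid <= max(horizon, t_last)]
  S_va <- predict_survival(base, sc_va, grid)
  bc <- brier_curve(S_va, ova$time, ova$status, grid)
  ibs_h <- integrated_brier(bc, t_max = horizon)
  ibs_last <- integrated_brier(bc, t_max = t_last)

  rg <- logrank_cutpoints(sc_tr, otr$time, otr$status, min_frac = min_frac)
  grp_va <- assign_risk_groups(rg, sc_va)
  hr <- group_hazard_ratios(grp_va, ova$time, ova$status)

  bm <- binary_metrics_at(sc_va, ova$time, ova$status, horizon,
                          cutoff = "median", ipcw = ipcw)
  slope_tr <- calibration_slope(sc_tr, otr$time, otr$status)
  slope_va <- calibration_slope(sc_va, ova$time, ova$status)

  km_obs <- do.call(rbind, lapply(levels(grp_va), function(g) {
    idx <- grp_va == g
    if (!any(idx)) return(NULL)
    sf <- survival::survfit(survival::Surv(ova$time[idx],
                                           ova$status[idx]) ~ 1)
    data.frame(group = g, time = sf$time, surv = sf$surv,
               kind = "observed")
  }))
  km_pred <- do.call(rbind, lapply(levels(grp_va), function(g) {
    idx <- grp_va == g
    if (!any(idx)) return(NULL)
    data.frame(group = g, time = grid,
               surv = colMeans(S_va[idx, , drop = FALSE]),
               kind = "predicted")
  }))

  structure(list(
    tpr = bm$tpr, tnr = bm$tnr, auc = bm$auc, horizon = horizon,
    uno_c = uno_c(sc_va, ova$time, ova$status, tau = t_last),
    ibs_horizon = ibs_h, ibs_last = ibs_last, t_last = t_last,
    slope_train = slope_tr, slope_val = slope_va,
    optimism = optimism(slope_tr, slope_va),
    hr_low = hr$hr_low, ci_low = hr$ci_low,
    hr_high = hr$hr_high, ci_high = hr$ci_high,
    lr_p = hr$lr_p,
    risk_groups = rg, validation_groups = grp_va,
    brier = bc, km_curves = rbind(km_obs, km_pred),
    scores = list(train = sc_tr, validation = sc_va)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("External validation report\n")
  cat(sprintf("  TPR / TNR / AUC at t = %.3g: %.3f / %.3f / %.3f\n",
              x$horizon, x$tpr, x$tnr, x$auc))
  cat(sprintf("  Uno's C-index: %.3f\n", x$uno_c))
  cat(sprintf("  IBS up to %.3g: %.3f; up to last event (%.3g): %.3f\n",
              x$horizon, x$ibs_horizon, x$t_last, x$ibs_last))
  cat(sprintf("  calibration slope train / validation: %.3f / %.3f",
              x$slope_train, x$slope_val))
  cat(sprintf("  (optimism %.3f)\n", x$optimism))
  cat(sprintf("  HR low vs intermediate: %.3f [%.3f, %.3f]\n",
              x$hr_low, x$ci_low[1], x$ci_low[2]))
  cat(sprintf("  HR high vs intermediate: %.3f [%.3f, %.3f]\n",
              x$hr_high, x$ci_high[1], x$ci_high[2]))
  cat(sprintf("  likelihood-ratio p-value: %.3g\n", x$lr_p))
  invisible(x)
}

#' Validation report as a two-column table
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return Data frame with columns `metric`, `value`.
#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(
    metric = c("TPR", "TNR", "AUC", "C_uno", "IBS_horizon", "IBS_last",
               "Optimism", "CI_L_lower", "HR_L", "CI_L_upper",
               "CI_H_lower", "HR_H", "CI_H_upper", "p_value_LR"),
    value = c(x$tpr, x$tnr, x$auc, x$uno_c, x$ibs_horizon, x$ibs_last,
              x$optimism, x$ci_low[1], x$hr_low, x$ci_low[2],
              x$ci_high[1], x$hr_high, x$ci_high[2], x$lr_p))
}
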