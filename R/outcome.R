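#' Outcome objects
#'
#' An outcome bundles the response with its family. Three families are
#' supported: `continuous` (squared-error loss), `binary` (logistic loss,
#' labels 0/1) and `survival` (right-censored time-to-event, Cox partial
#' likelihood; `status` 1 = event, 0 = censored, times strictly positive).
#'
#' @param y Numeric vector (continuous) or 0/1 vector (binary).
#' @return An object of class `pl_outcome`.
#' @examples
#' outcome_survival(time = c(1, 2, 3), status = c(1, 1, 0))
#' @export
outcome_continuous <- function(y) {
  y <- as.numeric(y)
  pl_assert(length(y) >= 1L && all(is.finite(y)), "missing_values",
            "continuous outcome must be finite and complete")
  pl_assert(stats::var(y) > 0 || length(y) == 1L, "constant_outcome",
            "continuous outcome is constant")
  structure(list(family = "continuous", y = y), class = "pl_outcome")
}

#' @rdname outcome_continuous
#' @export
outcome_binary <- function(y) {
  y <- as.numeric(y)
  pl_assert(all(is.finite(y)), "missing_values",
            "binary outcome must be complete")
  pl_assert(all(y %in% c(0, 1)), "invalid_binary_label",
            "binary outcome labels must be 0 or 1")
  pl_assert(length(unique(y)) == 2L, "constant_outcome",
            "binary outcome must contain both classes")
  structure(list(family = "binary", y = y), class = "pl_outcome")
}

#' @rdname outcome_continuous
#' @param time Positive event/censoring times.
#' @param status Event indicators: 1 = event observed, 0 = right-censored.
#' @export
outcome_survival <- function(time, status) {
  time <- as.numeric(time); status <- as.numeric(status)
  pl_assert(length(time) == length(status), "length_mismatch",
            "time and status must have equal length")
  pl_assert(all(is.finite(time)) && all(is.finite(status)), "missing_values",
            "survival outcome must be complete")
  if (any(time <= 0))
    pl_error("nonpositive_time", "survival times must be strictly positive")
  pl_assert(all(status %in% c(0, 1)), "invalid_status",
            "status must be 0 (censored) or 1 (event)")
  if (sum(status) == 0)
    pl_error("no_events", "survival outcome contains no events")
  structure(list(family = "survival", time = time, status = status),
            class = "pl_outcome")
}

n_samples <- function(outcome) {
  if (outcome$family == "survival") length(outcome$time) else length(outcome$y)
}

# response in the form glmnet expects
as_glmnet_y <- function(outcome) {
  switch(outcome$family,
         continuous = outcome$y,
         binary = outcome$y,
         survival = survival::Surv(outcome$time, outcome$status))
}

as_glmnet_family <- function(family) {
  switch(family, continuous = "gaussian", binary = "binomial",
         survival = "cox",
         pl_error("invalid_family", paste0("unknown family: ", family)))
}

subset_outcome <- function(outcome, idx) {
  if (outcome$family == "survival") {
    outcome_survival(outcome$time[idx], outcome$status[idx])
  } else if (outcome$family == "binary") {
    outcome_binary(outcome$y[idx])
  } else {
    outcome_continuous(outcome$y[idx])
  }
}

#' @export
print.pl_outcome <- function(x, ...) {
  n <- n_samples(x)
  if (x$family == "survival") {
    cat(sprintf("survival outcome: %d samples, %d events (%.0f%% censored)\n",
                n, sum(x$status), 100 * mean(x$status == 0)))
  } else {
    cat(sprintf("%s outcome: %d samples\n", x$family, n))
  }
  invisible(x)
}
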