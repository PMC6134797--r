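# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written as plain brute force, separate
# from the package's own code paths.

# closed-form Lasso solution for a single centered covariate, objective
# (1/2n)||y - x b||^2 + lambda |b| (no standardization)
soft_threshold_beta <- function(x, y, lambda) {
  rho <- sum(x * y) / length(y)
  sign(rho) * pmax(abs(rho) - lambda, 0) / (sum(x * x) / length(y))
}

# Kaplan-Meier of the censoring distribution, evaluated just below t
oracle_G_minus <- function(time, status, t) {
  sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  keep <- sf$time < t
  if (!any(keep)) 1 else min(sf$surv[keep][sum(keep)], 1)
}

oracle_G_at <- function(time, status, t) {
  sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  keep <- sf$time <= t
  if (!any(keep)) 1 else sf$surv[sum(keep)]
}

# Uno's C by explicit enumeration of all weighted pairs
oracle_uno_c <- function(scores, time, status, tau) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (status[i] != 1 || time[i] >= tau) next
    w <- 1 / oracle_G_minus(time, status, time[i])^2
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + w
      if (scores[i] > scores[j]) num <- num + w
      if (scores[i] == scores[j]) num <- num + 0.5 * w
    }
  }
  num / den
}

# IPCW Brier score at a single time by explicit per-subject terms
oracle_brier_at <- function(surv_at_t, time, status, t) {
  n <- length(time)
  terms <- numeric(n)
  for (i in seq_len(n)) {
    if (time[i] <= t && status[i] == 1) {
      terms[i] <- surv_at_t[i]^2 / oracle_G_minus(time, status, time[i])
    } else if (time[i] > t) {
      terms[i] <- (1 - surv_at_t[i])^2 / oracle_G_at(time, status, t)
    }
  }
  mean(terms)
}

# Nelson-Aalen cumulative hazard, independently coded
oracle_nelson_aalen <- function(time, status) {
  et <- sort(unique(time[status == 1]))
  H <- cumsum(vapply(et, function(t)
    sum(time == t & status == 1) / sum(time >= t), 1))
  list(time = et, hazard = H)
}

# exhaustive maximal three-group logrank search via survival::survdiff
oracle_best_cutpoints <- function(score, time, status, min_frac = 0.1) {
  n <- length(score)
  min_size <- max(1L, floor(min_frac * n))
  ss <- sort(unique(score))
  cands <- (ss[-1] + ss[-length(ss)]) / 2
  best <- list(chi2 = -Inf)
  for (c1 in cands) for (c2 in cands) {
    if (c2 <= c1) next
    g <- cut(score, c(-Inf, c1, c2, Inf), labels = c("L", "I", "H"))
    if (min(table(g)) < min_size) next
    sd <- survival::survdiff(survival::Surv(time, status) ~ g)
    if (sd$chisq > best$chi2)
      best <- list(chi2 = sd$chisq, cut1 = c1, cut2 = c2)
  }
  best
}

# small survival fixture with a known signal
make_surv_fixture <- function(n, seed, beta = c(1, -0.8, 0, 0),
                              censor = 0.3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, paste0("x", seq_along(beta))))
    eta <- drop(X %*% beta)
    Tt <- rexp(n, rate = 0.3 * exp(eta))
    C <- if (censor > 0) runif(n, 0, quantile(Tt, 0.9) / censor) else
      rep(Inf, n)
    list(X = X, time = pmin(Tt, C), status = as.numeric(Tt <= C),
         eta = eta)
  })
}

# two-block dataset builder for fit-level tests
make_two_block_dataset <- function(n, p1, p2, seed,
                                   family = "continuous",
                                   beta1 = NULL, beta2 = NULL,
                                   noise_sd = 1) {
  beta1 <- beta1 %||% c(rep(1, min(2, p1)), rep(0, p1 - min(2, p1)))
  beta2 <- beta2 %||% rep(0, p2)
  sim <- simulate_dataset(sim_config(
    n = n, block_sizes = c(A = p1, B = p2), beta = list(beta1, beta2),
    family = family, noise_sd = noise_sd, censoring_rate = 0.3,
    seed = seed))
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a
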