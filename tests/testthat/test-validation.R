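test_that("Uno's C-index handles perfect, uninformative and censored data", {
  # no censoring, score perfectly rank-concordant with shorter survival
  tt <- c(1, 2, 3, 4, 5)
  st <- rep(1, 5)
  expect_equal(uno_c(5:1, tt, st, tau = 6), 1)
  expect_equal(uno_c(rep(2, 5), tt, st, tau = 6), 0.5)
  # antisymmetry on censoring-free data
  withr::local_seed(8)
  sc <- rnorm(12); t2 <- rexp(12)
  expect_equal(uno_c(-sc, t2, rep(1, 12), tau = max(t2) + 1),
               1 - uno_c(sc, t2, rep(1, 12), tau = max(t2) + 1))
})

test_that("Uno's C-index equals brute-force pair enumeration under censoring", {
  time <- c(0.5, 1.2, 1.2, 2.0, 3.1, 4.0)
  status <- c(1, 1, 0, 1, 0, 1)
  score <- c(2.2, 1.0, 1.4, 0.3, -0.2, -1.0)
  tau <- 3.5
  expect_equal(uno_c(score, time, status, tau),
               oracle_uno_c(score, time, status, tau), tolerance = 1e-10)
  # larger random fixtures
  for (s in 1:5) {
    fx <- make_surv_fixture(10, seed = 300 + s)
    tau <- stats::median(fx$time)
    expect_equal(uno_c(fx$eta, fx$time, fx$status, tau),
                 oracle_uno_c(fx$eta, fx$time, fx$status, tau),
                 tolerance = 1e-10)
  }
})

test_that("Brier curves match oracle forecasts and hand-computed IPCW sums", {
  # perfect oracle forecast, no censoring: S jumps 1 -> 0 at the event
  tt <- c(1, 2, 3, 4)
  grid <- c(0.5, 1.5, 2.5, 3.5)
  S_perfect <- t(vapply(tt, function(ti) as.numeric(grid < ti),
                        numeric(4)))
  bc <- brier_curve(S_perfect, tt, rep(1, 4), grid)
  expect_equal(bc$brier, rep(0, 4))
  # degenerate forecast S = 1: BS(t) = fraction with event by t
  bc1 <- brier_curve(matrix(1, 4, 4), tt, rep(1, 4), grid)
  expect_equal(bc1$brier, c(0, 1, 2, 3) / 4)
  # censored fixture vs independent per-term computation
  time <- c(0.5, 1.0, 1.5, 2.5, 3.0)
  status <- c(1, 0, 1, 1, 0)
  withr::local_seed(14)
  S <- matrix(runif(5 * 3, 0.2, 0.95), 5, 3)
  S <- t(apply(S, 1, function(r) sort(r, decreasing = TRUE)))
  times3 <- c(0.75, 1.25, 2.75)
  bc2 <- brier_curve(S, time, status, times3)
  for (j in 1:3)
    expect_equal(bc2$brier[j],
                 oracle_brier_at(S[, j], time, status, times3[j]),
                 tolerance = 1e-10)
  # invariance under sample relabeling; IBS nonnegative
  perm <- c(3, 1, 5, 2, 4)
  bc3 <- brier_curve(S[perm, ], time[perm], status[perm], times3)
  expect_equal(bc3$brier, bc2$brier, tolerance = 1e-12)
  expect_gte(integrated_brier(bc2), 0)
})

test_that("integrated Brier score is the trapezoidal time average", {
  curve <- data.frame(time = c(0, 1, 2), brier = c(0, 0.2, 0.1))
  expect_equal(integrated_brier(curve, 2), (0.1 + 0.15) / 2)
  expect_equal(integrated_brier(curve, 1), 0.1)
})

test_that("calibration slope is exactly 1 in training and scale-equivariant", {
  fx <- make_surv_fixture(150, seed = 61)
  fit <- survival::coxph(survival::Surv(fx$time, fx$status) ~ fx$X,
                         ties = "breslow")
  lp <- drop(fx$X %*% coef(fit))
  expect_equal(calibration_slope(lp, fx$time, fx$status), 1,
               tolerance = 1e-6)
  s1 <- calibration_slope(fx$eta, fx$time, fx$status)
  s2 <- calibration_slope(2 * fx$eta, fx$time, fx$status)
  expect_equal(s2, s1 / 2, tolerance = 1e-6)
  expect_equal(optimism(s1, s2), s1 - s2)
})

test_that("an uninformative score has calibration slope near zero", {
  hits <- vapply(1:20, function(s) {
    fx <- make_surv_fixture(500, seed = 1200 + s, beta = rep(0, 3))
    sc <- withr::with_seed(5000 + s, rnorm(500))
    abs(calibration_slope(sc, fx$time, fx$status)) < 0.15
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("maximal-logrank cutpoints match exhaustive search and find clusters", {
  # 30-sample fixture: compare against brute force over all admissible pairs
  withr::local_seed(71)
  score <- rnorm(30)
  time <- rexp(30, 0.3 * exp(score))
  status <- rbinom(30, 1, 0.8)
  status[which.max(time)] <- 1
  rg <- logrank_cutpoints(score, time, status)
  oracle <- oracle_best_cutpoints(score, time, status)
  expect_equal(rg$chi2, oracle$chi2, tolerance = 1e-8)
  expect_equal(rg$cut1, oracle$cut1, tolerance = 1e-12)
  expect_equal(rg$cut2, oracle$cut2, tolerance = 1e-12)

  # three well-separated clusters with strongly distinct hazards
  withr::local_seed(72)
  n3 <- 50
  sc3 <- c(rnorm(n3, -5, 0.3), rnorm(n3, 0, 0.3), rnorm(n3, 5, 0.3))
  rate <- rep(c(0.05, 0.5, 5), each = n3)
  t3 <- rexp(3 * n3, rate)
  rg3 <- logrank_cutpoints(sc3, t3, rep(1, 3 * n3))
  cl <- rep(1:3, each = n3)
  # the low-hazard cluster is recovered exactly and the high-hazard
  # cluster lands entirely in the high-risk group; the maximal statistic
  # dominates the clean between-cluster split by construction
  expect_gt(rg3$cut1, -4.5); expect_lt(rg3$cut1, -0.7)
  expect_true(all(rg3$groups[cl == 1] == "low"))
  expect_true(all(rg3$groups[cl == 3] == "high"))
  g_clean <- cut(sc3, c(-Inf, -2.5, 2.5, Inf))
  chi_clean <- survival::survdiff(
    survival::Surv(t3, rep(1, 3 * n3)) ~ g_clean)$chisq
  expect_gte(rg3$chi2, chi_clean - 1e-8)
  expect_equal(levels(rg3$groups), c("low", "intermediate", "high"))

  # invariant under strictly monotone transforms of the score
  rg3b <- logrank_cutpoints(exp(sc3 / 3), t3, rep(1, 3 * n3))
  expect_identical(as.integer(rg3$groups), as.integer(rg3b$groups))
  expect_equal(rg3b$chi2, rg3$chi2, tolerance = 1e-8)
})

test_that("null scores still yield admissible groups without crashing", {
  withr::local_seed(73)
  score <- rnorm(40)
  time <- rexp(40, 0.5)  # independent of the score
  rg <- logrank_cutpoints(score, time, rep(1, 40))
  expect_true(all(table(rg$groups) >= 4))  # 10% of n
  expect_error(logrank_cutpoints(rnorm(5), rexp(5), rep(1, 5),
                                 min_frac = 0.4),
               class = "priorlasso_too_few_samples")
})

test_that("risk-group hazard ratios separate groups and flag empty ones", {
  withr::local_seed(81)
  n <- 100
  g <- factor(rep(c("low", "intermediate", "high"), each = n),
              levels = c("low", "intermediate", "high"))
  t3 <- rexp(3 * n, rep(c(0.1, 0.5, 2.0), each = n))
  hr <- group_hazard_ratios(g, t3, rep(1, 3 * n))
  expect_lt(hr$hr_low, 1); expect_gt(hr$hr_high, 1)
  expect_lt(hr$lr_p, 0.001)
  # CIs contain their point estimates
  expect_true(hr$ci_low[1] < hr$hr_low && hr$hr_low < hr$ci_low[2])
  expect_true(hr$ci_high[1] < hr$hr_high && hr$hr_high < hr$ci_high[2])
  # identical survival in all groups: HRs near 1 in most replicates
  hits <- vapply(1:10, function(s) {
    withr::with_seed(2000 + s, {
      tt <- rexp(600, 0.4)
      gg <- factor(rep(c("low", "intermediate", "high"), each = 200),
                   levels = c("low", "intermediate", "high"))
      h <- group_hazard_ratios(gg, tt, rep(1, 600))
      h$hr_low > 0.7 && h$hr_low < 1.4 && h$hr_high > 0.7 &&
        h$hr_high < 1.4
    })
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  st <- rep(1, 3 * n); st[g == "low"] <- 0
  expect_error(group_hazard_ratios(g, t3, st),
               class = "priorlasso_empty_group_events")
})

test_that("horizon TPR/TNR/AUC follow hand counts and null behaviour", {
  # perfect split: every death above the median, every survivor below
  time <- c(0.5, 1.0, 1.5, 3, 4, 5)
  status <- c(1, 1, 1, 0, 0, 0)
  score <- c(3, 2.5, 2, 1, 0.5, 0)
  m <- binary_metrics_at(score, time, status, horizon = 2)
  expect_equal(c(m$tpr, m$tnr, m$auc), c(1, 1, 1))

  # 8-subject fixture, hand-counted (horizon 2, cutoff = median = 1.1):
  # cases: subjects 1,2 (scores 2.0, 0.8) -> TPR 1/2
  # controls: subjects 5..8 (scores 1.5, 0.9, 0.2, -0.3) -> TNR 3/4
  # censored before horizon (subjects 3,4) excluded
  time8 <- c(0.7, 1.8, 0.9, 1.5, 2.5, 3.0, 4.0, 5.0)
  stat8 <- c(1, 1, 0, 0, 1, 0, 1, 0)
  sc8 <- c(2.0, 0.8, 1.3, 1.2, 1.5, 0.9, 0.2, -0.3)
  m8 <- binary_metrics_at(sc8, time8, stat8, horizon = 2,
                          cutoff = median(sc8))
  expect_equal(m8$tpr, 1 / 2)
  expect_equal(m8$tnr, 3 / 4)
  # AUC: pairs (case, control), case ranked higher:
  # case 2.0 beats 1.5, 0.9, 0.2, -0.3 (4); case 0.8 beats 0.2, -0.3 (2)
  expect_equal(m8$auc, 6 / 8)
  expect_equal(m8$n_cases, 2); expect_equal(m8$n_controls, 4)

  # score independent of outcome: AUC near 1/2 in most replicates
  hits <- vapply(1:20, function(s) {
    withr::with_seed(3000 + s, {
      tt <- rexp(400, 0.5)
      sc <- rnorm(400)
      abs(binary_metrics_at(sc, tt, rep(1, 400), horizon = 1)$auc -
            0.5) < 0.05
    })
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("the full validation report satisfies its type invariants", {
  train <- simulate_dataset(aml_like_preset(scale = 0.003, n = 180,
                                            seed = 91))
  val <- simulate_dataset(aml_like_preset(scale = 0.003, n = 150,
                                          seed = 92))
  fit <- priority_lasso(train$dataset,
                        fit_options(seed = 7, nfolds_lambda = 5))
  rep <- validate_model(fit, train$dataset, val$dataset, horizon = 2)
  expect_true(all(c(rep$tpr, rep$tnr, rep$auc, rep$uno_c) >= 0))
  expect_true(all(c(rep$tpr, rep$tnr, rep$auc, rep$uno_c) <= 1))
  expect_gte(rep$ibs_horizon, 0); expect_gte(rep$ibs_last, 0)
  expect_true(rep$ci_low[1] < rep$hr_low & rep$hr_low < rep$ci_low[2])
  expect_true(rep$ci_high[1] < rep$hr_high & rep$hr_high < rep$ci_high[2])
  expect_true(rep$lr_p >= 0 && rep$lr_p <= 1)
  expect_equal(rep$optimism, rep$slope_train - rep$slope_val)
  tab <- as.data.frame(rep)
  expect_equal(nrow(tab), 14L)
  expect_true(all(is.finite(tab$value)))
})
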