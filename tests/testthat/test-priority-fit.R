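test_that("a one-block hierarchy reduces to a standard Lasso fit", {
  withr::local_seed(17)
  n <- 80
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("g", 1:6)))
  y <- drop(x %*% c(1, -1, 0.5, 0, 0, 0) + rnorm(n))
  ds <- pl_dataset(x, block_spec(list(all = colnames(x))),
                   outcome_continuous(y))
  opts <- fit_options(seed = 8)
  fit <- priority_lasso(ds, opts)
  foldid <- make_folds(n, 10, seed = opts$seed + 1L)
  oracle <- glmnet::cv.glmnet(x, y, foldid = foldid, type.measure = "mse")
  expect_equal(fit$step_fits[[1]]$lambda, oracle$lambda.min)
  expect_lt(max(abs(coef(fit) -
                      as.numeric(coef(oracle, s = "lambda.min"))[-1])),
            1e-10)
})

test_that("step 2 equals an independent Lasso on the step-1 residuals", {
  sim <- make_two_block_dataset(100, 4, 6, seed = 23,
                                beta1 = c(1, -1, 0, 0),
                                beta2 = c(0.5, rep(0, 5)))
  ds <- sim$dataset
  opts <- fit_options(seed = 5)
  fit <- priority_lasso(ds, opts)
  s1 <- fit$step_fits[[1]]
  s2 <- fit$step_fits[[2]]
  eta1 <- s1$intercept + drop(ds$X[, names(s1$coefficients)] %*%
                                s1$coefficients)
  resid <- ds$outcome$y - eta1
  x2 <- ds$X[, names(s2$coefficients)]
  foldid <- make_folds(nrow(ds$X), 10, seed = opts$seed + 2L)
  oracle <- glmnet::cv.glmnet(x2, resid, foldid = foldid,
                              type.measure = "mse")
  cf <- as.numeric(coef(oracle, s = s2$lambda))[-1]
  expect_lt(max(abs(s2$coefficients - cf)), 1e-6)
})

test_that("the final score decomposes exactly into block contributions", {
  sim <- simulate_dataset(sim_config(
    n = 90, block_sizes = c(A = 3, B = 5, C = 4),
    beta = list(c(1, 0, 0), c(0.4, -0.4, 0, 0, 0), rep(0, 4)),
    family = "survival", censoring_rate = 0.3, seed = 31))
  fit <- priority_lasso(sim$dataset, fit_options(seed = 6))
  sc <- linear_score(fit, sim$dataset$X)
  expect_lt(max(abs(sc$score - (sc$intercept + rowSums(sc$by_block)))),
            1e-10)
  expect_equal(unname(sc$score), unname(fit$train_score),
               tolerance = 1e-10)
})

test_that("an all-zero step passes its offset through unchanged", {
  # pure-noise block in a survival model: no intercept, so a null block
  # must leave the cross-validated offsets exactly equal to the prior ones
  withr::local_seed(3)
  n <- 80
  x1 <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("a1", "a2")))
  x2 <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("b", 1:5)))
  eta <- drop(x1 %*% c(1.2, -1.2))
  Tt <- rexp(n, 0.3 * exp(eta))
  ds <- pl_dataset(cbind(x1, x2),
                   block_spec(list(A = colnames(x1), B = colnames(x2))),
                   outcome_survival(Tt, rep(1, n)))
  opts <- fit_options(seed = 19, lambda_rule = "1se", nfolds_offset = 5)
  prior <- drop(x1 %*% c(1, -1))
  rec <- compute_cv_offsets(ds, 2, prior, opts)
  all_zero <- all(vapply(rec$fold_coefficients,
                         function(b) all(b == 0), TRUE))
  expect_true(all_zero)
  expect_identical(rec$contribution, rep(0, n))
  expect_identical(rec$offsets, prior)
})

test_that("cross-validated offsets agree with explicit fold-exclusion refits", {
  sim <- make_two_block_dataset(60, 3, 4, seed = 41,
                                beta1 = c(1, -1, 0),
                                beta2 = c(0.6, rep(0, 3)))
  ds <- sim$dataset
  opts <- fit_options(seed = 9, nfolds_offset = 5, nfolds_lambda = 5)
  rec <- compute_cv_offsets(ds, 1, rep(0, 60), opts)
  x1 <- ds$X[, ds$spec$blocks[[ds$spec$priority[1]]]]
  y <- ds$outcome$y
  recon <- numeric(60)
  for (k in 1:5) {
    tr <- which(rec$foldid != k)
    # explicit fold-exclusion refit: cross-validate lambda on S \ S_k with
    # the recorded inner folds, select, and score the held-out fold
    cvf <- glmnet::cv.glmnet(x1[tr, ], y[tr],
                             foldid = rec$fold_inner_foldid[[k]],
                             type.measure = "mse")
    lam <- select_lambda(list(lambda = cvf$lambda, cvm = cvf$cvm,
                              cvsd = cvf$cvsd), "min")
    expect_equal(lam, rec$fold_lambda[k])
    cf <- as.numeric(coef(cvf$glmnet.fit, s = lam))
    expect_equal(unname(rec$fold_coefficients[[k]]), cf[-1],
                 tolerance = 1e-12)
    expect_equal(rec$fold_intercepts[k], cf[1], tolerance = 1e-12)
    recon[-tr] <- cf[1] + drop(x1[-tr, ] %*% cf[-1])
  }
  # offsets are exactly prior + fold-external score of the excluded fits
  expect_identical(rec$offsets, rec$contribution)
  expect_equal(rec$contribution, recon, tolerance = 1e-12)

  rec2 <- compute_cv_offsets(ds, 1, rep(0, 60), opts)
  expect_identical(rec, rec2)  # seeded determinism
})

test_that("cv-offset models keep full-data coefficients and are deterministic", {
  sim <- make_two_block_dataset(70, 3, 4, seed = 47,
                                beta1 = c(1, 0, 0), beta2 = rep(0, 4))
  opts <- fit_options(seed = 2, cv_offsets = TRUE, nfolds_offset = 5)
  f1 <- priority_lasso(sim$dataset, opts)
  f2 <- priority_lasso(sim$dataset, opts)
  expect_identical(coef(f1), coef(f2))
  # step 1 has no offset, so its coefficients match the plain variant
  f_plain <- priority_lasso(sim$dataset,
                            fit_options(seed = 2, cv_offsets = FALSE))
  expect_identical(f1$step_fits[[1]]$coefficients,
                   f_plain$step_fits[[1]]$coefficients)
})

test_that("order selection is deterministic and respects candidate order", {
  sim <- make_two_block_dataset(80, 3, 3, seed = 53,
                                beta1 = c(1.2, -1, 0))
  ds <- sim$dataset
  opts <- fit_options(seed = 4, nfolds_lambda = 5)
  single <- choose_order(ds, list(c("A", "B")), opts)
  expect_equal(single$best_order, c("A", "B"))
  expect_length(single$cv_error, 1L)

  both <- choose_order(ds, list(c("A", "B"), c("B", "A")), opts)
  dup <- choose_order(ds, list(c("A", "B"), c("B", "A"),
                               c("A", "B"), c("B", "A")), opts)
  expect_equal(unname(dup$cv_error[1:2]), unname(both$cv_error))
  expect_equal(dup$best_order, both$best_order)
})

test_that("predictive blocks are exploited whichever priority they get", {
  # signal only in block A: the two orders reach similar CV error
  deltas <- vapply(1:8, function(s) {
    sim <- make_two_block_dataset(120, 4, 4, seed = 600 + s,
                                  beta1 = c(1.5, -1.5, 0, 0),
                                  noise_sd = 1)
    res <- choose_order(sim$dataset, list(c("A", "B"), c("B", "A")),
                        fit_options(seed = s, nfolds_lambda = 5))
    unname(abs(diff(res$cv_error)) / mean(res$cv_error))
  }, 1)
  expect_lt(mean(deltas), 0.25)
})
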