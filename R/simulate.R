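#' Configuration for the synthetic multi-omics generator
#'
#' The generator draws `latent_factors` standard-normal factors per sample;
#' each feature is a linear combination of its block's factors plus
#' independent Gaussian noise, scaled so that every continuous feature has
#' marginal variance `feature_var`. The per-block `loading_frac` sets the
#' fraction of a feature's variance carried by the shared factors -- blocks
#' loading on the same factors therefore carry redundant predictive signal,
#' the structure that motivates a priority order. Binary blocks threshold
#' the latent continuous feature at the `prevalence` quantile. The outcome
#' is generated from the true linear predictor
#' \eqn{\eta = \sum_m X^{(m)} \beta^{(m)}}: Gaussian noise (continuous),
#' a logistic link (binary), or a Weibull/exponential hazard
#' \eqn{h_0 t^{a-1} e^{\eta}} with independent uniform-window censoring
#' calibrated by bisection to the target censoring rate (survival).
#'
#' @param n Sample count.
#' @param block_sizes Integer vector `p_1..p_M` (optionally named; names
#'   become block names).
#' @param block_types Per block, `"continuous"` or `"binary"` (recycled).
#' @param latent_factors Number of shared latent factors `L`.
#' @param factor_map Per block, integer vector of the factor indices the
#'   block loads on (default: all factors).
#' @param loading_frac Per-block fraction in `[0, 1)` of feature variance
#'   explained by the shared factors (recycled; 0 = independent features).
#' @param loadings Optional list of explicit `p_m x L` loading matrices,
#'   overriding `factor_map`/`loading_frac` for the given blocks.
#' @param beta List of true coefficient vectors, one per block (defaults to
#'   all zero).
#' @param family Outcome family.
#' @param noise_sd Gaussian noise SD for the continuous outcome; ignored if
#'   `snr` is given, in which case `noise_sd = sd(eta)/sqrt(snr)`.
#' @param snr Optional signal-to-noise ratio (continuous family).
#' @param baseline_hazard,weibull_shape Survival hazard
#'   \eqn{h_0 a t^{a-1} e^\eta} scale and shape (shape 1 = exponential).
#' @param censoring_rate Target fraction censored, in `[0, 1)`.
#' @param prevalence Per-block prevalence of binary features (recycled).
#' @param feature_var Marginal variance of continuous features.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, block_sizes, block_types = "continuous",
                       latent_factors = 2L, factor_map = NULL,
                       loading_frac = 0, loadings = NULL, beta = NULL,
                       family = c("continuous", "binary", "survival"),
                       noise_sd = 1, snr = NULL, baseline_hazard = 0.2,
                       weibull_shape = 1, censoring_rate = 0.3,
                       prevalence = 0.3, feature_var = 1, seed = 1L) {
  family <- match.arg(family)
  M <- length(block_sizes)
  pl_assert(M >= 1L && all(block_sizes >= 1), "invalid_config",
            "block_sizes must be positive")
  nm <- names(block_sizes) %||% paste0("block", seq_len(M))
  block_types <- rep_len(block_types, M)
  pl_assert(all(block_types %in% c("continuous", "binary")),
            "invalid_config", "block_types must be continuous or binary")
  loading_frac <- rep_len(loading_frac, M)
  pl_assert(all(loading_frac >= 0 & loading_frac < 1), "invalid_config",
            "loading_frac must lie in [0, 1)")
  prevalence <- rep_len(prevalence, M)
  beta <- beta %||% lapply(block_sizes, function(p) rep(0, p))
  pl_assert(length(beta) == M &&
              all(vapply(beta, length, 1L) == block_sizes),
            "invalid_config", "beta must match block_sizes")
  pl_assert(censoring_rate >= 0 && censoring_rate < 1, "invalid_config",
            "censoring_rate must lie in [0, 1)")
  pl_assert(n >= 2 && latent_factors >= 1, "invalid_config",
            "need n >= 2 and at least one latent factor")
  factor_map <- factor_map %||%
    rep(list(seq_len(latent_factors)), M)
  structure(list(n = as.integer(n), block_sizes = as.integer(block_sizes),
                 block_names = nm, block_types = block_types,
                 latent_factors = as.integer(latent_factors),
                 factor_map = factor_map, loading_frac = loading_frac,
                 loadings = loadings, beta = beta, family = family,
                 noise_sd = noise_sd, snr = snr,
                 baseline_hazard = baseline_hazard,
                 weibull_shape = weibull_shape,
                 censoring_rate = censoring_rate, prevalence = prevalence,
                 feature_var = feature_var, seed = as.integer(seed)),
            class = "sim_config")
}

# default loading matrix: features cycle over the block's factors, each row
# carrying sqrt(frac * feature_var) on its factor
default_loadings <- function(p, L, map, frac, feature_var) {
  lam <- matrix(0, p, L)
  if (frac > 0 && length(map))
    lam[cbind(seq_len(p), rep_len(map, p))] <- sqrt(frac * feature_var)
  lam
}

#' Generate a synthetic multi-omics dataset
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a [pl_dataset()], priority = block order of
#'   the config) and `truth`: `beta` (named per-feature true coefficients),
#'   `eta` (true linear predictor), `factors` (n x L latent matrix),
#'   `loadings`, and for survival `censoring_realized`.
#' @export
simulate_dataset <- function(config) {
  pl_assert(inherits(config, "sim_config"), "invalid_config",
            "`config` must be a sim_config")
  cf <- config
  M <- length(cf$block_sizes)
  withr::with_seed(cf$seed, {
    Z <- matrix(stats::rnorm(cf$n * cf$latent_factors), cf$n)
    blocks <- vector("list", M)
    lam_list <- vector("list", M)
    for (m in seq_len(M)) {
      p <- cf$block_sizes[m]
      lam <- cf$loadings[[m]] %||%
        default_loadings(p, cf$latent_factors, cf$factor_map[[m]],
                         cf$loading_frac[m], cf$feature_var)
      pl_assert(all(rowSums(lam^2) <= cf$feature_var + 1e-12),
                "invalid_config",
                "loading rows must not exceed the feature variance")
      noise_var <- pmax(cf$feature_var - rowSums(lam^2), 0)
      X <- Z %*% t(lam) +
        matrix(stats::rnorm(cf$n * p), cf$n) %*% diag(sqrt(noise_var), p)
      if (cf$block_types[m] == "binary") {
        thr <- stats::qnorm(1 - cf$prevalence[m],
                            sd = sqrt(cf$feature_var))
        X <- (X > thr) + 0
      }
      colnames(X) <- paste0(cf$block_names[m], "_f", seq_len(p))
      blocks[[m]] <- X
      lam_list[[m]] <- lam
    }
    Xall <- do.call(cbind, blocks)
    eta <- drop(Xall %*% unlist(cf$beta))
    outc <- switch(cf$family,
      continuous = {
        sdv <- if (!is.null(cf$snr)) {
          s <- stats::sd(eta)
          pl_assert(s > 0, "invalid_config",
                    "snr needs a non-degenerate linear predictor")
          s / sqrt(cf$snr)
        } else cf$noise_sd
        outcome_continuous(eta + stats::rnorm(cf$n, sd = sdv))
      },
      binary = outcome_binary(stats::rbinom(cf$n, 1,
                                            stats::plogis(eta))),
      survival = {
        a <- cf$weibull_shape
        E <- stats::rexp(cf$n)
        Tt <- (E / (cf$baseline_hazard * exp(eta)))^(1 / a)
        if (cf$censoring_rate > 0) {
          u <- calibrate_censoring(Tt, cf$censoring_rate)
          C <- stats::runif(cf$n, 0, u)
          outcome_survival(pmin(Tt, C), as.numeric(Tt <= C))
        } else {
          outcome_survival(Tt, rep(1, cf$n))
        }
      })
    spec <- block_spec(stats::setNames(lapply(blocks, colnames),
                                       cf$block_names))
    ds <- pl_dataset(Xall, spec, outc)
    truth <- list(beta = stats::setNames(unlist(cf$beta), colnames(Xall)),
                  eta = eta, factors = Z, loadings = lam_list)
    if (cf$family == "survival")
      truth$censoring_realized <- mean(outc$status == 0)
    list(dataset = ds, truth = truth)
  })
}

# choose the uniform-censoring upper bound by bisection so that the
# expected censored fraction given the drawn event times hits the target:
# P(C < T) with C ~ U(0, u) is min(T/u, 1)
calibrate_censoring <- function(Tt, target) {
  f <- function(u) mean(pmin(Tt / u, 1)) - target
  lo <- min(Tt) * 1e-3
  hi <- max(Tt) * 1e3
  if (f(hi) > 0) return(hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' A study-shaped simulation preset
#'
#' Emulates the shape of a multi-omics AML survival study: a 2-indicator
#' prioritized risk-score block, 8 clinical covariates, 40 binary mutation
#' indicators, and a large continuous expression block of
#' `round(15809 * scale)` features; roughly 50% censoring. Predictive
#' signal is shared between the score and clinical blocks (common latent
#' factors) and between the mutation and expression blocks, so the priority
#' order genuinely matters.
#'
#' @param scale Scale factor for the expression block (1 = full size).
#' @param n Sample count (default 447).
#' @param seed Seed.
#' @return A [sim_config()].
#' @export
aml_like_preset <- function(scale = 1, n = 447L, seed = 1L) {
  pl_assert(scale > 0, "invalid_config", "scale must be positive")
  p4 <- max(1L, as.integer(round(15809 * scale)))
  sizes <- c(risk_score = 2L, clinical = 8L, mutations = 40L,
             expression = p4)
  beta <- list(
    risk_score = c(0.9, 1.4),
    clinical = c(0.35, 0.28, 0.17, -0.08, rep(0, 4)),
    mutations = c(0.35, 0.3, rep(0, 38)),
    expression = c(utils::head(c(0.12, 0.1, -0.1), p4),
                   rep(0, max(0L, p4 - 3L))))
  sim_config(
    n = n, block_sizes = sizes,
    block_types = c("binary", "continuous", "binary", "continuous"),
    latent_factors = 4L,
    factor_map = list(1:2, 1:2, 3:4, 3:4),
    loading_frac = c(0.5, 0.35, 0.3, 0.3),
    beta = beta, family = "survival",
    baseline_hazard = 0.18, weibull_shape = 1,
    censoring_rate = 0.5,
    prevalence = c(0.35, 0.3, 0.15, 0.3),
    seed = seed)
}
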