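#' Fitting options for the prioritized block-wise Lasso
#'
#' @param cv_offsets Logical; if `TRUE`, the offset passed from each step to
#'   the next is cross-validated: each sample's offset contribution is
#'   computed from a fit that excluded that sample's fold, counteracting the
#'   over-optimism of in-sample linear scores. The reported coefficients of
#'   every step are always the full-data estimates.
#' @param nfolds_lambda Folds for the per-step penalty (lambda) selection
#'   cross-validation (default 10).
#' @param nfolds_offset Folds for the offset cross-validation (default 10);
#'   uses a partition distinct from the lambda folds.
#' @param lambda_rule `"min"` (penalty of minimal mean CV error) or `"1se"`
#'   (largest penalty with CV error within one standard error of the
#'   minimum; sparser).
#' @param max_nonzero Per-block cap on the number of non-zero coefficients:
#'   `NULL` (unlimited), a single number recycled over blocks, or a vector of
#'   length `M` in priority order (`NA` entries = unlimited).
#' @param penalize_first_block Logical; if `FALSE` the block of highest
#'   priority is fitted unpenalized by ordinary least squares / logistic /
#'   Cox regression (requires `p < n` in that block).
#' @param standardize Logical; standardize features to unit variance inside
#'   the solver (coefficients are always returned on the original covariate
#'   scale).
#' @param seed Integer seed governing every random fold assignment of the
#'   fit.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(cv_offsets = FALSE, nfolds_lambda = 10L,
                        nfolds_offset = 10L,
                        lambda_rule = c("min", "1se"), max_nonzero = NULL,
                        penalize_first_block = TRUE, standardize = TRUE,
                        seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  pl_assert(is_count(nfolds_lambda) && nfolds_lambda >= 2, "invalid_options",
            "nfolds_lambda must be an integer >= 2")
  pl_assert(is_count(nfolds_offset) && nfolds_offset >= 2, "invalid_options",
            "nfolds_offset must be an integer >= 2")
  pl_assert(is.null(max_nonzero) ||
              (is.numeric(max_nonzero) && all(is.na(max_nonzero) |
                                                max_nonzero >= 0)),
            "invalid_options", "max_nonzero must be NULL or nonnegative")
  pl_assert(is_count(seed), "invalid_options", "seed must be an integer")
  structure(list(cv_offsets = isTRUE(cv_offsets),
                 nfolds_lambda = as.integer(nfolds_lambda),
                 nfolds_offset = as.integer(nfolds_offset),
                 lambda_rule = lambda_rule,
                 max_nonzero = max_nonzero,
                 penalize_first_block = isTRUE(penalize_first_block),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "fit_options")
}

# cap for the block at priority position m, or Inf
max_nonzero_at <- function(options, m, M) {
  mx <- options$max_nonzero
  if (is.null(mx)) return(Inf)
  if (length(mx) == 1L) mx <- rep(mx, M)
  pl_assert(length(mx) == M, "invalid_options",
            "max_nonzero must have length 1 or M")
  v <- mx[m]
  if (is.na(v)) Inf else v
}
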