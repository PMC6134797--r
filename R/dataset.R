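#' Assemble a dataset of covariates, block structure and outcome
#'
#' Validates that the covariate matrix is numeric and complete, that its
#' columns are exactly the features named by the block specification (in any
#' order; columns are re-indexed to the specification's priority order), and
#' that the outcome length matches the sample count. Missing values are
#' rejected, not imputed; categorical covariates must be pre-encoded as
#' numeric indicator columns.
#'
#' @param X Numeric matrix or data frame, samples in rows, named feature
#'   columns.
#' @param spec A [block_spec()].
#' @param outcome A `pl_outcome` (see [outcome_continuous()]).
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to the row names of `X` or `"s1".."sn"`.
#' @return An object of class `pl_dataset` with elements `X` (columns in
#'   priority-block order), `spec`, `outcome`, `sample_ids`.
#' @export
pl_dataset <- function(X, spec, outcome, sample_ids = NULL) {
  pl_assert(inherits(spec, "block_spec"), "invalid_blockspec",
            "`spec` must be a block_spec")
  pl_assert(inherits(outcome, "pl_outcome"), "invalid_outcome",
            "`outcome` must be a pl_outcome")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  pl_assert(!is.null(colnames(X)) && all(nzchar(colnames(X))),
            "unnamed_features", "X must have named columns")
  if (anyNA(X) || any(!is.finite(X)))
    pl_error("missing_values", "X contains missing or non-finite values")
  feats <- spec_features(spec)
  unknown <- setdiff(feats, colnames(X))
  if (length(unknown))
    pl_error("unknown_feature",
             paste0("block spec names features absent from the matrix: ",
                    paste(utils::head(unknown, 5L), collapse = ", ")))
  uncovered <- setdiff(colnames(X), feats)
  if (length(uncovered))
    pl_error("uncovered_feature",
             paste0("matrix columns not covered by the block spec: ",
                    paste(utils::head(uncovered, 5L), collapse = ", ")))
  pl_assert(n_samples(outcome) == nrow(X), "length_mismatch",
            "outcome length must equal the number of rows of X")
  sample_ids <- as.character(sample_ids %||% rownames(X) %||%
                               paste0("s", seq_len(nrow(X))))
  pl_assert(length(sample_ids) == nrow(X) && !anyDuplicated(sample_ids),
            "invalid_sample_ids", "sample ids must be unique, one per row")
  X <- X[, feats, drop = FALSE]
  rownames(X) <- sample_ids
  structure(list(X = X, spec = spec, outcome = outcome,
                 sample_ids = sample_ids),
            class = "pl_dataset")
}

# covariate submatrix of the block at priority position m
block_matrix <- function(dataset, m) {
  nm <- dataset$spec$priority[m]
  dataset$X[, dataset$spec$blocks[[nm]], drop = FALSE]
}

dataset_subset <- function(dataset, idx) {
  pl_dataset(dataset$X[idx, , drop = FALSE], dataset$spec,
             subset_outcome(dataset$outcome, idx),
             sample_ids = dataset$sample_ids[idx])
}

#' @export
print.pl_dataset <- function(x, ...) {
  cat(sprintf("priority-block dataset: %d samples x %d features\n",
              nrow(x$X), ncol(x$X)))
  print(x$spec)
  print(x$outcome)
  invisible(x)
}

#' Read a dataset from delimited text files
#'
#' `matrix_path` is a CSV with a header row; its first column holds sample
#' identifiers and the remaining numeric columns are features.
#' `outcome_path` is a CSV whose first column holds the same sample ids (rows
#' may appear in any order) followed by either a single outcome column
#' (continuous or binary) or `time` and `status` columns (survival).
#' `blockspec_path` is a YAML config as written by [write_block_spec()].
#'
#' @param matrix_path,outcome_path,blockspec_path File paths.
#' @param family `"auto"` (default) infers survival from the presence of
#'   `time`/`status` columns and binary from an all-0/1 outcome column;
#'   otherwise one of `"continuous"`, `"binary"`, `"survival"`.
#' @return A `pl_dataset`.
#' @export
read_dataset <- function(matrix_path, outcome_path, blockspec_path,
                         family = c("auto", "continuous", "binary",
                                    "survival")) {
  family <- match.arg(family)
  for (p in c(matrix_path, outcome_path, blockspec_path))
    pl_assert(file.exists(p), "missing_file", paste0("file not found: ", p))
  spec <- read_block_spec(blockspec_path)
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  pl_assert(ncol(raw) >= 2L, "invalid_matrix",
            "matrix file needs a sample-id column plus feature columns")
  ids <- as.character(raw[[1L]])
  Xd <- raw[, -1L, drop = FALSE]
  bad <- names(Xd)[!vapply(Xd, is.numeric, TRUE)]
  if (length(bad))
    pl_error("non_numeric_feature",
             paste0("non-numeric feature columns (pre-encode categoricals): ",
                    paste(utils::head(bad, 5L), collapse = ", ")))
  X <- as.matrix(Xd)
  rownames(X) <- ids

  odf <- utils::read.csv(outcome_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  oid <- as.character(odf[[1L]])
  pl_assert(setequal(oid, ids) && length(oid) == length(ids),
            "length_mismatch",
            "outcome file must contain exactly the matrix sample ids")
  odf <- odf[match(ids, oid), , drop = FALSE]
  has_surv <- all(c("time", "status") %in% names(odf))
  if (family == "auto")
    family <- if (has_surv) "survival" else {
      yv <- odf[[2L]]
      if (all(yv %in% c(0, 1))) "binary" else "continuous"
    }
  outc <- if (family == "survival") {
    pl_assert(has_surv, "invalid_outcome",
              "survival outcome requires `time` and `status` columns")
    outcome_survival(odf$time, odf$status)
  } else if (family == "binary") {
    outcome_binary(odf[[2L]])
  } else {
    outcome_continuous(odf[[2L]])
  }
  pl_dataset(X, spec, outc, sample_ids = ids)
}

#' Write a dataset to delimited text files
#'
#' Writes `matrix.csv`, `outcome.csv` and `blocks.yaml` (the formats read by
#' [read_dataset()]) into `dir`.
#'
#' @param dataset A `pl_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.csv"),
             outcome = file.path(dir, "outcome.csv"),
             blocks = file.path(dir, "blocks.yaml"))
  utils::write.csv(
    data.frame(sample_id = dataset$sample_ids,
               dataset$X, check.names = FALSE),
    paths[["matrix"]], row.names = FALSE)
  o <- dataset$outcome
  odf <- if (o$family == "survival") {
    data.frame(sample_id = dataset$sample_ids, time = o$time,
               status = o$status)
  } else {
    data.frame(sample_id = dataset$sample_ids, y = o$y)
  }
  utils::write.csv(odf, paths[["outcome"]], row.names = FALSE)
  write_block_spec(dataset$spec, paths[["blocks"]])
  invisible(paths)
}
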