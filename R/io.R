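#' Export a fitted model as a plain-text coefficient table
#'
#' Sparse penalized models are transportable: the fitted coefficients and
#' the names of the selected variables are all a user needs to apply the
#' model to new data. This writes a TSV with one row per non-zero
#' coefficient (`block_priority`, `block_name`, `feature`, `coefficient`,
#' full double precision) preceded by commented header lines carrying the
#' family, intercept, block structure and fitting options. The file
#' round-trips losslessly through [import_model()]: linear scores computed
#' from the re-imported model are bit-identical.
#'
#' @param model A fitted `priority_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_model <- function(model, path) {
  pl_assert(inherits(model, c("priority_model", "portable_model")),
            "unfitted_model", "`model` must be a fitted model object")
  spec <- model$spec
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# priorlasso model export")
  wl("# family: ", model$family)
  wl("# intercept: ", fmt_num(model$intercept))
  wl("# priority: ", paste(spec$priority, collapse = ","))
  for (nm in names(spec$blocks))
    wl("# block ", nm, ": ", paste(spec$blocks[[nm]], collapse = ","))
  if (!is.null(model$options))
    wl("# options: ",
       jsonlite::toJSON(model$options[c("cv_offsets", "lambda_rule",
                                        "nfolds_lambda", "nfolds_offset",
                                        "penalize_first_block",
                                        "standardize", "seed")],
                        auto_unbox = TRUE))
  wl("block_priority\tblock_name\tfeature\tcoefficient")
  cf <- model$coefficients
  for (m in seq_along(spec$priority)) {
    nm <- spec$priority[m]
    fe <- intersect(spec$blocks[[nm]], names(cf))
    fe <- fe[cf[fe] != 0]
    for (f in fe) wl(m, "\t", nm, "\t", f, "\t", fmt_num(cf[[f]]))
  }
  invisible(path)
}

#' Import a model exported by [export_model()]
#'
#' @param path Path to a model TSV.
#' @return Object of class `portable_model` (usable with [linear_score()]
#'   and [export_model()]): `family`, `intercept`, `spec`, `coefficients`
#'   (zeros filled in for unselected features).
#' @export
import_model <- function(path) {
  pl_assert(file.exists(path), "missing_file",
            paste0("model file not found: ", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    pl_assert(length(ln) == 1L, "invalid_model_file",
              paste0("model file lacks header field: ", key))
    sub(paste0("^# ", key, ": ?"), "", ln)
  }
  family <- get("family")
  intercept <- as.numeric(get("intercept"))
  priority <- strsplit(get("priority"), ",")[[1L]]
  blk_lines <- hdr[grepl("^# block ", hdr)]
  blocks <- list()
  for (ln in blk_lines) {
    body <- sub("^# block ", "", ln)
    nm <- sub(":.*$", "", body)
    blocks[[nm]] <- strsplit(sub("^[^:]*: ?", "", body), ",")[[1L]]
  }
  spec <- block_spec(blocks, priority = priority)
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  cf <- stats::setNames(rep(0, length(spec_features(spec))),
                        spec_features(spec))
  if (nrow(tab)) {
    pl_assert(all(tab$feature %in% names(cf)), "unknown_feature",
              "model file names features absent from its block spec")
    cf[tab$feature] <- as.numeric(tab$coefficient)
  }
  structure(list(family = family, intercept = intercept, spec = spec,
                 coefficients = cf, options = NULL),
            class = "portable_model")
}

#' Write / read a Breslow baseline hazard table
#'
#' @param baseline A [breslow_baseline()].
#' @param path TSV path.
#' @return `write_baseline` returns `path` invisibly; `read_baseline` a
#'   `breslow_baseline`.
#' @export
write_baseline <- function(baseline, path) {
  utils::write.table(
    data.frame(time = fmt_num(baseline$time),
               cumhaz = fmt_num(baseline$hazard)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  tab <- utils::read.delim(path)
  structure(list(time = as.numeric(tab$time),
                 hazard = as.numeric(tab$cumhaz)),
            class = "breslow_baseline")
}
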