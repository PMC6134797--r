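#' Define a block structure and priority order over covariates
#'
#' A block specification assigns every covariate to exactly one of `M` named
#' blocks and fixes a priority order over the blocks. The block of highest
#' priority is fitted first; predictive information shared between blocks is
#' attributed to the block that comes earlier in the order.
#'
#' @param blocks Named list; each element is a character vector of feature
#'   names belonging to that block. Every feature must occur in exactly one
#'   block.
#' @param priority Character vector: a permutation of `names(blocks)`, highest
#'   priority first. Defaults to the order of `blocks`.
#' @return An object of class `block_spec` with elements `blocks` (named list,
#'   kept in original order) and `priority` (character).
#' @examples
#' bs <- block_spec(list(clinical = c("age", "wbc"), expr = c("g1", "g2")),
#'                  priority = c("clinical", "expr"))
#' n_blocks(bs)
#' @export
block_spec <- function(blocks, priority = names(blocks)) {
  pl_assert(is.list(blocks) && length(blocks) >= 1L, "invalid_blockspec",
            "`blocks` must be a non-empty named list of feature vectors")
  pl_assert(!is.null(names(blocks)) && all(nzchar(names(blocks))) &&
              !anyDuplicated(names(blocks)), "invalid_blockspec",
            "blocks must have unique, non-empty names")
  blocks <- lapply(blocks, as.character)
  pl_assert(all(vapply(blocks, length, 1L) >= 1L), "empty_block",
            "every block must contain at least one feature")
  feats <- unlist(blocks, use.names = FALSE)
  dup <- feats[duplicated(feats)]
  if (length(dup))
    pl_error("duplicated_feature",
             paste0("feature assigned to more than one block: ",
                    paste(unique(dup), collapse = ", ")))
  pl_assert(is.character(priority) || is.numeric(priority),
            "invalid_priority", "`priority` must name or index the blocks")
  if (is.numeric(priority)) priority <- names(blocks)[priority]
  pl_assert(length(priority) == length(blocks) &&
              setequal(priority, names(blocks)) && !anyDuplicated(priority),
            "invalid_priority",
            "`priority` must be a permutation of the block names")
  structure(list(blocks = blocks, priority = as.character(priority)),
            class = "block_spec")
}

#' Number of blocks in a block specification
#' @param spec A `block_spec`.
#' @return Integer `M`.
#' @export
n_blocks <- function(spec) length(spec$blocks)

#' Features of a block specification, in priority order
#' @param spec A `block_spec`.
#' @return Character vector of all feature names, blocks concatenated in
#'   priority order.
#' @export
spec_features <- function(spec) {
  unlist(spec$blocks[spec$priority], use.names = FALSE)
}

# sizes p_m in priority order
spec_sizes <- function(spec) {
  vapply(spec$blocks[spec$priority], length, 1L)
}

#' @export
print.block_spec <- function(x, ...) {
  cat("Block specification:", length(x$blocks), "blocks\n")
  for (i in seq_along(x$priority)) {
    nm <- x$priority[i]
    cat(sprintf("  priority %d: %s (%d features)\n",
                i, nm, length(x$blocks[[nm]])))
  }
  invisible(x)
}

#' Read / write a block specification as a YAML config
#'
#' The file has two top-level keys: `blocks`, a mapping from block name to the
#' list of its feature names, and `priority`, the list of block names from
#' highest to lowest priority.
#'
#' @param path File path.
#' @return `read_block_spec` returns a `block_spec`.
#' @export
read_block_spec <- function(path) {
  pl_assert(file.exists(path), "missing_file",
            paste0("block spec file not found: ", path))
  cfg <- yaml::read_yaml(path)
  pl_assert(is.list(cfg) && !is.null(cfg$blocks), "invalid_blockspec",
            "block spec file must contain a `blocks` mapping")
  block_spec(lapply(cfg$blocks, as.character),
             priority = as.character(cfg$priority %||% names(cfg$blocks)))
}

#' @rdname read_block_spec
#' @param spec A `block_spec`.
#' @export
write_block_spec <- function(spec, path) {
  yaml::write_yaml(list(blocks = lapply(spec$blocks, as.list),
                        priority = as.list(spec$priority)), path)
  invisible(path)
}
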