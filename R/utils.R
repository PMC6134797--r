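# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed errors so callers/tests can distinguish validation failures
pl_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("priorlasso_", class), "priorlasso_error",
              "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

pl_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) pl_error(class, msg)
  invisible(TRUE)
}

# full-precision number formatting for plain-text round trips
fmt_num <- function(x) sprintf("%.17g", x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}
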