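#' @import data.table
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Missing-value token used throughout output tables.
NA_TOKEN <- "."

`%||%` <- function(x, y) if (is.null(x)) y else x

# ASCII-only lowercasing; annotation files are ASCII and this keeps
# case-insensitive matching locale-independent.
lc <- function(x) tolower(x)

abort_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("intervanno_data_error", "error")))
}

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("intervanno_config_error", "error")))
}

is_count_range <- function(x) {
  is.numeric(x) && length(x) %in% c(1L, 2L) && all(x >= 0) && !anyNA(x)
}

# Deterministic draw from an integer range given as c(lo, hi) or a scalar.
draw_range <- function(rng, n) {
  if (length(rng) == 1L) rep.int(as.integer(rng), n)
  else sample(seq.int(rng[1L], rng[2L]), n, replace = TRUE)
}
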