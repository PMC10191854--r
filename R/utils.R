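# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical key for a set of sample identifiers
#'
#' Sample subsets (mutation groups, tree nodes) are keyed by the sorted,
#' "+"-joined sample ids, so that set identity is a plain string comparison.
#'
#' @param samples character vector of sample ids.
#' @return a single string key.
#' @keywords internal
sample_key <- function(samples) {
  paste(sort(unique(as.character(samples))), collapse = "+")
}

#' @rdname sample_key
#' @param key a key produced by [sample_key()].
#' @keywords internal
key_samples <- function(key) {
  if (is.na(key) || !nzchar(key)) return(character(0))
  strsplit(key, "+", fixed = TRUE)[[1]]
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop(sprintf("`%s` must be a single non-negative integer, got %s",
                 name, deparse(substitute(x))), call. = FALSE)
  }
  invisible(x)
}

# Strict column check used by table readers and analysis entry points.
require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
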