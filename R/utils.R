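#' Round half away from zero
#'
#' Percentages in rendered tables are rounded half away from zero (so 18.45
#' prints as 18.5), not by banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# semicolon token lists <-> character vectors ------------------------------

split_tokens <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, ";", fixed = TRUE)
}

join_tokens <- function(lst) {
  vapply(lst, paste, character(1), collapse = ";")
}

has_tokens <- function(x) !is.na(x) & x != ""

n_tokens <- function(x) lengths(split_tokens(x))

tokens_valid <- function(x, valid) {
  vapply(split_tokens(x), function(t) all(t %in% valid), logical(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rowwise any/sum over a set of columns, robust to 0- and 1-row frames
row_any_cols <- function(df, cols, f) {
  Reduce(`|`, lapply(cols, function(cl) f(df[[cl]])),
         rep(FALSE, nrow(df)))
}

row_sum_cols <- function(df, cols, f) {
  Reduce(`+`, lapply(cols, function(cl) f(df[[cl]])),
         rep(0L, nrow(df)))
}
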