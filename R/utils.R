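#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), in the input
#' order. Thin validating wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`. `NA` is not allowed.
#' @return Numeric vector of FDR values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Inverse hyperbolic cosine count transform
#'
#' `y = acosh(1 + x)`: monotone, zero-preserving, variance-stabilising for
#' overdispersed counts; useful when area normalisation produces extreme
#' values from cells with tiny area estimates.
#'
#' @param x Nonnegative numeric vector or matrix.
#' @return Transformed values, same shape as `x`.
#' @export
acosh_transform <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (any(x < 0, na.rm = TRUE)) stop("acosh transform requires nonnegative input")
  acosh(1 + x)
}

# Deterministic child seed from a master seed and a counter, kept inside the
# 32-bit integer range so set.seed() accepts it.
child_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(index) * 69621) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop unless `df` has the named columns.
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
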