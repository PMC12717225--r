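# Composition features and morphological clustering: per-stratum substate
# fraction matrices, Ward clustering of samples, and the metadata
# association statistics (OLS and rank-sum, both BH-corrected).

#' Substate fraction matrix
#'
#' Per sample (or sample x subregion stratum), the percentage of cells in
#' each substate; rows sum to 100. Cells from excluded regions (intraluminal
#' thrombi by default) are dropped before tallying, and substates absent
#' from a stratum get 0.
#'
#' @param cells Cell data frame with `sample_id`, `substate` and (for
#'   stratified or exclusion use) `subregion`.
#' @param stratum `"sample"` or `"sample_region"`.
#' @param exclude_regions Regions whose cells are dropped; default
#'   `"thrombus"`.
#' @return Numeric matrix, strata x substates, percentages.
#' @export
substate_fractions <- function(cells, stratum = c("sample", "sample_region"),
                               exclude_regions = "thrombus") {
  stratum <- match.arg(stratum)
  check_columns(cells, c("sample_id", "substate"), "cells")
  if (length(exclude_regions) && "subregion" %in% names(cells)) {
    cells <- cells[!(cells$subregion %in% exclude_regions), , drop = FALSE]
  }
  key <- if (stratum == "sample") cells$sample_id else {
    check_columns(cells, "subregion", "cells")
    paste(cells$sample_id, cells$subregion, sep = ":")
  }
  if (!length(key)) stop("no cells left after exclusions")
  tab <- table(factor(key), factor(cells$substate))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty stratum/strata", sum(empty)))
    tab <- tab[!empty, , drop = FALSE]
  }
  m <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  m
}

#' Ward hierarchical clustering of samples on composition features
#'
#' Agglomerative clustering with Euclidean distance and Ward's linkage
#' (`hclust` method `"ward.D2"`, the variance-minimising criterion on
#' unsquared distances), cut at `k` clusters.
#'
#' @param features Numeric matrix, samples x features (e.g. a
#'   [substate_fractions()] matrix).
#' @param k Number of clusters.
#' @param zscore_columns Standardise columns first; default `FALSE` (raw
#'   percentages).
#' @return List with `hclust` (the merge tree), `k`, and `labels` (named
#'   integer cluster ids).
#' @export
ward_cluster <- function(features, k, zscore_columns = FALSE) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must not contain missing values")
  if (k > nrow(features)) stop("k cannot exceed the number of rows")
  if (zscore_columns) features <- scale(features)
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  list(hclust = hc, k = as.integer(k), labels = stats::cutree(hc, k = k))
}

#' Linear associations between per-sample numeric variables
#'
#' Ordinary least squares for each declared pair, with the slope's
#' two-sided t-test p-value, R², and BH correction across the family.
#'
#' @param data Per-sample data frame of numeric variables.
#' @param pairs Data frame (or 2-column matrix) of column-name pairs `x`,
#'   `y` declaring the tested family.
#' @return Data frame with `x`, `y`, `slope`, `r_squared`, `p`, `fdr`.
#' @export
associate_numeric <- function(data, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("x", "y")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- data[[pairs$x[i]]]; y <- data[[pairs$y[i]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("need at least 3 paired finite values")
    if (stats::sd(x) == 0) stop("zero variance in predictor ", pairs$x[i])
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    data.frame(x = pairs$x[i], y = pairs$y[i],
               slope = unname(stats::coef(fit)[2]),
               r_squared = s$r.squared,
               p = s$coefficients[2, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out
}

#' Rank-sum association between numeric variables and a two-level factor
#'
#' Two-sided Wilcoxon rank-sum test of each variable between the two factor
#' levels, BH-corrected across the family.
#'
#' @param data Per-sample data frame.
#' @param vars Character vector of numeric column names (the family).
#' @param group Name of a two-level grouping column.
#' @return Data frame with `variable`, `p`, `fdr`.
#' @export
associate_categorical <- function(data, vars, group) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("`group` must have exactly two levels")
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  p <- vapply(vars, function(v) {
    suppressWarnings(stats::wilcox.test(data[[v]][g == levels(g)[1]],
                                        data[[v]][g == levels(g)[2]],
                                        alternative = "two.sided"))$p.value
  }, numeric(1))
  data.frame(variable = vars, p = unname(p), fdr = bh_adjust(unname(p)),
             stringsAsFactors = FALSE)
}
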