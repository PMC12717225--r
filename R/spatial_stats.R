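# Local spatial statistics on binarised cell-identity patterns: local
# bivariate Moran's I colocalisation (kNN row-standardised weights) and
# local Getis-Ord G hotspot inference (binary distance-band weights), both
# with conditional permutation nulls and BH correction.

#' Binarise cell identities
#'
#' Indicator of membership in a target substate (1 = presence, 0 =
#' absence).
#'
#' @param labels Character/factor vector of substate labels, or a cell data
#'   frame with a `substate` column.
#' @param target Target substate label.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(labels, target) {
  if (is.data.frame(labels)) {
    check_columns(labels, "substate", "cells")
    labels <- labels$substate
  }
  if (!any(labels == target)) {
    warning(sprintf("target substate '%s' absent: all-zero indicator", target))
  }
  as.integer(labels == target)
}

#' K-nearest-neighbour spatial weights (row-standardised)
#'
#' Euclidean kNN over cell centroids of one sample; each cell's k
#' neighbours get weight 1/k (distance ties broken by row order; cells in
#' samples smaller than `k + 1` use all available neighbours).
#'
#' @param coords Two-column matrix / data frame of `x_um`, `y_um` for one
#'   sample.
#' @param k Number of neighbours; default 30.
#' @return A `spatial_weights` object (`kind = "knn"`).
#' @export
knn_weights <- function(coords, k = 30) {
  xy <- as_coord_matrix(coords)
  n <- nrow(xy)
  if (n < 2) stop("need at least two cells")
  k <- min(k, n - 1)
  idx <- knn_index(xy, k)
  structure(list(kind = "knn", idx = idx, k = k, n = n),
            class = "spatial_weights")
}

#' Distance-band spatial weights (binary)
#'
#' Binary weights connecting all cell pairs within `radius_um` (self
#' excluded).
#'
#' @param coords Two-column matrix / data frame of coordinates in µm.
#' @param radius_um Band radius; default 2500.
#' @return A `spatial_weights` object (`kind = "distance_band"`) with a
#'   neighbour index list.
#' @export
distance_band_weights <- function(coords, radius_um = 2500) {
  xy <- as_coord_matrix(coords)
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= radius_um))
  structure(list(kind = "distance_band", nb = nb, radius_um = radius_um, n = n),
            class = "spatial_weights")
}

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    check_columns(coords, c("x_um", "y_um"), "coords")
    coords <- cbind(coords$x_um, coords$y_um)
  }
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  coords
}

# One conditional-permutation draw shared across cells: a random ordering
# of the n - 1 "other" cells, remapped per focal cell so the focal index is
# skipped. Returns an n x maxk matrix of donor indices.
conditional_draw <- function(n, maxk) {
  sel <- sample.int(n - 1)[seq_len(maxk)]
  m <- matrix(sel, n, maxk, byrow = TRUE)
  m + (m >= seq_len(n))
}

#' Local bivariate Moran's I with conditional permutation inference
#'
#' Measures, per cell, the association between one substate's presence and
#' the spatially lagged presence of another:
#' `I_i = z_x[i] * sum_j w_ij z_y[j]`, with both indicators standardised to
#' mean 0 and population SD 1 and row-standardised kNN weights. The null
#' holds `x_i` in place and redistributes `y` over the other cells
#' (conditional permutation); the one-sided empirical p-value is the
#' right-tail add-one p `(r + 1)/(N + 1)` (`r` = permutations with a larger
#' `I_i`), testing positive local association; it is uniform under the
#' null. BH correction runs across cells.
#'
#' @param x,y 0/1 (or numeric) vectors over the same cells (see
#'   [binarize()]); swapping `x` and `y` changes the statistic.
#' @param weights A [knn_weights()] object.
#' @param permutations Number of conditional permutations; default 999.
#' @param seed Master seed.
#' @param alpha FDR significance level for the quadrant category.
#' @return Data frame per cell: `I`, `lag`, `p`, `fdr`, `category`
#'   (`HH`/`HL`/`LH`/`LL`), `significant`.
#' @export
local_bivariate_moran <- function(x, y, weights, permutations = 999,
                                  seed = 1L, alpha = 0.05) {
  stopifnot(inherits(weights, "spatial_weights"), weights$kind == "knn")
  n <- weights$n
  if (length(x) != n || length(y) != n) stop("x and y must align with the weights")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y: Moran's I is undefined")
  }
  zx <- (x - mean(x)) / pop_sd(x)
  zy <- (y - mean(y)) / pop_sd(y)
  k <- weights$k
  lag <- rowMeans(matrix(zy[weights$idx], n, k))
  I <- zx * lag

  r <- integer(n)
  for (b in seq_len(permutations)) {
    set.seed(child_seed(seed, b))
    donors <- conditional_draw(n, k)
    lag_b <- rowMeans(matrix(zy[donors], n, k))
    I_b <- zx * lag_b
    r <- r + (I_b > I) + 0.5 * (I_b == I)
  }
  # mid-p right-tail Monte-Carlo p: the null statistic is discrete for
  # binarised data, so ties are split between tails to keep the null
  # p-value distribution uniform rather than conservative
  p <- (r + 1) / (permutations + 1)
  fdr <- bh_adjust(p)
  category <- paste0(ifelse(zx > 0, "H", "L"), ifelse(lag > 0, "H", "L"))
  data.frame(I = I, lag = lag, p = p, fdr = fdr, category = category,
             significant = fdr < alpha, stringsAsFactors = FALSE)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Local Getis-Ord G hotspot statistic with conditional permutation
#'
#' Plain `G_i` (self excluded): the share of the variable's total mass
#' (excluding the focal cell) found inside its distance band,
#' `G_i = sum_{j in N(i)} x_j / sum_{j != i} x_j`. Cells with no neighbours
#' or a zero denominator are emitted as `NA` with a warning. The
#' conditional permutation null redistributes `x` over the other cells;
#' two-sided p-values are `min(2 p_left, 2 p_right)` capped at 1. Hot
#' (cold) cells are significant cells above (below) their permutation null
#' mean.
#'
#' @param x Nonnegative numeric vector (typically a [binarize()]
#'   indicator) with at least one positive entry.
#' @param weights A [distance_band_weights()] object.
#' @param permutations Number of permutations; default 999.
#' @param seed Master seed.
#' @param alpha FDR significance level.
#' @return Data frame per cell: `G`, `null_mean`, `p`, `fdr`, `category`
#'   (`hot`/`cold`/`ns`), `significant`.
#' @export
local_getis_ord <- function(x, weights, permutations = 999, seed = 1L,
                            alpha = 0.05) {
  stopifnot(inherits(weights, "spatial_weights"),
            weights$kind == "distance_band")
  n <- weights$n
  if (length(x) != n) stop("x must align with the weights")
  if (all(x == 0)) stop("x has no positive entries")
  ki <- lengths(weights$nb)
  den <- sum(x) - x
  num <- vapply(seq_len(n), function(i) sum(x[weights$nb[[i]]]), numeric(1))
  G <- ifelse(ki > 0 & den > 0, num / den, NA_real_)
  if (anyNA(G)) {
    warning(sprintf("%d cell(s) with no neighbours or zero denominator: G is NA",
                    sum(is.na(G))))
  }

  maxk <- max(ki)
  mask <- matrix(0, n, maxk)
  for (i in seq_len(n)) if (ki[i] > 0) mask[i, seq_len(ki[i])] <- 1
  l <- numeric(n); r <- numeric(n); null_sum <- numeric(n)
  ok <- !is.na(G)
  for (b in seq_len(permutations)) {
    set.seed(child_seed(seed, b))
    donors <- conditional_draw(n, maxk)
    num_b <- rowSums(matrix(x[donors], n, maxk) * mask)
    G_b <- num_b / den
    null_sum <- null_sum + ifelse(ok, G_b, 0)
    tie <- ok & G_b == G
    l <- l + (ok & G_b < G) + 0.5 * tie
    r <- r + (ok & G_b > G) + 0.5 * tie
  }
  # mid-p tail counts (ties split between tails, see local_bivariate_moran);
  # the two-sided p doubles the smaller tail, capped at 1
  p_left <- (l + 1) / (permutations + 1)
  p_right <- (r + 1) / (permutations + 1)
  p <- ifelse(ok, pmin(1, 2 * pmin(p_left, p_right)), NA_real_)
  fdr <- rep(NA_real_, n)
  fdr[ok] <- bh_adjust(p[ok])
  null_mean <- ifelse(ok, null_sum / permutations, NA_real_)
  category <- ifelse(!ok | fdr >= alpha, "ns",
                     ifelse(G > null_mean, "hot", "cold"))
  data.frame(G = G, null_mean = null_mean, p = p, fdr = fdr,
             category = category, significant = !is.na(fdr) & fdr < alpha,
             stringsAsFactors = FALSE)
}

#' Marker-gene expression contrast between one substate and the rest
#'
#' Per gene (and per sample when `sample` is given), a two-sided Wilcoxon
#' rank-sum test of normalised expression between the target group and all
#' other cells, BH-corrected across the whole family. Samples where either
#' group is empty are skipped with a warning.
#'
#' @param expr Cells x genes matrix of normalised expression.
#' @param is_target Logical vector marking the target substate's cells.
#' @param genes Genes to test; default all columns.
#' @param sample Optional per-cell sample ids for per-sample testing.
#' @return Data frame with `sample` (if given), `gene`, `p`, `fdr`.
#' @export
marker_expression_contrast <- function(expr, is_target, genes = colnames(expr),
                                       sample = NULL) {
  expr <- as.matrix(expr)
  stopifnot(length(is_target) == nrow(expr))
  groups <- if (is.null(sample)) list(all = seq_len(nrow(expr))) else
    split(seq_len(nrow(expr)), sample)
  rows <- list()
  for (sid in names(groups)) {
    idx <- groups[[sid]]
    tg <- is_target[idx]
    if (!any(tg) || all(tg)) {
      warning(sprintf("sample '%s': one group empty, skipped", sid))
      next
    }
    p <- vapply(genes, function(g) {
      suppressWarnings(stats::wilcox.test(expr[idx[tg], g],
                                          expr[idx[!tg], g],
                                          alternative = "two.sided"))$p.value
    }, numeric(1))
    rows[[sid]] <- data.frame(sample = sid, gene = genes, p = unname(p),
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(sample = character(0),
                                       gene = character(0), p = numeric(0),
                                       fdr = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  if (is.null(sample)) out$sample <- NULL
  out
}
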