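# Cell neighbourhood machinery: radius graphs, per-cell neighbourhood
# composition matrices, Leiden clustering of neighbourhoods, the
# edge-count enrichment score, and its within-sample permutation test with
# Monte-Carlo p-values, Agresti-Coull intervals and BH correction.

#' Radius-based spatial neighbourhood graph
#'
#' Connects every pair of cells of the same sample whose Euclidean distance
#' is at most `radius_um` (closed ball). Edges never cross samples.
#'
#' @param cells Cell data frame with `sample_id`, `x_um`, `y_um` (row order
#'   is the canonical cell order for all downstream operations).
#' @param radius_um Neighbourhood radius in µm; default 100.
#' @return A `spatial_graph`: list with `edges` (data frame `i`, `j`
#'   integer row indices with `i < j`, plus `sample_id`), `n`, `cell_ids`,
#'   `radius_um`.
#' @export
radius_graph <- function(cells, radius_um = 100) {
  check_columns(cells, c("sample_id", "x_um", "y_um"), "cells")
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
    stop("cell coordinates must be finite")
  }
  n <- nrow(cells)
  edge_list <- list()
  for (sid in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == sid)
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(cbind(cells$x_um[idx], cells$y_um[idx])))
    hit <- which(upper.tri(d) & d <= radius_um, arr.ind = TRUE)
    if (nrow(hit)) {
      edge_list[[sid]] <- data.frame(i = idx[hit[, 1]], j = idx[hit[, 2]],
                                     sample_id = sid, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_list)) do.call(rbind, edge_list) else
    data.frame(i = integer(0), j = integer(0), sample_id = character(0))
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n,
                 cell_ids = cells$cell_id %||% as.character(seq_len(n)),
                 radius_um = radius_um),
            class = "spatial_graph")
}

#' Neighbourhood composition matrix
#'
#' For each cell, the number of neighbours (graph-adjacent cells, focal
#' cell excluded) of each substate. Isolated cells get all-zero rows.
#'
#' @param cells Cell data frame with a `substate` column, in the same row
#'   order used to build `graph`.
#' @param graph A [radius_graph()].
#' @param include_self Add the focal cell to its own neighbourhood counts;
#'   default `FALSE`.
#' @return Integer matrix, cells x substates, with attribute `radius_um`.
#' @export
neighbourhood_matrix <- function(cells, graph, include_self = FALSE) {
  check_columns(cells, "substate", "cells")
  if (anyNA(cells$substate)) stop("every cell needs a substate label")
  stopifnot(inherits(graph, "spatial_graph"), nrow(cells) == graph$n)
  lab <- factor(cells$substate)
  S <- nlevels(lab)
  n <- graph$n
  li <- as.integer(lab)
  foc <- c(graph$edges$i, graph$edges$j)
  nb <- c(li[graph$edges$j], li[graph$edges$i])
  if (include_self) {
    foc <- c(foc, seq_len(n))
    nb <- c(nb, li)
  }
  m <- matrix(tabulate((nb - 1) * n + foc, nbins = n * S), nrow = n, ncol = S,
              dimnames = list(graph$cell_ids, levels(lab)))
  attr(m, "radius_um") <- graph$radius_um
  m
}

#' Leiden clustering of neighbourhood composition vectors
#'
#' Builds a k-nearest-neighbour graph (Euclidean, ties broken by row index)
#' on the neighbourhood count vectors pooled across samples, then runs
#' Leiden community detection (modularity objective) at the given
#' resolution. Deterministic under a fixed seed.
#'
#' @param matrix Cells x substates neighbourhood matrix
#'   ([neighbourhood_matrix()], possibly row-bound across samples).
#' @param knn_k Neighbours in the kNN graph; default 15.
#' @param resolution Leiden resolution; default 1.
#' @param seed Integer seed.
#' @param log1p Apply `log1p` to the counts before distances; default
#'   `FALSE` (raw counts).
#' @return List with `labels` (integer cluster per cell, named),
#'   `signatures` (cluster x substate mean neighbourhood counts) and
#'   `parameters`.
#' @export
cluster_neighbourhoods <- function(matrix, knn_k = 15, resolution = 1.0,
                                   seed = 1L, log1p = FALSE) {
  X <- as.matrix(matrix)
  n <- nrow(X)
  if (n < knn_k + 1) stop("need more cells than knn_k")
  if (log1p) X <- log1p(X)
  if (all(abs(sweep(X, 2, X[1, ])) < 1e-12)) {
    labels <- stats::setNames(rep(1L, n), rownames(X))
  } else {
    nn <- knn_index(X, knn_k)
    el <- cbind(rep(seq_len(n), ncol(nn)), as.integer(nn))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
    labels <- stats::setNames(as.integer(igraph::membership(cl)), rownames(X))
  }
  sig <- rowsum(as.matrix(matrix), labels) / as.integer(table(labels))
  list(labels = labels, signatures = sig,
       parameters = list(knn_k = knn_k, resolution = resolution, seed = seed,
                         log1p = log1p))
}

# Blockwise exact k-nearest-neighbour indices (self excluded, distance ties
# broken by row index).
knn_index <- function(X, k, block = 1024) {
  n <- nrow(X)
  k <- min(k, n - 1)
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (start in seq(1, n, by = block)) {
    rows <- start:min(n, start + block - 1)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    d2[cbind(seq_along(rows), rows)] <- Inf
    out[rows, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

# Upper-triangle pair bookkeeping over S substates: linear code of an
# unordered pair (a, b), a <= b, and the list of all pair codes.
pair_code <- function(a, b, S) (pmin(a, b) - 1L) * S + pmax(a, b)

all_pair_codes <- function(S) {
  a <- rep(seq_len(S), times = S:1)
  b <- unlist(lapply(seq_len(S), function(i) i:S))
  list(code = (a - 1L) * S + b, a = a, b = b)
}

#' Within-cluster neighbourhood enrichment scores
#'
#' For one neighbourhood cluster, restricts the spatial graph to the
#' cluster's cells and counts, for each unordered substate pair (including
#' same-substate pairs), the unique undirected edges joining that pair.
#' Scores over all pairs sum to the within-cluster edge count.
#'
#' @param graph A [radius_graph()].
#' @param labels Substate labels aligned with the graph's cells (factor or
#'   character).
#' @param cluster_members Logical vector or integer indices of the cells in
#'   the cluster.
#' @return Upper-triangular integer matrix, substates x substates.
#' @export
enrichment_score <- function(graph, labels, cluster_members) {
  stopifnot(inherits(graph, "spatial_graph"))
  lab <- factor(labels)
  if (length(lab) != graph$n) stop("labels must align with the graph's cells")
  S <- nlevels(lab)
  member <- rep(FALSE, graph$n)
  member[cluster_members] <- TRUE
  keep <- member[graph$edges$i] & member[graph$edges$j]
  li <- as.integer(lab)
  code <- pair_code(li[graph$edges$i[keep]], li[graph$edges$j[keep]], S)
  cnt <- tabulate(code, nbins = S * S)
  out <- matrix(0L, S, S, dimnames = list(levels(lab), levels(lab)))
  pc <- all_pair_codes(S)
  out[cbind(pc$a, pc$b)] <- cnt[pc$code]
  out
}

#' Monte-Carlo empirical p-values with the add-one rule
#'
#' From exceedance counts over `N` permutations (`l` nulls strictly below,
#' `r` strictly above the observed statistic):
#' `p_left = (l + 1)/(N + 1)`, `p_right = (r + 1)/(N + 1)`, and the
#' two-sided `p_two = min(2 p_left, 2 p_right)` capped at 1. Monte-Carlo
#' p-values can never be 0.
#'
#' @param l,r Exceedance counts (vectorised).
#' @param N Number of permutations.
#' @return List with `p_left`, `p_right`, `p_two`.
#' @export
mc_pvalues <- function(l, r, N) {
  if (any(N < 1)) stop("N must be at least 1")
  if (any(l < 0 | r < 0 | l + r > N)) stop("need l, r >= 0 and l + r <= N")
  p_left <- (l + 1) / (N + 1)
  p_right <- (r + 1) / (N + 1)
  list(p_left = p_left, p_right = p_right,
       p_two = pmin(1, pmin(2 * p_left, 2 * p_right)))
}

#' Agresti-Coull confidence interval for a binomial proportion
#'
#' Pseudo-count-adjusted interval: with `ñ = n + z²` and
#' `p̃ = (x + z²/2) / ñ`, the interval is `p̃ ± z sqrt(p̃(1−p̃)/ñ)`,
#' clipped to `[0, 1]`.
#'
#' @param x Success (exceedance) count, `0 <= x <= n`.
#' @param n Number of trials (permutations).
#' @param z Normal quantile; default 1.96.
#' @return Numeric vector `c(lo, hi)` (vectorised over `x`: a 2-column
#'   matrix).
#' @export
agresti_coull_ci <- function(x, n, z = 1.96) {
  if (any(n == 0)) stop("n must be positive")
  if (any(x < 0 | x > n)) stop("x must lie in [0, n]")
  nt <- n + z^2
  pt <- (x + z^2 / 2) / nt
  hw <- z * sqrt(pt * (1 - pt) / nt)
  cbind(lo = pmax(0, pt - hw), hi = pmin(1, pt + hw))
}

#' Permutation test of neighbourhood enrichment
#'
#' Holds coordinates, edges and cluster memberships fixed, shuffles
#' substate labels within each sample `N` times, and for every
#' (neighbourhood cluster, unordered substate pair) compares the observed
#' enrichment score with the permutation null. Empirical p-values use the
#' add-one Monte-Carlo rule `p_left = (l + 1)/(N + 1)`,
#' `p_right = (r + 1)/(N + 1)` where `l`/`r` count permutations with a
#' score strictly below/above the observed; the two-sided p-value is
#' `min(2 p_left, 2 p_right)` capped at 1, with the endpoint-wise min-rule
#' Agresti-Coull interval. BH correction runs jointly across all
#' (cluster, pair) tests unless `per_cluster_fdr`.
#'
#' @param cells Cell data frame with `sample_id` and `substate`, in graph
#'   row order.
#' @param graph A [radius_graph()] over `cells`.
#' @param clusters Neighbourhood-cluster labels per cell, or the result of
#'   [cluster_neighbourhoods()].
#' @param N Number of permutations; default 10000.
#' @param seed Master seed; per-permutation seeds are derived by counter.
#' @param alpha Significance level on the FDR; default 0.05.
#' @param per_cluster_fdr Correct within each cluster instead of jointly.
#' @param z Normal quantile for the Agresti-Coull intervals.
#' @return Data frame (one row per cluster x substate pair): `cluster`,
#'   `substate_a`, `substate_b`, `observed`, `l`, `r`, `p_left`, `p_right`,
#'   `p_two`, `ci_lo`, `ci_hi`, `fdr`, `significant`.
#' @export
permutation_test <- function(cells, graph, clusters, N = 10000, seed = 1L,
                             alpha = 0.05, per_cluster_fdr = FALSE, z = 1.96) {
  if (N < 1) stop("N must be at least 1")
  stopifnot(inherits(graph, "spatial_graph"))
  if (is.list(clusters) && !is.null(clusters$labels)) clusters <- clusters$labels
  if (length(clusters) != graph$n) stop("clusters must align with cells")
  lab <- factor(cells$substate)
  li <- as.integer(lab)
  S <- nlevels(lab)
  pc <- all_pair_codes(S)
  npair <- length(pc$code)

  cl_f <- factor(clusters)
  ncl <- nlevels(cl_f)
  cl_i <- as.integer(cl_f)
  within <- cl_i[graph$edges$i] == cl_i[graph$edges$j]
  e_cl <- cl_i[graph$edges$i][within]
  ei <- graph$edges$i[within]
  ej <- graph$edges$j[within]

  sample_split <- split(seq_len(graph$n), cells$sample_id)

  score_all <- function(l_vec) {
    code <- pair_code(l_vec[ei], l_vec[ej], S)
    # offset codes per cluster so one tabulate covers all clusters
    cnt <- tabulate(code + (e_cl - 1L) * (S * S), nbins = S * S * ncl)
    matrix(cnt, nrow = S * S, ncol = ncl)[pc$code, , drop = FALSE]
  }

  obs <- score_all(li)
  l_cnt <- matrix(0L, npair, ncl)
  r_cnt <- matrix(0L, npair, ncl)
  perm <- li
  for (b in seq_len(N)) {
    set.seed(child_seed(seed, b))
    for (ix in sample_split) perm[ix] <- li[ix][sample.int(length(ix))]
    sc <- score_all(perm)
    l_cnt <- l_cnt + (sc < obs)
    r_cnt <- r_cnt + (sc > obs)
  }

  mc <- mc_pvalues(l_cnt, r_cnt, N)
  p_left <- mc$p_left
  p_right <- mc$p_right
  p_two <- mc$p_two
  ci_l <- agresti_coull_ci(as.integer(l_cnt), N, z)
  ci_r <- agresti_coull_ci(as.integer(r_cnt), N, z)
  ci_lo <- pmin(1, pmin(2 * ci_l[, "lo"], 2 * ci_r[, "lo"]))
  ci_hi <- pmin(1, pmin(2 * ci_l[, "hi"], 2 * ci_r[, "hi"]))

  out <- data.frame(
    cluster = rep(levels(cl_f), each = npair),
    substate_a = rep(levels(lab)[pc$a], ncl),
    substate_b = rep(levels(lab)[pc$b], ncl),
    observed = as.integer(obs),
    l = as.integer(l_cnt),
    r = as.integer(r_cnt),
    p_left = as.numeric(p_left),
    p_right = as.numeric(p_right),
    p_two = as.numeric(p_two),
    ci_lo = ci_lo,
    ci_hi = ci_hi,
    stringsAsFactors = FALSE
  )
  out$fdr <- if (per_cluster_fdr) {
    stats::ave(out$p_two, out$cluster, FUN = bh_adjust)
  } else {
    bh_adjust(out$p_two)
  }
  out$significant <- out$fdr < alpha
  out
}
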