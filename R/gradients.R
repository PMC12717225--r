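# Macrophage layering analysis: per-sample min-max expression
# normalisation, substate mean profiles, top-variance gene selection,
# Z-scored profiles, and normalised lumen-distance layering.

#' Per-sample, per-gene min-max normalisation
#'
#' Rescales each gene to `[0, 1]` within each sample:
#' `(x - min) / (max - min)`, compensating for sequencing-depth differences
#' across samples. Genes constant within a sample map to all zeros so
#' profiles stay finite.
#'
#' @param expr Cells x genes matrix (area-normalised expression).
#' @param sample Optional per-cell sample ids; `NULL` treats all cells as
#'   one sample.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(expr, sample = NULL) {
  expr <- as.matrix(expr)
  groups <- if (is.null(sample)) list(seq_len(nrow(expr))) else
    split(seq_len(nrow(expr)), sample)
  out <- expr
  for (idx in groups) {
    block <- expr[idx, , drop = FALSE]
    lo <- apply(block, 2, min)
    hi <- apply(block, 2, max)
    rng <- hi - lo
    scaled <- sweep(sweep(block, 2, lo), 2, ifelse(rng > 0, rng, 1), "/")
    scaled[, rng == 0] <- 0
    out[idx, ] <- scaled
  }
  out
}

#' Mean expression profiles per substate
#'
#' Arithmetic mean of (min-max normalised) expression over the cells of
#' each substate of interest.
#'
#' @param expr Cells x genes matrix.
#' @param labels Substate labels per cell.
#' @param substates Substates of interest; default all observed.
#' @return Matrix, substates x genes.
#' @export
substate_mean_profiles <- function(expr, labels, substates = NULL) {
  expr <- as.matrix(expr)
  stopifnot(length(labels) == nrow(expr))
  substates <- substates %||% sort(unique(labels))
  missing <- setdiff(substates, labels)
  if (length(missing)) {
    stop("substate(s) with no cells: ", paste(missing, collapse = ", "))
  }
  keep <- labels %in% substates
  m <- rowsum(expr[keep, , drop = FALSE], labels[keep])
  m / as.integer(table(factor(labels[keep], levels = rownames(m))))
}

#' Genes with the highest across-substate variance
#'
#' Ranks genes by the variance of their mean-profile column across
#' substates and returns the top `n`; ties break by gene name.
#'
#' @param profiles Substates x genes matrix ([substate_mean_profiles()]).
#' @param n Number of genes; default 20.
#' @return Character vector of gene names, highest variance first.
#' @export
top_variance_genes <- function(profiles, n = 20) {
  profiles <- as.matrix(profiles)
  if (n > ncol(profiles)) stop("n exceeds the number of genes")
  v <- apply(profiles, 2, stats::var)
  colnames(profiles)[order(-v, colnames(profiles))][seq_len(n)]
}

#' Z-score profiles per gene across substates
#'
#' Standardises each gene column to mean 0, population SD 1 across
#' substates; zero-variance columns map to zeros.
#'
#' @param profiles Substates x genes matrix.
#' @return Z-scored matrix of the same shape.
#' @export
zscore_profiles <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least two substates to Z-score")
  mu <- colMeans(profiles)
  sd <- sqrt(colMeans(sweep(profiles, 2, mu)^2))
  out <- sweep(sweep(profiles, 2, mu), 2, ifelse(sd > 0, sd, 1), "/")
  out[, sd == 0] <- 0
  out
}

#' Normalised distance from the lumen
#'
#' Per cell: Euclidean distance from the centroid to the nearest point on
#' any lumen polygon boundary (0 inside the lumen), normalised by the
#' sample's maximum raw distance, and an inclusion flag
#' `normalized <= cap` restricting attention to subluminal tissue.
#'
#' @param cells Cell data frame of one sample (`cell_id`, `x_um`, `y_um`).
#' @param polygons Polygon vertex table of the same sample containing at
#'   least one `lumen` region (fragmented lumens allowed: nearest wins).
#' @param cap Inclusion cap on the normalised distance; default 0.25.
#' @return Data frame: `cell_id`, `raw_um`, `normalized`, `included`.
#' @export
lumen_distance <- function(cells, polygons, cap = 0.25) {
  check_columns(cells, c("x_um", "y_um"), "cells")
  polys <- split_polygons(polygons)
  lumens <- polys[vapply(polys, function(p) p$region[1] == "lumen", logical(1))]
  if (!length(lumens)) stop("no lumen polygon in this sample")
  raw <- rep(Inf, nrow(cells))
  inside <- rep(FALSE, nrow(cells))
  for (lp in lumens) {
    raw <- pmin(raw, polygon_boundary_distance(cells$x_um, cells$y_um, lp))
    inside <- inside | point_in_polygon(cells$x_um, cells$y_um, lp)
  }
  raw[inside] <- 0
  mx <- max(raw)
  normalized <- if (mx > 0) raw / mx else raw
  data.frame(cell_id = cells$cell_id %||% seq_len(nrow(cells)),
             raw_um = raw, normalized = normalized,
             included = normalized <= cap, stringsAsFactors = FALSE)
}

#' Substate layering order along the lumen distance
#'
#' Median normalised lumen distance per substate over included cells,
#' ranked ascending (closest to the lumen first). Substates with no
#' included cells are dropped with a warning.
#'
#' @param distances A [lumen_distance()] table.
#' @param labels Substate labels aligned with `distances` rows.
#' @param substates Substates to rank; default all observed.
#' @return List with `medians` (named, ascending), `ranking` (substate
#'   names in order) and `samples` (per-substate normalised distance
#'   vectors for plotting).
#' @export
layering_order <- function(distances, labels, substates = NULL) {
  stopifnot(length(labels) == nrow(distances))
  substates <- substates %||% sort(unique(labels))
  keep <- distances$included & labels %in% substates
  vals <- split(distances$normalized[keep], factor(labels[keep], levels = substates))
  empty <- lengths(vals) == 0
  if (any(empty)) {
    warning("substate(s) with no included cells dropped: ",
            paste(names(vals)[empty], collapse = ", "))
    vals <- vals[!empty]
  }
  med <- sort(vapply(vals, stats::median, numeric(1)))
  list(medians = med, ranking = names(med), samples = vals)
}
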