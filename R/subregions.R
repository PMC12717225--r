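# Polygon-based subregion handling: areas, normalised areas, cell-to-region
# assignment and per-region noise-transcript accounting. Region polygons
# come in as a tidy vertex table (sample_id, region, x_um, y_um), the same
# layout the GeoJSON reader/writer uses.

# Anatomical containment order used to resolve overlap slivers; innermost
# first. Unknown region names sort after these, alphabetically.
REGION_PRIORITY <- c("lumen", "thrombus", "necrotic_core", "fibrous_cap",
                     "intima", "media")

region_order <- function(regions) {
  known <- match(regions, REGION_PRIORITY)
  order(is.na(known), known, regions)
}

split_polygons <- function(polygons) {
  check_columns(polygons, c("sample_id", "region", "x_um", "y_um"), "polygons")
  key <- paste(polygons$sample_id, polygons$region, sep = "\r")
  split(polygons, factor(key, levels = unique(key)))
}

# Assign point coordinates to regions of one sample by priority-ordered
# even-odd containment. Returns a character vector ("unassigned" outside).
assign_points <- function(px, py, sample_polys) {
  out <- rep("unassigned", length(px))
  regions <- vapply(sample_polys, function(p) p$region[1], character(1))
  for (k in region_order(regions)) {
    todo <- out == "unassigned"
    if (!any(todo)) break
    hit <- point_in_polygon(px[todo], py[todo], sample_polys[[k]])
    out[todo][hit] <- regions[k]
  }
  out
}

#' Assign cells to annotated subregions
#'
#' Labels each cell with the region whose polygon contains its centroid
#' (even-odd rule, boundary counts as inside). Where digitised polygons
#' overlap, anatomical containment order wins (lumen > thrombus >
#' necrotic_core > fibrous_cap > intima > media). Cells outside every
#' polygon get `"unassigned"`.
#'
#' @param cells Cell data frame with `sample_id`, `x_um`, `y_um`.
#' @param polygons Tidy polygon vertex table (`sample_id`, `region`,
#'   `x_um`, `y_um`).
#' @return `cells` with a `subregion` column.
#' @export
assign_cells_to_regions <- function(cells, polygons) {
  check_columns(cells, c("sample_id", "x_um", "y_um"), "cells")
  cells$subregion <- "unassigned"
  polys <- split_polygons(polygons)
  poly_sample <- vapply(polys, function(p) p$sample_id[1], character(1))
  for (sid in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == sid)
    sp <- polys[poly_sample == sid]
    if (!length(sp)) next
    cells$subregion[idx] <- assign_points(cells$x_um[idx], cells$y_um[idx], sp)
  }
  cells
}

#' Normalised subregion areas of one sample
#'
#' Each annotated region's shoelace area as a percentage of the sample's
#' total annotated area (the sum over its regions, lumen included by
#' default).
#'
#' @param polygons Polygon vertex table for a single sample.
#' @param include_lumen Keep the lumen in numerator and denominator;
#'   default `TRUE`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
normalized_region_areas <- function(polygons, include_lumen = TRUE) {
  polys <- split_polygons(polygons)
  if (length(unique(polygons$sample_id)) != 1) {
    stop("normalized_region_areas expects polygons of a single sample")
  }
  areas <- vapply(polys, polygon_area, numeric(1))
  names(areas) <- vapply(polys, function(p) p$region[1], character(1))
  if (!include_lumen) areas <- areas[names(areas) != "lumen"]
  total <- sum(areas)
  if (total <= 0) stop("total annotated area is zero")
  100 * areas / total
}

#' Per-region transcript and noise accounting
#'
#' Bins every transcript (assigned and noise) to a region by its own
#' coordinates and reports, per region: assigned count, noise count, the
#' relative noise ratio `noise / (noise + assigned)`, and the region's share
#' of the sample's total noise. Transcripts outside every polygon appear as
#' `"unassigned"`, so counts conserve.
#'
#' @param transcripts Transcript table of one sample (`x_um`, `y_um`,
#'   `cell_id` with `NA` marking noise).
#' @param polygons Polygon vertex table for the same sample.
#' @return Data frame with columns `region`, `n_assigned`, `n_noise`,
#'   `noise_ratio`, `noise_share`.
#' @export
region_noise_stats <- function(transcripts, polygons) {
  check_columns(transcripts, c("x_um", "y_um", "cell_id"), "transcripts")
  polys <- split_polygons(polygons)
  regions <- vapply(polys, function(p) p$region[1], character(1))
  lab <- assign_points(transcripts$x_um, transcripts$y_um, polys)
  noise <- is_noise_transcript(transcripts)
  levels <- c(regions[region_order(regions)], "unassigned")
  lab <- factor(lab, levels = levels)
  n_assigned <- as.integer(table(lab[!noise]))
  n_noise <- as.integer(table(lab[noise]))
  tot <- n_assigned + n_noise
  data.frame(
    region = levels,
    n_assigned = n_assigned,
    n_noise = n_noise,
    noise_ratio = ifelse(tot > 0, n_noise / tot, NA_real_),
    noise_share = if (sum(n_noise) > 0) n_noise / sum(n_noise) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Compare a per-sample statistic between groups (Mann-Whitney U + BH)
#'
#' Unpaired two-sided Mann-Whitney U (Wilcoxon rank-sum) tests for every
#' unordered pair of groups, Benjamini-Hochberg corrected across the family.
#' Exact p-values where the implementation allows (no ties, small n),
#' normal approximation otherwise.
#'
#' @param values Numeric vector of per-sample statistics.
#' @param groups Group labels, same length as `values`.
#' @return Data frame with `group_a`, `group_b`, `p`, `fdr`.
#' @export
compare_region_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least two groups")
  if (any(vapply(gl, function(g) sum(groups == g), integer(1)) == 0)) {
    stop("a group has no values")
  }
  pairs <- utils::combn(gl, 2)
  p <- apply(pairs, 2, function(gp) {
    suppressWarnings(stats::wilcox.test(values[groups == gp[1]],
                                        values[groups == gp[2]],
                                        alternative = "two.sided"))$p.value
  })
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             p = p, fdr = bh_adjust(p), stringsAsFactors = FALSE)
}
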