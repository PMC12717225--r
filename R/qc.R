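# Transcript and cell quality control for Baysor-style segmentation output,
# plus the assignment-confidence AUC criterion used to pick the best
# segmentation candidate per sample.

is_noise_transcript <- function(transcripts) {
  is.na(transcripts$cell_id) | transcripts$cell_id == ""
}

#' Filter transcripts on Q-score and assignment confidence
#'
#' Removes low-quality reads (`qscore < q_min`) from all transcripts;
#' assigned transcripts must additionally have
#' `assignment_confidence > conf_min` (strict, so confidence exactly at the
#' threshold is removed). Noise transcripts pass only the Q-score filter and
#' stay flagged as noise.
#'
#' @param transcripts Data frame with `gene`, `x_um`, `y_um`, `qscore`,
#'   `cell_id` (`NA` for noise) and `assignment_confidence`.
#' @param q_min Phred-like Q-score threshold (kept if `>=`); default 20.
#' @param conf_min Assignment-confidence threshold (kept if `>`); default 0.5.
#' @return Filtered transcript data frame.
#' @export
filter_transcripts <- function(transcripts, q_min = 20, conf_min = 0.5) {
  check_columns(transcripts, c("qscore", "cell_id", "assignment_confidence"),
                "transcripts")
  if (nrow(transcripts) == 0) return(transcripts)
  noise <- is_noise_transcript(transcripts)
  keep <- transcripts$qscore >= q_min &
    (noise | transcripts$assignment_confidence > conf_min)
  transcripts[keep, , drop = FALSE]
}

#' Cell-level quality filter
#'
#' A cell is retained iff it has at least `min_nonzero_genes` genes with
#' nonzero counts AND average assignment confidence `>= min_conf` AND
#' `max_cluster_frac >= min_max_cluster_frac` (low values flag doublets) AND
#' `lifespan >= min_lifespan` (low values flag noise). Thresholds are kept,
#' matching the strictly-lower-than removal semantics.
#'
#' @param cells Cell data frame (see [generate_sample()] for the schema).
#' @param counts Raw cells x genes count matrix whose rownames cover
#'   `cells$cell_id`.
#' @param min_nonzero_genes,min_conf,min_max_cluster_frac,min_lifespan
#'   Filter thresholds; defaults 10, 0.75, 0.9, 50.
#' @return List with `cells` and `counts` subset to retained cells, and
#'   `attrition`: per-criterion failure counts plus total removed.
#' @export
cell_quality_filter <- function(cells, counts, min_nonzero_genes = 10,
                                min_conf = 0.75, min_max_cluster_frac = 0.9,
                                min_lifespan = 50) {
  check_columns(cells, c("cell_id", "avg_assignment_confidence",
                         "max_cluster_frac", "lifespan"), "cells")
  if (!all(cells$cell_id %in% rownames(counts))) {
    stop("data-integrity error: some cells are missing from the count matrix")
  }
  counts <- counts[cells$cell_id, , drop = FALSE]
  nonzero <- rowSums(counts > 0)
  fail_genes <- nonzero < min_nonzero_genes
  fail_conf <- cells$avg_assignment_confidence < min_conf
  fail_frac <- cells$max_cluster_frac < min_max_cluster_frac
  fail_life <- cells$lifespan < min_lifespan
  keep <- !(fail_genes | fail_conf | fail_frac | fail_life)
  list(
    cells = cells[keep, , drop = FALSE],
    counts = counts[keep, , drop = FALSE],
    attrition = c(
      nonzero_genes = sum(fail_genes),
      confidence = sum(fail_conf),
      max_cluster_frac = sum(fail_frac),
      lifespan = sum(fail_life),
      removed = sum(!keep)
    )
  )
}

#' Area normalisation of a count matrix
#'
#' Divides each cell's counts by its segmented area in µm², compensating for
#' the larger transcript capture of larger cells.
#'
#' @param counts Raw cells x genes matrix.
#' @param cells Cell data frame supplying `area_um2` for every row of
#'   `counts`.
#' @return Normalised matrix with attribute `normalized = TRUE`.
#' @export
area_normalize <- function(counts, cells) {
  check_columns(cells, c("cell_id", "area_um2"), "cells")
  if (isTRUE(attr(counts, "normalized"))) {
    stop("counts are already area-normalized")
  }
  if (!all(rownames(counts) %in% cells$cell_id)) {
    stop("data-integrity error: count rows missing from the cell table")
  }
  area <- cells$area_um2[match(rownames(counts), cells$cell_id)]
  if (any(!is.finite(area)) || any(area <= 0)) {
    stop("cell areas must be positive and finite")
  }
  out <- counts / area
  attr(out, "normalized") <- TRUE
  out
}

#' Assignment-confidence density mass above a threshold (AUC)
#'
#' Fits a Gaussian kernel density (Scott's bandwidth, 512-point grid over
#' the data range extended by three bandwidths) to the per-cell average
#' assignment confidences and returns the fraction of the total density
#' mass lying in `[lower, 1]` — the segmentation-quality criterion used to
#' rank candidate segmentations. Zero-variance input returns 1 if the
#' constant is `>= lower`, else 0.
#'
#' @param confidences Numeric vector of per-cell average assignment
#'   confidences in `[0, 1]`, or a cell data frame with an
#'   `avg_assignment_confidence` column.
#' @param lower Lower integration bound; default 0.75.
#' @return A proportion in `[0, 1]`.
#' @export
confidence_auc <- function(confidences, lower = 0.75) {
  if (is.data.frame(confidences)) {
    check_columns(confidences, "avg_assignment_confidence", "cells")
    confidences <- confidences$avg_assignment_confidence
  }
  confidences <- confidences[!is.na(confidences)]
  if (!length(confidences)) stop("no confidences to integrate")
  if (stats::sd(confidences) == 0 || length(confidences) == 1) {
    return(as.numeric(confidences[1] >= lower))
  }
  h <- stats::bw.nrd(confidences)
  d <- stats::density(confidences, bw = h, n = 512,
                      from = min(confidences) - 3 * h,
                      to = max(confidences) + 3 * h)
  # trapezoidal mass in [lower, 1], clipping grid cells that straddle the
  # bounds, normalised by the total mass so the value is a proportion
  mids <- (d$y[-1] + d$y[-length(d$y)]) / 2
  x_lo <- d$x[-length(d$x)]; x_hi <- d$x[-1]
  overlap <- pmax(0, pmin(x_hi, 1) - pmax(x_lo, lower))
  total <- sum(mids * (x_hi - x_lo))
  if (total <= 0) stop("degenerate density estimate")
  min(1, max(0, sum(mids * overlap) / total))
}

#' Select the best segmentation candidate by confidence AUC
#'
#' Ranks candidate segmentations of one sample by [confidence_auc()] of
#' their per-cell average assignment confidences and returns the argmax;
#' ties break lexicographically on candidate id.
#'
#' @param candidates List of candidates, each a list with `candidate_id` and
#'   `cells` (see [generate_candidates()]).
#' @param lower Lower integration bound passed to [confidence_auc()].
#' @return The winning `candidate_id` (character), with the per-candidate
#'   AUC values attached as attribute `auc`.
#' @export
select_segmentation <- function(candidates, lower = 0.75) {
  if (!length(candidates)) stop("no candidates supplied")
  ids <- vapply(candidates, function(ca) ca$candidate_id, character(1))
  auc <- vapply(candidates, function(ca) confidence_auc(ca$cells, lower), numeric(1))
  names(auc) <- ids
  ord <- order(-auc, ids)
  structure(ids[ord[1]], auc = auc)
}

#' Fraction of transcripts classified as noise
#'
#' Share of transcripts left unassigned to any cell, computed after the
#' Q-score filter (apply [filter_transcripts()] first).
#'
#' @param transcripts Transcript data frame with a `cell_id` column (`NA`
#'   marks noise).
#' @return Proportion in `[0, 1]`.
#' @export
noise_fraction <- function(transcripts) {
  check_columns(transcripts, "cell_id", "transcripts")
  if (nrow(transcripts) == 0) stop("no transcripts: noise fraction is undefined")
  mean(is_noise_transcript(transcripts))
}
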