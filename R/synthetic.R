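# Synthetic plaque-tissue generator.
#
# Emulates the data model of a Xenium run segmented with Baysor: per-cell
# centroids, areas and assignment-confidence QC fields, per-transcript
# coordinates with Phred-like quality scores and noise flags, a cell x gene
# count matrix, and concentric subregion polygons (lumen, fibrous cap,
# necrotic core, intima, media). Spatial architecture is planted by placing
# each cell substate in a radial band of the tissue disc, so every
# downstream spatial statistic has a known ground truth.

#' Configuration for the synthetic plaque generator
#'
#' @param n_samples Number of samples in a cohort.
#' @param cells_per_sample Cells per sample.
#' @param substates Substate catalogue: data frame with columns `label`,
#'   `inner`, `outer` (radial band as fractions of the tissue radius, inside
#'   `[lumen_radius/tissue_radius, 1]`) and `prop` (expected fraction of
#'   cells). Optional `theta_start`/`theta_end` columns (fractions of the
#'   full turn, default 0 and 1) additionally restrict a substate to an
#'   angular sector, for planting sector-shaped spatial domains. Default: a
#'   seven-substate plaque-like catalogue with macrophage substates layered
#'   from the lumen towards the necrotic core.
#' @param n_genes Number of genes on the panel.
#' @param program_means Substate x gene matrix of negative-binomial mean
#'   counts at average cell area. Default: 4 marker genes per substate at
#'   mean 3 over a background of 0.2.
#' @param nb_dispersion Negative-binomial size (shape) parameter shared
#'   across genes; smaller means more overdispersion.
#' @param area_lognormal `c(meanlog, sdlog)` of the cell-area distribution
#'   in log µm².
#' @param confidence_beta Named list of `c(alpha, beta)` Beta parameters for
#'   per-cell average assignment confidence, one entry per segmentation
#'   candidate configuration; the first entry is used by
#'   [generate_sample()].
#' @param noise_transcript_rate Expected fraction of all transcripts that
#'   are unassigned noise, in `[0, 1)`.
#' @param tissue_radius_um,lumen_radius_um Tissue disc and lumen radii (µm).
#' @param band_jitter_um Gaussian radial jitter (sd, µm) applied to planted
#'   cell positions; 0 keeps every cell exactly inside its band.
#' @param seed Master seed; per-sample child seeds are derived from it by a
#'   counter so any one sample can be regenerated on its own.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 6,
                       cells_per_sample = 1000,
                       substates = NULL,
                       n_genes = 40,
                       program_means = NULL,
                       nb_dispersion = 2,
                       area_lognormal = c(meanlog = log(80), sdlog = 0.4),
                       confidence_beta = list(baysor_scale10 = c(alpha = 16, beta = 2)),
                       noise_transcript_rate = 0.1,
                       tissue_radius_um = 1500,
                       lumen_radius_um = 200,
                       band_jitter_um = 10,
                       seed = 1L) {
  lf <- lumen_radius_um / tissue_radius_um
  if (is.null(substates)) substates <- default_substates(lf)
  check_columns(substates, c("label", "inner", "outer", "prop"), "substates")
  if (any(substates$inner >= substates$outer)) {
    stop("configuration error: each substate's inner band fraction must be < outer")
  }
  if (any(substates$inner < lf - 1e-9) || any(substates$outer > 1 + 1e-9)) {
    stop("configuration error: radial bands must lie within [lumen_radius/tissue_radius, 1]")
  }
  if (noise_transcript_rate < 0 || noise_transcript_rate >= 1) {
    stop("noise_transcript_rate must be in [0, 1)")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (tissue_radius_um <= 0 || lumen_radius_um <= 0 || lumen_radius_um >= tissue_radius_um) {
    stop("need 0 < lumen_radius_um < tissue_radius_um")
  }
  if (is.null(program_means)) {
    program_means <- default_program_means(substates$label, n_genes)
  }
  if (ncol(program_means) > n_genes) {
    stop("n_genes must be at least the number of program genes")
  }
  if (nrow(program_means) != nrow(substates)) {
    stop("program_means must have one row per substate")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    cells_per_sample = as.integer(cells_per_sample),
    substates = substates,
    n_genes = as.integer(n_genes),
    program_means = program_means,
    nb_dispersion = nb_dispersion,
    area_lognormal = area_lognormal,
    confidence_beta = confidence_beta,
    noise_transcript_rate = noise_transcript_rate,
    tissue_radius_um = tissue_radius_um,
    lumen_radius_um = lumen_radius_um,
    band_jitter_um = band_jitter_um,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Plaque-like default catalogue: macrophage substates layered outward from
# the lumen, VSMC in the mural layers, immune cells spread through the
# intima. `lf` is the lumen fraction of the tissue radius.
default_substates <- function(lf) {
  data.frame(
    label = c("EC", "Mac_HMOX1", "Mac_TREM2hi_CCL18hi", "Mac_TREM2hi",
              "Tcell", "Plasma_cell", "VSMC"),
    inner = c(lf, lf, 0.30, 0.45, lf, 0.55, 0.55),
    outer = c(0.20, 0.30, 0.45, 0.55, 0.55, 0.80, 1.00),
    prop = c(0.08, 0.15, 0.15, 0.10, 0.15, 0.07, 0.30),
    stringsAsFactors = FALSE
  )
}

default_program_means <- function(labels, n_genes, marker_per_substate = 4,
                                  marker_mean = 4, background = 0.45) {
  s <- length(labels)
  need <- s * marker_per_substate
  if (n_genes < need) {
    stop(sprintf("n_genes must be at least %d for the default gene programs", need))
  }
  m <- matrix(background, nrow = s, ncol = n_genes,
              dimnames = list(labels, sprintf("gene%03d", seq_len(n_genes))))
  for (i in seq_len(s)) {
    m[i, ((i - 1) * marker_per_substate + 1):(i * marker_per_substate)] <- marker_mean
  }
  m
}

# Map a substate label to coarser type levels so QC and annotation code can
# exercise the full cell schema.
coarse_types <- function(substate) {
  low <- ifelse(grepl("^Mac", substate), "Macrophage",
         ifelse(substate %in% c("Tcell", "Plasma_cell"), substate,
         ifelse(substate == "EC", "Endothelial", substate)))
  high <- ifelse(low %in% c("Macrophage", "Tcell", "Plasma_cell"), "Immune",
          ifelse(low == "Endothelial", "Vascular",
          ifelse(low == "VSMC", "Mural", "Other")))
  list(low = low, high = high)
}

# Region radial layout (fractions of tissue radius). Controls consist only
# of media, intima and lumen: the intima then spans from the lumen to the
# media.
region_layout <- function(condition, lf) {
  if (identical(condition, "control")) {
    list(intima = c(lf, 0.80), media = c(0.80, 1.00))
  } else {
    list(fibrous_cap = c(lf, 0.30), necrotic_core = c(0.30, 0.55),
         intima = c(0.55, 0.80), media = c(0.80, 1.00))
  }
}

#' Generate one synthetic plaque or control sample
#'
#' @param config A [sim_config()].
#' @param sample_id Sample identifier used in all emitted tables.
#' @param condition `"plaque"` (default) or `"control"`; controls omit the
#'   necrotic-core and fibrous-cap polygons.
#' @param props Optional named numeric vector of substate proportions
#'   overriding the catalogue (renormalised to 1).
#' @param seed Seed for this sample; defaults to the config master seed.
#' @return A `synthetic_sample` list with elements `cells`, `transcripts`,
#'   `counts` (cells x genes), `polygons` (tidy vertex table), `truth`
#'   (planted substate and radial band per cell), `sample_id`, `condition`.
#' @export
generate_sample <- function(config, sample_id = "sample01",
                            condition = c("plaque", "control"),
                            props = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  set.seed(seed)
  n <- config$cells_per_sample
  R <- config$tissue_radius_um
  lf <- config$lumen_radius_um / R
  cat <- config$substates
  p <- props %||% stats::setNames(cat$prop, cat$label)
  p <- p[cat$label] / sum(p[cat$label])

  sub_idx <- sample.int(nrow(cat), n, replace = TRUE, prob = p)
  inner <- cat$inner[sub_idx] * R
  outer <- cat$outer[sub_idx] * R
  # uniform areal density within the band (not uniform in radius)
  r <- sqrt(stats::runif(n, inner^2, outer^2))
  if (config$band_jitter_um > 0) {
    r <- pmin(R, pmax(1e-6, r + stats::rnorm(n, 0, config$band_jitter_um)))
  }
  th_lo <- (if ("theta_start" %in% names(cat)) cat$theta_start[sub_idx] else 0) * 2 * pi
  th_hi <- (if ("theta_end" %in% names(cat)) cat$theta_end[sub_idx] else 1) * 2 * pi
  theta <- stats::runif(n, th_lo, th_hi)
  x <- r * cos(theta); y <- r * sin(theta)
  area <- stats::rlnorm(n, config$area_lognormal[[1]], config$area_lognormal[[2]])
  mean_area <- exp(config$area_lognormal[[1]] + config$area_lognormal[[2]]^2 / 2)

  cell_id <- sprintf("%s_c%05d", sample_id, seq_len(n))
  substate <- cat$label[sub_idx]
  types <- coarse_types(substate)
  cb <- config$confidence_beta[[1]]
  cells <- data.frame(
    cell_id = cell_id, sample_id = sample_id,
    x_um = x, y_um = y, area_um2 = area,
    substate = substate,
    low_level_type = types$low, high_level_type = types$high,
    avg_assignment_confidence = stats::rbeta(n, cb[[1]], cb[[2]]),
    max_cluster_frac = stats::rbeta(n, 40, 1),
    lifespan = stats::rgamma(n, shape = 10, scale = 12),
    stringsAsFactors = FALSE
  )

  g <- config$n_genes
  mu <- config$program_means[sub_idx, , drop = FALSE] * (area / mean_area)
  counts <- matrix(
    stats::rnbinom(n * g, size = config$nb_dispersion, mu = as.numeric(mu)),
    nrow = n, ncol = g,
    dimnames = list(cell_id, colnames(config$program_means))
  )

  transcripts <- transcripts_from_counts(counts, cells, config, sample_id)
  polygons <- sample_polygons(sample_id, condition, config)
  truth <- data.frame(
    cell_id = cell_id, substate = substate,
    band_inner_um = inner, band_outer_um = outer, radius_um = r,
    stringsAsFactors = FALSE
  )
  structure(list(sample_id = sample_id, condition = condition, cells = cells,
                 transcripts = transcripts, counts = counts,
                 polygons = polygons, truth = truth),
            class = "synthetic_sample")
}

# One transcript row per count unit, scattered around its cell centroid;
# noise transcripts are uniform over the tissue disc, carry confidence 0 and
# an NA cell id.
transcripts_from_counts <- function(counts, cells, config, sample_id) {
  nz <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[nz]
  ci <- rep(nz[, 1], reps)
  gi <- rep(nz[, 2], reps)
  n_assigned <- length(ci)
  scatter <- sqrt(cells$area_um2[ci] / pi) / 1.5
  tx <- data.frame(
    gene = colnames(counts)[gi],
    x_um = cells$x_um[ci] + stats::rnorm(n_assigned, 0, scatter),
    y_um = cells$y_um[ci] + stats::rnorm(n_assigned, 0, scatter),
    qscore = pmax(0, stats::rnorm(n_assigned, 32, 7)),
    cell_id = cells$cell_id[ci],
    assignment_confidence = stats::rbeta(n_assigned, 8, 2),
    stringsAsFactors = FALSE
  )
  rate <- config$noise_transcript_rate
  n_noise <- if (rate > 0) round(rate / (1 - rate) * n_assigned) else 0L
  if (n_noise > 0) {
    rr <- config$tissue_radius_um * sqrt(stats::runif(n_noise))
    tt <- stats::runif(n_noise, 0, 2 * pi)
    noise <- data.frame(
      gene = sample(colnames(counts), n_noise, replace = TRUE),
      x_um = rr * cos(tt), y_um = rr * sin(tt),
      qscore = pmax(0, stats::rnorm(n_noise, 32, 7)),
      cell_id = NA_character_,
      assignment_confidence = 0,
      stringsAsFactors = FALSE
    )
    tx <- rbind(tx, noise)
  }
  tx$sample_id <- sample_id
  rownames(tx) <- NULL
  tx
}

# Concentric region polygons: the lumen as a 64-gon disc, every other region
# as a one-piece annulus polygon (see annulus_polygon()).
sample_polygons <- function(sample_id, condition, config) {
  R <- config$tissue_radius_um
  lf <- config$lumen_radius_um / R
  layout <- region_layout(condition, lf)
  polys <- list(data.frame(
    sample_id = sample_id, region = "lumen",
    x_um = circle_polygon(0, 0, config$lumen_radius_um)[, 1],
    y_um = circle_polygon(0, 0, config$lumen_radius_um)[, 2],
    stringsAsFactors = FALSE
  ))
  for (reg in names(layout)) {
    v <- annulus_polygon(0, 0, layout[[reg]][1] * R, layout[[reg]][2] * R)
    polys[[length(polys) + 1]] <- data.frame(
      sample_id = sample_id, region = reg,
      x_um = v[, 1], y_um = v[, 2], stringsAsFactors = FALSE
    )
  }
  do.call(rbind, polys)
}

#' Generate a multi-sample synthetic cohort
#'
#' Samples are labelled plaque or control; control samples omit the
#' necrotic-core and fibrous-cap polygons and regions. Per-sample seeds are
#' derived from the master seed by a counter, so regenerating sample `i`
#' alone reproduces it exactly.
#'
#' @param config A [sim_config()].
#' @param n_control Number of control samples (the first `n_control`).
#' @param condition_effect Optional `list(substate =, delta =)`: the named
#'   substate's expected proportion is raised by `delta` in plaque samples
#'   (renormalised), planting a composition difference between conditions.
#' @param sample_props Optional `n_samples` x substate matrix of proportions
#'   (rows renormalised), e.g. composition archetypes; overrides the
#'   catalogue and `condition_effect`.
#' @return A `synthetic_cohort`: list of `samples` (named list) and
#'   `metadata` (sample_id, patient_id, condition, a binary covariate
#'   `symptomatic`, and numeric `age`).
#' @export
generate_cohort <- function(config, n_control = 0, condition_effect = NULL,
                            sample_props = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 1) stop("n_samples must be >= 1")
  ids <- sprintf("sample%02d", seq_len(config$n_samples))
  condition <- ifelse(seq_len(config$n_samples) <= n_control, "control", "plaque")
  labels <- config$substates$label
  samples <- vector("list", config$n_samples)
  names(samples) <- ids
  for (i in seq_len(config$n_samples)) {
    props <- stats::setNames(config$substates$prop, labels)
    if (!is.null(sample_props)) {
      props <- stats::setNames(as.numeric(sample_props[i, labels]), labels)
    } else if (!is.null(condition_effect) && condition[i] == "plaque") {
      props[condition_effect$substate] <- props[condition_effect$substate] +
        condition_effect$delta
      props <- pmax(props, 0)
    }
    samples[[i]] <- generate_sample(config, ids[i], condition[i],
                                    props = props,
                                    seed = child_seed(config$seed, i))
  }
  set.seed(child_seed(config$seed, 0L))
  metadata <- data.frame(
    sample_id = ids,
    patient_id = sprintf("patient%02d", seq_len(config$n_samples)),
    condition = condition,
    symptomatic = sample(c("yes", "no"), config$n_samples, replace = TRUE),
    age = round(stats::runif(config$n_samples, 50, 85)),
    stringsAsFactors = FALSE
  )
  structure(list(samples = samples, metadata = metadata),
            class = "synthetic_cohort")
}

#' Shuffle substate labels within a sample (permutation null)
#'
#' Permutes substate labels uniformly among a sample's cells while leaving
#' coordinates, counts and polygons untouched; the label multiset is
#' preserved. Given a plain cell table, labels are shuffled within each
#' `sample_id` group.
#'
#' @param sample A `synthetic_sample` or a cell data frame with `sample_id`
#'   and `substate` columns.
#' @param seed Integer seed.
#' @return Object of the same shape with permuted `substate` labels.
#' @export
shuffle_labels_null <- function(sample, seed) {
  set.seed(seed)
  if (inherits(sample, "synthetic_sample")) {
    sample$cells$substate <- sample$cells$substate[sample.int(nrow(sample$cells))]
    return(sample)
  }
  check_columns(sample, c("sample_id", "substate"), "cells")
  for (sid in unique(sample$sample_id)) {
    idx <- which(sample$sample_id == sid)
    sample$substate[idx] <- sample$substate[idx][sample.int(length(idx))]
  }
  sample
}

#' Generate segmentation candidates for one sample
#'
#' Reuses one planted geometry and redraws the per-cell average assignment
#' confidence from each candidate configuration's Beta parameters, emulating
#' the same tissue segmented under different input-combination / scale
#' settings.
#'
#' @param config A [sim_config()] whose `confidence_beta` has one entry per
#'   candidate.
#' @param sample_id Sample identifier.
#' @param ... Passed to [generate_sample()].
#' @return Named list of candidates, each `list(candidate_id, cells, counts)`.
#' @export
generate_candidates <- function(config, sample_id = "sample01", ...) {
  base <- generate_sample(config, sample_id, ...)
  out <- list()
  for (k in seq_along(config$confidence_beta)) {
    cid <- names(config$confidence_beta)[k] %||% sprintf("candidate%02d", k)
    cb <- config$confidence_beta[[k]]
    cells <- base$cells
    set.seed(child_seed(config$seed, 1000L + k))
    cells$avg_assignment_confidence <- stats::rbeta(nrow(cells), cb[[1]], cb[[2]])
    out[[cid]] <- list(candidate_id = cid, cells = cells, counts = base$counts)
  }
  out
}
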