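# Readers and writers for the on-disk layout: cell and transcript CSVs
# (Baysor-style, with a column map to tolerate dialect drift), counts in
# MatrixMarket with row/column sidecars, subregion polygons as GeoJSON
# FeatureCollections (coordinates in µm), and a cohort metadata CSV.

#' Read a Baysor-style cell table
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping on-disk column names to the
#'   canonical schema (`cell_id`, `sample_id`, `x_um`, `y_um`, `area_um2`,
#'   `substate`, `avg_assignment_confidence`, `max_cluster_frac`,
#'   `lifespan`, ...); identity by default.
#' @return Cell data frame in canonical columns.
#' @export
read_cells_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) names(df)[match(col_map, names(df))] <- names(col_map)
  check_columns(df, c("cell_id", "sample_id", "x_um", "y_um"), "cells")
  df
}

#' Read a transcript table
#'
#' @inheritParams read_cells_csv
#' @return Transcript data frame (`cell_id` empty strings become `NA`,
#'   flagging noise).
#' @export
read_transcripts_csv <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) names(df)[match(col_map, names(df))] <- names(col_map)
  check_columns(df, c("gene", "x_um", "y_um", "qscore"), "transcripts")
  if ("cell_id" %in% names(df)) df$cell_id[df$cell_id %in% ""] <- NA_character_
  df
}

#' Write / read a count matrix as MatrixMarket with sidecars
#'
#' `<stem>.mtx` plus `<stem>_cells.txt` and `<stem>_genes.txt` holding the
#' row and column labels, one per line.
#'
#' @param counts Cells x genes matrix with dimnames.
#' @param stem Path stem (no extension).
#' @return `write_counts_mtx`: the stem, invisibly. `read_counts_mtx`: a
#'   dense base matrix with dimnames.
#' @export
write_counts_mtx <- function(counts, stem) {
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, "_cells.txt"))
  writeLines(colnames(counts), paste0(stem, "_genes.txt"))
  invisible(stem)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  dimnames(m) <- list(readLines(paste0(stem, "_cells.txt")),
                      readLines(paste0(stem, "_genes.txt")))
  m
}

#' Write / read subregion polygons as GeoJSON
#'
#' One Feature per region with properties `sample_id` and `region`;
#' geometry is a single-ring Polygon in µm. The ring is closed on disk
#' (first vertex repeated) and reopened on read.
#'
#' @param polygons Tidy vertex table (`sample_id`, `region`, `x_um`,
#'   `y_um`).
#' @param path GeoJSON path.
#' @return `write_polygons_geojson`: `path`, invisibly.
#'   `read_polygons_geojson`: a tidy vertex table.
#' @export
write_polygons_geojson <- function(polygons, path) {
  polys <- split_polygons(polygons)
  features <- lapply(polys, function(p) {
    ring <- cbind(p$x_um, p$y_um)
    ring <- rbind(ring, ring[1, ])
    list(
      type = "Feature",
      properties = list(sample_id = p$sample_id[1], region = p$region[1]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) ring[i, ])))
    )
  })
  names(features) <- NULL
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  out <- lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) c(v[[1]], v[[2]])))
    n <- nrow(ring)
    if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    data.frame(sample_id = f$properties$sample_id,
               region = f$properties$region,
               x_um = ring[, 1], y_um = ring[, 2], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write a synthetic cohort to a directory
#'
#' Emits `cells.csv`, `transcripts.csv`, `metadata.csv`,
#' `polygons.geojson`, and per-sample `counts_<sample>.mtx` with sidecars.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- do.call(rbind, lapply(cohort$samples, `[[`, "cells"))
  tx <- do.call(rbind, lapply(cohort$samples, `[[`, "transcripts"))
  polys <- do.call(rbind, lapply(cohort$samples, `[[`, "polygons"))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(tx, file.path(dir, "transcripts.csv"), row.names = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  write_polygons_geojson(polys, file.path(dir, "polygons.geojson"))
  for (s in cohort$samples) {
    write_counts_mtx(s$counts, file.path(dir, paste0("counts_", s$sample_id)))
  }
  invisible(dir)
}
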