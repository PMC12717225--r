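test_that("shoelace areas match hand values and the triangulation oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(square), 1)
  expect_equal(polygon_area(square[nrow(square):1, ]), 1)  # orientation-free
  expect_equal(polygon_area(rbind(c(0, 0), c(2, 0), c(0, 2))), 2)

  set.seed(3)
  for (i in 1:20) {
    pts <- cbind(runif(30, -50, 50), runif(30, -50, 50))
    hull <- pts[chull(pts), ]           # convex, hence simple
    expect_equal(polygon_area(hull), fan_triangulation_area(hull),
                 tolerance = 1e-9)
  }

  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie), "self-intersecting")
})

test_that("point-in-polygon agrees with a winding-number oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_true(point_in_polygon(0.5, 0.5, square))
  expect_true(point_in_polygon(1, 0.5, square))   # closed boundary
  expect_false(point_in_polygon(1.5, 0.5, square))

  ann <- annulus_polygon(0, 0, 100, 200)
  disc <- circle_polygon(0, 0, 100)
  set.seed(11)
  px <- runif(500, -250, 250); py <- runif(500, -250, 250)
  expect_equal(point_in_polygon(px, py, ann), winding_inside(px, py, ann))
  expect_equal(point_in_polygon(px, py, disc), winding_inside(px, py, disc))
})

test_that("cells are assigned by containment with anatomical priority", {
  media <- data.frame(sample_id = "s", region = "media",
                      x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 1))
  cells <- data.frame(cell_id = "c1", sample_id = "s", x_um = 0.5, y_um = 0.5)
  expect_equal(assign_cells_to_regions(cells, media)$subregion, "media")
  edge <- data.frame(cell_id = "c2", sample_id = "s", x_um = 1, y_um = 0.5)
  expect_equal(assign_cells_to_regions(edge, media)$subregion, "media")
  out <- data.frame(cell_id = "c3", sample_id = "s", x_um = 5, y_um = 5)
  expect_equal(assign_cells_to_regions(out, media)$subregion, "unassigned")

  # nested polygons: innermost region wins
  lum <- circle_polygon(0, 0, 50)
  med <- circle_polygon(0, 0, 200)
  polys <- rbind(
    data.frame(sample_id = "s", region = "media", x_um = med[, 1], y_um = med[, 2]),
    data.frame(sample_id = "s", region = "lumen", x_um = lum[, 1], y_um = lum[, 2])
  )
  inner <- data.frame(cell_id = "c4", sample_id = "s", x_um = 10, y_um = 0)
  expect_equal(assign_cells_to_regions(inner, polys)$subregion, "lumen")

  # permutation invariance of input cell order
  cfg <- tiny_config(cells = 200)
  s <- generate_sample(cfg, "s1")
  a <- assign_cells_to_regions(s$cells, s$polygons)
  perm <- sample(nrow(s$cells))
  b <- assign_cells_to_regions(s$cells[perm, ], s$polygons)
  expect_equal(b$subregion[order(perm)], a$subregion)
})

test_that("normalised region areas are percentages summing to 100", {
  mk <- function(region, side) data.frame(
    sample_id = "s", region = region,
    x_um = c(0, side, side, 0) + ifelse(region == "media", 100, 0),
    y_um = c(0, 0, side, side))
  polys <- rbind(mk("necrotic_core", sqrt(70)), mk("media", sqrt(30)))
  pct <- normalized_region_areas(polys)
  expect_equal(unname(pct[c("necrotic_core", "media")]), c(70, 30))
  expect_equal(sum(pct), 100)
  expect_equal(unname(normalized_region_areas(mk("media", 5))), 100)

  cfg <- tiny_config(cells = 50)
  s <- generate_sample(cfg, "s1")
  pct2 <- normalized_region_areas(s$polygons)
  expect_equal(sum(pct2), 100, tolerance = 1e-9)
  # matches shoelace areas recomputed independently
  areas <- vapply(split(s$polygons, s$polygons$region), function(p)
    fan_triangulation_area(cbind(p$x_um, p$y_um)), numeric(1))
  expect_equal(sort(pct2), sort(100 * areas / sum(areas)), tolerance = 1e-6)
})

test_that("region noise accounting conserves counts and tracks areas", {
  square <- function(region, x0) data.frame(
    sample_id = "s", region = region,
    x_um = c(0, 10, 10, 0) + x0, y_um = c(0, 0, 10, 10))
  polys <- rbind(square("intima", 0), square("media", 20))
  tx <- data.frame(
    gene = "g",
    x_um = c(rep(5, 10), rep(25, 10)), y_um = rep(5, 20),
    qscore = 30,
    cell_id = c(rep("c", 10), rep("c", 5), rep(NA, 5)),
    assignment_confidence = 0.9, stringsAsFactors = FALSE)
  rs <- region_noise_stats(tx, polys)
  expect_equal(rs$noise_ratio[rs$region == "intima"], 0)
  expect_equal(rs$noise_ratio[rs$region == "media"], 0.5)
  expect_equal(sum(rs$n_assigned) + sum(rs$n_noise), nrow(tx))

  # uniform noise spreads across regions in proportion to area
  cfg <- tiny_config(cells = 600, noise_transcript_rate = 0.3)
  s <- generate_sample(cfg, "s1")
  rs2 <- region_noise_stats(s$transcripts, s$polygons)
  areas <- vapply(split(s$polygons, s$polygons$region),
                  polygon_area, numeric(1))
  R <- cfg$tissue_radius_um
  n_noise <- sum(rs2$n_noise)
  for (reg in names(areas)) {
    p <- areas[[reg]] / (pi * R^2)
    share <- rs2$noise_share[rs2$region == reg]
    expect_lt(abs(share - p), 2.58 * sqrt(p * (1 - p) / n_noise) + 0.005)
  }
})

test_that("group comparisons use exact rank-sum p-values and BH", {
  p <- compare_region_groups(c(1, 2, 3, 10, 11, 12),
                             rep(c("a", "b"), each = 3))
  expect_equal(p$p, 0.1)
  expect_equal(p$fdr, 0.1)

  same <- compare_region_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)

  multi <- compare_region_groups(c(1, 2, 10, 11, 20, 21),
                                 rep(c("a", "b", "c"), each = 2))
  expect_equal(nrow(multi), 3)
  expect_equal(multi$fdr, stepup_bh(multi$p))
  expect_error(compare_region_groups(1:3, c("a", "a", "a")), "two groups")
})
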