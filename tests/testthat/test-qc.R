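make_tx <- function(q, conf, noise = FALSE) {
  data.frame(gene = "g", x_um = 0, y_um = 0, qscore = q,
             cell_id = if (noise) NA_character_ else "c1",
             assignment_confidence = conf, stringsAsFactors = FALSE)
}

test_that("transcript filter applies strict boundary semantics", {
  tx <- rbind(make_tx(19, 0.9), make_tx(20, 0.9), make_tx(21, 0.9))
  expect_equal(nrow(filter_transcripts(tx)), 2)          # Q = 20 kept
  expect_equal(nrow(filter_transcripts(make_tx(30, 0.5))), 0)  # conf 0.5 removed
  expect_equal(nrow(filter_transcripts(make_tx(30, 0.51))), 1)
  # noise transcripts pass the Q filter only and stay noise
  noisy <- rbind(make_tx(30, 0, noise = TRUE), make_tx(10, 0, noise = TRUE))
  kept <- filter_transcripts(noisy)
  expect_equal(nrow(kept), 1)
  expect_true(is.na(kept$cell_id))
  expect_equal(nrow(filter_transcripts(tx[0, ])), 0)
  # idempotence
  once <- filter_transcripts(tx)
  expect_identical(filter_transcripts(once), once)
})

test_that("cell filter keeps threshold-equal cells and logs attrition", {
  # c1 fails the gene filter (9 nonzero), c2 sits exactly on the
  # confidence and lifespan thresholds (kept), c3 fails confidence,
  # c4 fails max_cluster_frac, c5 fails lifespan, c6 fails two criteria
  cells <- data.frame(
    cell_id = paste0("c", 1:6), sample_id = "s",
    avg_assignment_confidence = c(0.9, 0.75, 0.74, 0.9, 0.9, 0.5),
    max_cluster_frac = c(0.95, 0.95, 0.95, 0.89, 0.95, 0.95),
    lifespan = c(60, 50, 60, 60, 49, 10),
    stringsAsFactors = FALSE
  )
  counts <- matrix(1, 6, 12, dimnames = list(cells$cell_id, paste0("g", 1:12)))
  counts[1, 10:12] <- 0
  res <- cell_quality_filter(cells, counts)
  expect_equal(res$cells$cell_id, "c2")
  expect_equal(rownames(res$counts), "c2")
  expect_equal(res$attrition[["nonzero_genes"]], 1)
  expect_equal(res$attrition[["confidence"]], 2)
  expect_equal(res$attrition[["max_cluster_frac"]], 1)
  expect_equal(res$attrition[["lifespan"]], 2)
  # inclusion-exclusion: removed counts the union, not the sum
  expect_equal(res$attrition[["removed"]], 5)
  expect_lt(res$attrition[["removed"]],
            sum(res$attrition[c("nonzero_genes", "confidence",
                                "max_cluster_frac", "lifespan")]))

  # all passing -> identity; applying twice changes nothing
  again <- cell_quality_filter(res$cells, res$counts)
  expect_identical(again$cells, res$cells)
  expect_equal(again$attrition[["removed"]], 0)

  expect_error(cell_quality_filter(cells, counts[1:3, ]), "data-integrity")
})

test_that("area normalisation divides by cell area", {
  cells <- data.frame(cell_id = c("a", "b"), area_um2 = c(2, 4))
  counts <- matrix(c(2, 4, 4, 8), 2, 2, byrow = TRUE,
                   dimnames = list(c("a", "b"), c("g1", "g2")))
  norm <- area_normalize(counts, cells)
  expect_equal(unname(norm["a", ]), c(1, 2))
  expect_equal(unname(norm["b", ]), c(1, 2))
  expect_true(attr(norm, "normalized"))
  expect_error(area_normalize(norm, cells), "already")

  set.seed(1)
  cells5 <- data.frame(cell_id = paste0("c", 1:5),
                       area_um2 = runif(5, 10, 100))
  m <- matrix(rpois(15, 4), 5, 3,
              dimnames = list(cells5$cell_id, paste0("g", 1:3)))
  expect_equal(unname(area_normalize(m, cells5)),
               unname(m / cells5$area_um2), ignore_attr = TRUE)
  bad <- cells5; bad$area_um2[2] <- 0
  expect_error(area_normalize(m, bad), "positive")
})

test_that("acosh transform is monotone, zero-preserving and invertible", {
  expect_equal(acosh_transform(0), 0)
  expect_equal(acosh_transform(cosh(2) - 1), 2)
  x <- sort(runif(50, 0, 10))
  expect_true(all(diff(acosh_transform(x)) > 0))
  expect_error(acosh_transform(-1), "nonnegative")
})

test_that("confidence AUC handles degenerate input and orders candidates", {
  expect_equal(confidence_auc(rep(0.95, 30)), 1)
  expect_equal(confidence_auc(rep(0.60, 30)), 0)
  expect_error(confidence_auc(numeric(0)))

  set.seed(42)
  good <- rbeta(500, 20, 1)
  poor <- rbeta(500, 5, 5)
  expect_gt(confidence_auc(good), confidence_auc(poor))
  expect_true(confidence_auc(good) >= 0 && confidence_auc(good) <= 1)

  # approximate invariance to duplicating every observation (bandwidth
  # shrinks slightly with n under Scott's rule)
  expect_equal(confidence_auc(c(good, good)), confidence_auc(good),
               tolerance = 0.02)

  # cross-check against trapezoidal integration on a 10x finer grid
  h <- bw.nrd(good)
  d <- density(good, bw = h, n = 5120,
               from = min(good) - 3 * h, to = max(good) + 3 * h)
  inside <- d$x >= 0.75 & d$x <= 1
  fine <- sum(diff(d$x[inside]) *
              (head(d$y[inside], -1) + tail(d$y[inside], -1)) / 2) /
          sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  expect_equal(confidence_auc(good), min(1, fine), tolerance = 1e-3)
})

test_that("segmentation selection takes the AUC argmax with stable ties", {
  one <- list(list(candidate_id = "only",
                   cells = data.frame(avg_assignment_confidence = rep(0.8, 5))))
  expect_equal(as.character(select_segmentation(one)), "only")

  two <- list(
    list(candidate_id = "hi", cells = data.frame(avg_assignment_confidence = rep(0.95, 9))),
    list(candidate_id = "lo", cells = data.frame(avg_assignment_confidence = rep(0.60, 9)))
  )
  expect_equal(as.character(select_segmentation(two)), "hi")

  # lexicographic tie-break on equal AUC
  tie <- list(
    list(candidate_id = "b", cells = data.frame(avg_assignment_confidence = rep(0.9, 4))),
    list(candidate_id = "a", cells = data.frame(avg_assignment_confidence = rep(0.9, 4)))
  )
  expect_equal(as.character(select_segmentation(tie)), "a")

  # Beta(20,1) beats Beta(5,5) across seeds
  for (sd in 1:10) {
    cfg <- tiny_config(cells = 200, seed = sd,
                       confidence_beta = list(good = c(20, 1), bad = c(5, 5)))
    cand <- generate_candidates(cfg, "s1", seed = sd)
    expect_equal(as.character(select_segmentation(cand)), "good")
  }
})

test_that("noise fraction counts unassigned transcripts", {
  tx <- do.call(rbind, c(replicate(75, make_tx(30, 0.9), simplify = FALSE),
                         replicate(25, make_tx(30, 0, noise = TRUE),
                                   simplify = FALSE)))
  expect_equal(noise_fraction(tx), 0.25)
  expect_equal(noise_fraction(tx[1:75, ]), 0)
  expect_error(noise_fraction(tx[0, ]), "undefined")

  cfg <- tiny_config(cells = 700, noise_transcript_rate = 0.1)
  s <- generate_sample(cfg, "s1")
  nf <- noise_fraction(s$transcripts)
  n <- nrow(s$transcripts)
  expect_lt(abs(nf - 0.1), 2.58 * sqrt(0.1 * 0.9 / n) + 1 / n)
})
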