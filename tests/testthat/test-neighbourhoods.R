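chain_cells <- function(labels = c("A", "B", "A", "B")) {
  data.frame(cell_id = paste0("c", 1:4), sample_id = "s",
             x_um = c(0, 90, 180, 500), y_um = 0,
             substate = labels, stringsAsFactors = FALSE)
}

test_that("radius graph contains exactly the pairs within the closed ball", {
  single <- data.frame(cell_id = "c", sample_id = "s", x_um = 0, y_um = 0)
  expect_equal(nrow(radius_graph(single)$edges), 0)

  g <- radius_graph(chain_cells(), 100)
  expect_equal(g$edges[, c("i", "j")],
               data.frame(i = 1:2, j = 2:3), ignore_attr = TRUE)

  # inclusive boundary
  pair <- data.frame(cell_id = c("a", "b"), sample_id = "s",
                     x_um = c(0, 100), y_um = 0)
  expect_equal(nrow(radius_graph(pair, 100)$edges), 1)

  # no cross-sample edges
  two <- data.frame(cell_id = c("a", "b"), sample_id = c("s1", "s2"),
                    x_um = c(0, 1), y_um = 0)
  expect_equal(nrow(radius_graph(two)$edges), 0)

  # 300 random cells match the O(n^2) oracle
  set.seed(2)
  cells <- data.frame(cell_id = paste0("c", 1:300), sample_id = "s",
                      x_um = runif(300, 0, 1000), y_um = runif(300, 0, 1000))
  g2 <- radius_graph(cells, 80)
  oracle <- brute_radius_edges(cells$x_um, cells$y_um, 80)
  got <- as.matrix(g2$edges[, c("i", "j")])
  expect_equal(got[order(got[, 1], got[, 2]), ],
               oracle[order(oracle[, 1], oracle[, 2]), ],
               ignore_attr = TRUE)
})

test_that("neighbourhood matrix counts neighbours per substate", {
  cells <- chain_cells(c("A", "B", "A", "B"))
  g <- radius_graph(cells, 100)
  nm <- neighbourhood_matrix(cells, g)
  expect_equal(unname(nm[1, ]), c(0, 1))  # c1 sees one B
  expect_equal(unname(nm[2, ]), c(2, 0))  # c2 sees two A
  expect_equal(unname(nm[3, ]), c(0, 1))
  expect_equal(unname(nm[4, ]), c(0, 0))  # isolated: zero row

  with_self <- neighbourhood_matrix(cells, g, include_self = TRUE)
  expect_equal(unname(with_self[4, ]), c(0, 1))

  # random instance equals per-cell brute tally; row sums equal degree
  set.seed(4)
  rc <- data.frame(cell_id = paste0("c", 1:200), sample_id = "s",
                   x_um = runif(200, 0, 800), y_um = runif(200, 0, 800),
                   substate = sample(c("A", "B", "C"), 200, replace = TRUE))
  g2 <- radius_graph(rc, 90)
  nm2 <- neighbourhood_matrix(rc, g2)
  deg <- tabulate(c(g2$edges$i, g2$edges$j), 200)
  expect_equal(unname(rowSums(nm2)), deg)
  for (i in sample(200, 20)) {
    nbs <- c(g2$edges$j[g2$edges$i == i], g2$edges$i[g2$edges$j == i])
    for (s in c("A", "B", "C")) {
      expect_equal(nm2[i, s], sum(rc$substate[nbs] == s))
    }
  }
})

test_that("neighbourhood clustering is deterministic and handles degeneracy", {
  flat <- matrix(1, 40, 3)
  cl <- cluster_neighbourhoods(flat, knn_k = 5, seed = 1)
  expect_equal(length(unique(cl$labels)), 1)

  set.seed(6)
  X <- rbind(matrix(rpois(200 * 3, c(20, 1, 1)), 200, 3, byrow = TRUE),
             matrix(rpois(200 * 3, c(1, 20, 1)), 200, 3, byrow = TRUE))
  a <- cluster_neighbourhoods(X, knn_k = 10, resolution = 0.05, seed = 3)
  b <- cluster_neighbourhoods(X, knn_k = 10, resolution = 0.05, seed = 3)
  expect_identical(a$labels, b$labels)
  expect_error(cluster_neighbourhoods(X[1:5, ], knn_k = 10), "knn_k")

  # signatures: recomputing from labels and the matrix reproduces them
  sig <- rowsum(X, a$labels) / as.integer(table(a$labels))
  expect_equal(a$signatures, sig)
})

test_that("enrichment scores count within-cluster edges per substate pair", {
  cells <- chain_cells(c("A", "B", "A", "B"))
  g <- radius_graph(cells, 100)
  es <- enrichment_score(g, cells$substate, 1:4)
  expect_equal(es["A", "B"], 2)
  expect_equal(es["A", "A"], 0)
  expect_equal(es["B", "B"], 0)
  expect_equal(sum(es), nrow(g$edges))

  empty <- enrichment_score(g, cells$substate, integer(0))
  expect_true(all(empty == 0))

  # random instances equal the brute-force oracle, with conservation
  set.seed(5)
  for (rep in 1:5) {
    n <- 120
    cells2 <- data.frame(cell_id = paste0("c", 1:n), sample_id = "s",
                         x_um = runif(n, 0, 500), y_um = runif(n, 0, 500),
                         substate = sample(c("A", "B", "C", "D"), n, TRUE))
    g2 <- radius_graph(cells2, 70)
    members <- sample(n, 70)
    es2 <- enrichment_score(g2, cells2$substate, members)
    oracle <- brute_enrichment(as.matrix(g2$edges[, c("i", "j")]),
                               cells2$substate, members, c("A", "B", "C", "D"))
    expect_identical(unname(es2), unname(oracle))
    keep <- logical(n); keep[members] <- TRUE
    expect_equal(sum(es2), sum(keep[g2$edges$i] & keep[g2$edges$j]))
  }
})

test_that("Monte-Carlo p-value formulas reproduce forced values", {
  mc <- mc_pvalues(l = 3, r = 0, N = 3)
  expect_equal(mc$p_left, 1)
  expect_equal(mc$p_right, 0.25)
  expect_equal(mc$p_two, 0.5)

  tie <- mc_pvalues(l = 0, r = 0, N = 10)
  expect_equal(tie$p_left, 1 / 11)
  expect_equal(tie$p_right, 1 / 11)
  expect_equal(tie$p_two, 2 / 11)

  expect_error(mc_pvalues(5, 6, 10), "l \\+ r")
  expect_error(mc_pvalues(0, 0, 0), "at least 1")
})

test_that("Agresti-Coull intervals follow the pseudo-count formula", {
  ci <- agresti_coull_ci(2, 8, z = 2)
  expect_equal(ci[, "lo"], 1 / 3 - 2 * sqrt((1 / 3) * (2 / 3) / 12),
               ignore_attr = TRUE)
  expect_equal(ci[, "hi"], 1 / 3 + 2 * sqrt((1 / 3) * (2 / 3) / 12),
               ignore_attr = TRUE)
  expect_gte(agresti_coull_ci(0, 10)[, "lo"], 0)
  expect_lte(agresti_coull_ci(10, 10)[, "hi"], 1)
  expect_error(agresti_coull_ci(1, 0), "positive")

  # coverage at a small tail proportion, the regime the permutation test
  # uses the interval in
  set.seed(13)
  x <- rbinom(1000, 999, 0.05)
  ci <- agresti_coull_ci(x, 999)
  covered <- ci[, "lo"] <= 0.05 & ci[, "hi"] >= 0.05
  expect_gte(mean(covered), 0.93)
})

test_that("permutation test conserves scores and flags planted adjacency", {
  # two substates planted adjacent within one cluster come out significant
  hits <- 0
  for (sd in 1:10) {
    set.seed(sd)
    n_half <- 60
    cells <- data.frame(
      cell_id = paste0("c", 1:(2 * n_half)), sample_id = "s",
      x_um = c(runif(n_half, 0, 220), runif(n_half, 800, 1400)),
      y_um = runif(2 * n_half, 0, 220),
      substate = c(sample(rep(c("A", "B"), n_half / 2)),
                   sample(c("A", "B", "C"), n_half, TRUE)),
      stringsAsFactors = FALSE)
    g <- radius_graph(cells, 100)
    clusters <- rep(1:2, each = n_half)
    pt <- permutation_test(cells, g, clusters, N = 500, seed = sd)
    row <- pt[pt$cluster == "1" & pt$substate_a == "A" & pt$substate_b == "B", ]
    hits <- hits + (row$fdr < 0.05)
    expect_true(all(pt$p_left > 0 & pt$p_right > 0 & pt$p_two > 0))
    expect_true(all(pt$p_two <= 1))
    expect_true(all(pt$ci_lo <= pt$ci_hi))
  }
  expect_gte(hits, 9)
})
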