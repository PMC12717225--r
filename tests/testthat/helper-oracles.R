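# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair counting, fan triangulation,
# winding numbers, and a hand-written step-up FDR.

# O(n^2) brute-force radius graph: all unordered pairs within r.
brute_radius_edges <- function(x, y, r) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r) {
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), ncol = 2)
}

# Brute-force enrichment: loop over edges, tally unordered label pairs of
# edges with both endpoints in the member set.
brute_enrichment <- function(edges, labels, members, levels) {
  S <- length(levels)
  m <- matrix(0L, S, S, dimnames = list(levels, levels))
  memb <- rep(FALSE, length(labels))
  memb[members] <- TRUE
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (memb[i] && memb[j]) {
      a <- match(labels[i], levels); b <- match(labels[j], levels)
      lo <- min(a, b); hi <- max(a, b)
      m[lo, hi] <- m[lo, hi] + 1L
    }
  }
  m
}

# Fan triangulation area of a polygon (signed triangles from vertex 1).
fan_triangulation_area <- function(v) {
  n <- nrow(v)
  tot <- 0
  for (i in 2:(n - 1)) {
    tot <- tot + ((v[i, 1] - v[1, 1]) * (v[i + 1, 2] - v[1, 2]) -
                  (v[i + 1, 1] - v[1, 1]) * (v[i, 2] - v[1, 2])) / 2
  }
  abs(tot)
}

# Winding-number point-in-polygon (nonzero rule; agrees with even-odd for
# the simple polygons used in tests). Boundary handled with a tolerance.
winding_inside <- function(px, py, v, tol = 1e-9) {
  n <- nrow(v)
  vapply(seq_along(px), function(q) {
    wn <- 0
    on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      x1 <- v[j, 1]; y1 <- v[j, 2]; x2 <- v[i, 1]; y2 <- v[i, 2]
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      t <- if (len2 == 0) 0 else ((px[q] - x1) * dx + (py[q] - y1) * dy) / len2
      t <- min(1, max(0, t))
      if (sqrt((px[q] - (x1 + t * dx))^2 + (py[q] - (y1 + t * dy))^2) <= tol) {
        on_edge <- TRUE
      }
      if (y1 <= py[q]) {
        if (y2 > py[q] && (dx * (py[q] - y1) - dy * (px[q] - x1)) > 0) wn <- wn + 1
      } else {
        if (y2 <= py[q] && (dx * (py[q] - y1) - dy * (px[q] - x1)) < 0) wn <- wn - 1
      }
      j <- i
    }
    on_edge || wn != 0
  }, logical(1))
}

# Hand-written Benjamini-Hochberg step-up adjustment.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Small convenience configuration for fast synthetic samples.
tiny_config <- function(..., cells = 300, seed = 1) {
  sim_config(n_samples = 2, cells_per_sample = cells, seed = seed, ...)
}

# Adjusted Rand index between two labelings (closed form from the
# contingency table), so acceptance checks do not depend on the clustering
# code under test.
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
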