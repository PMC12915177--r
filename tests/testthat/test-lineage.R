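make_cluster_cells <- function(centers, per = 5, sd = 0) {
  n <- nrow(centers) * per
  set.seed(42)
  data.frame(id = paste0("c", seq_len(n)),
             cluster = rep(rownames(centers), each = per),
             emb_1 = rep(centers[, 1], each = per) + rnorm(n, sd = sd),
             emb_2 = rep(centers[, 2], each = per) + rnorm(n, sd = sd))
}

cells_experiment <- function(cells) {
  cell_experiment(matrix(1L, 2, nrow(cells),
                         dimnames = list(c("g1", "g2"), cells$id)),
                  genes = data.frame(id = c("g1", "g2")), cells = cells)
}

test_that("MST of collinear centroids is the chain, 2 clusters a single edge", {
  centers <- rbind(A = c(0, 0), B = c(1, 0), C = c(2, 0))
  g <- build_cluster_graph(cells_experiment(make_cluster_cells(centers)))
  edges <- apply(g$edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(edges, c("A-B", "B-C"))
  centers2 <- centers[1:2, ]
  g2 <- build_cluster_graph(cells_experiment(make_cluster_cells(centers2)))
  expect_equal(nrow(g2$edges), 1)
})

test_that("star layouts give star trees, matching a brute-force MST", {
  theta <- seq(0, 2 * pi, length.out = 6)[-6]
  centers <- rbind(hub = c(0, 0), t(sapply(theta, function(a)
    c(cos(a), sin(a)))))
  rownames(centers) <- c("hub", paste0("S", 1:5))
  g <- build_cluster_graph(cells_experiment(make_cluster_cells(centers)))
  expect_true(all(g$edges[, 1] == "hub" | g$edges[, 2] == "hub"))
  expect_equal(mst_weight(g), brute_force_mst_weight(g$centroids),
               tolerance = 1e-12)
})

test_that("MST matches independent references on random layouts of <= 8 clusters", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    centers <- matrix(runif(2 * n, 0, 10), ncol = 2,
                      dimnames = list(paste0("K", seq_len(n)), NULL))
    g <- build_cluster_graph(cells_experiment(make_cluster_cells(centers)))
    d <- as.matrix(stats::dist(g$centroids))
    ig <- igraph::mst(igraph::graph_from_adjacency_matrix(
      d, mode = "undirected", weighted = TRUE))
    ig_w <- sum(igraph::E(ig)$weight)
    expect_equal(mst_weight(g), ig_w, tolerance = 1e-9)
    if (n <= 5)
      expect_equal(mst_weight(g), brute_force_mst_weight(g$centroids),
                   tolerance = 1e-9)
  }
})

test_that("clusters with fewer than 3 cells are rejected", {
  cells <- make_cluster_cells(rbind(A = c(0, 0), B = c(1, 0)), per = 5)
  cells <- cells[-(1:3), ]  # cluster A left with 2 cells
  expect_error(build_cluster_graph(cells_experiment(cells)), "fewer than 3")
})

test_that("lineage extraction yields one root-to-leaf path per leaf", {
  centers <- rbind(R = c(0, 0), M = c(1, 0), A = c(1.5, 1), B = c(1.5, -1),
                   C = c(2.2, 0))
  g <- build_cluster_graph(cells_experiment(make_cluster_cells(centers)))
  lin <- infer_lineages(g, "R")
  expect_length(lin$paths, 3)            # leaves A, B, C off the M hub
  expect_true(all(vapply(lin$paths, function(p) p[1] == "R", logical(1))))
  expect_identical(names(lin$paths), sort(names(lin$paths)))
  # a path graph rooted at one end is a single lineage
  centers2 <- rbind(R = c(0, 0), M = c(1, 0), E = c(2, 0))
  g2 <- build_cluster_graph(cells_experiment(make_cluster_cells(centers2)))
  expect_length(infer_lineages(g2, "R")$paths, 1)
})

test_that("the synthetic branching dataset's topology is recovered", {
  ms <- medium_sim()
  expect_length(ms$lin$paths, 3)
  # each inferred lineage terminates in the matching truth lineage's last bin
  terminals <- vapply(ms$lin$paths, function(p) p[length(p)], character(1))
  expect_setequal(substr(terminals, 1, 2), c("L1", "L2", "L3"))
})

test_that("pseudotime equals distance from the root centroid on a straight curve", {
  centers <- rbind(A = c(0, 0), B = c(4, 0))
  cells <- make_cluster_cells(centers, per = 6)
  cells$emb_2 <- 0
  cells$emb_1 <- rep(seq(0, 4, length.out = 12))
  cells$cluster <- rep(c("A", "B"), each = 6)
  ex <- cells_experiment(cells)
  g <- build_cluster_graph(ex)
  lin <- fit_pseudotime(ex, infer_lineages(g, "A"))
  # control points are the two centroids; arc length = x - x(centroid A)
  expected <- pmax(0, pmin(cells$emb_1 - mean(cells$emb_1[cells$cluster == "A"]),
                           diff(range(g$centroids[, 1]))))
  expect_equal(unname(lin$pseudotime[, 1]), expected, tolerance = 1e-9)
})

test_that("weights sum to one and are split evenly between equidistant curves", {
  ms <- medium_sim()
  expect_equal(unname(rowSums(ms$lin$weights)),
               rep(1, nrow(ms$lin$weights)), tolerance = 1e-12)
  # root-segment cells lie on the shared part of all three polylines:
  # distances tie, so weights are equal across lineages
  root_cells <- ms$sim$truth$pseudotime < 0.05
  w <- ms$lin$weights[root_cells, , drop = FALSE]
  expect_lt(max(abs(w - 1 / 3)), 1e-6)
})

test_that("inferred pseudotime tracks the simulated ordering", {
  ms <- medium_sim()
  for (l in colnames(ms$lin$pseudotime)) {
    sel <- ms$lin$assignment == l
    rho <- cor(ms$lin$pseudotime[sel, l], ms$sim$truth$pseudotime[sel],
               method = "spearman")
    expect_gte(abs(rho), 0.95)
  }
})

test_that("pseudotime is invariant to rigid transforms of the embedding", {
  ms <- medium_sim()
  ex <- ms$sim$experiment
  phi <- 0.83
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  xy <- cbind(ex$cells$emb_1, ex$cells$emb_2) %*% R
  ex2 <- ex
  ex2$cells$emb_1 <- xy[, 1] + 5
  ex2$cells$emb_2 <- xy[, 2] - 3
  g2 <- build_cluster_graph(ex2)
  lin2 <- fit_pseudotime(ex2, infer_lineages(g2, "root_b1"))
  expect_equal(lin2$pseudotime, ms$lin$pseudotime, tolerance = 1e-8)
  expect_equal(lin2$weights, ms$lin$weights, tolerance = 1e-8)
})

test_that("curve refinement converges quietly and warns when capped", {
  ms <- medium_sim()
  ex <- ms$sim$experiment
  lin0 <- infer_lineages(ms$graph, "root_b1")
  refined <- fit_pseudotime(ex, lin0, n_iter = 25, tol = 1e-2)
  expect_true(refined$converged)
  expect_warning(fit_pseudotime(ex, lin0, n_iter = 1, tol = 1e-12),
                 "did not converge")
})

test_that("knots sit at evenly spaced quantiles and K = 2 spans the range", {
  ms <- medium_sim()
  lin <- ms$lin
  idx <- cbind(seq_len(nrow(lin$pseudotime)),
               match(lin$assignment, colnames(lin$pseudotime)))
  pooled <- lin$pseudotime[idx][lin$weights[idx] >= 0.5 - 1e-8]
  expect_equal(ms$knots$positions,
               unname(quantile(pooled, seq(0, 1, 0.25), type = 7)))
  k2 <- place_knots(lin, K = 2)
  expect_equal(k2$positions, c(min(pooled), max(pooled)))
  expect_true(all(diff(ms$knots$positions) > 0))
})

test_that("uniform pooled pseudotime puts 5 knots near (0, .25, .5, .75, 1)", {
  set.seed(17)
  n <- 4000
  pt <- matrix(runif(n), ncol = 1, dimnames = list(NULL, "lin_X"))
  lin <- structure(list(paths = list(lin_X = c("A", "B")),
                        pseudotime = pt,
                        weights = matrix(1, n, 1,
                                         dimnames = list(NULL, "lin_X")),
                        assignment = rep("lin_X", n)),
                   class = "lineage_set")
  k <- place_knots(lin, K = 5)
  expect_equal(k$positions, c(0, 0.25, 0.5, 0.75, 1), tolerance = 0.02)
})

test_that("a lineage ending before the penultimate knot is rejected", {
  ms <- medium_sim()
  lin <- ms$lin
  # truncate one lineage's pseudotime artificially
  short <- colnames(lin$pseudotime)[2]
  sel <- lin$assignment == short
  lin$pseudotime[sel, short] <- lin$pseudotime[sel, short] * 0.3
  expect_error(place_knots(lin), "ends before knot")
})
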