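# shared fixtures, built once per test run

# tiny hand-constructed experiment for exact filter checks
tiny_experiment <- function() {
  counts <- matrix(0L, nrow = 6, ncol = 4)
  counts[1, ] <- c(5L, 2L, 0L, 1L)
  counts[2, ] <- c(1L, 0L, 3L, 0L)
  counts[3, ] <- c(0L, 4L, 1L, 2L)
  counts[4, ] <- c(2L, 1L, 0L, 0L)
  counts[5, ] <- c(0L, 0L, 2L, 1L)
  counts[6, ] <- c(3L, 1L, 1L, 0L)
  cell_experiment(
    counts,
    genes = data.frame(id = paste0("g", 1:6), symbol = paste0("g", 1:6),
                       is_mito = c(TRUE, rep(FALSE, 5)),
                       is_ribo = FALSE, is_noncoding = FALSE),
    cells = data.frame(id = paste0("c", 1:4),
                       tissue = c("blood", "biopsy", "blood", "biopsy"),
                       cluster = c("A", "A", "B", "B"),
                       emb_1 = c(0, 0.1, 1, 1.1),
                       emb_2 = c(0, 0.1, 0, 0.1)))
}

# medium branching simulation reused by the lineage / DE / marker tests
sim_cache <- new.env()
medium_sim <- function() {
  if (is.null(sim_cache$sim)) {
    cfg <- trajectory_sim_config(n_lineages = 3, cells_per_lineage = 300,
                                 n_genes = 400, n_planted_markers = 10,
                                 planted_log2fc = 2, seed = 7L)
    sim <- simulate_trajectory_dataset(cfg)
    graph <- build_cluster_graph(sim$experiment)
    lin <- fit_pseudotime(sim$experiment, infer_lineages(graph, "root_b1"))
    knots <- place_knots(lin)
    sim_cache$sim <- list(sim = sim, graph = graph, lin = lin, knots = knots)
  }
  sim_cache$sim
}

medium_fits <- function() {
  if (is.null(sim_cache$fits)) {
    ms <- medium_sim()
    sim_cache$fits <- fit_nb_smoothers(ms$sim$experiment, ms$lin, ms$knots)
  }
  sim_cache$fits
}

focal_inferred <- function(lin) grep("^lin_L1_", colnames(lin$pseudotime),
                                     value = TRUE)[1]

# independent brute-force minimum spanning tree: enumerate all edge subsets
# of size n-1 and keep the lightest connected one
brute_force_mst_weight <- function(centroids) {
  d <- as.matrix(stats::dist(centroids))
  n <- nrow(centroids)
  all_edges <- t(utils::combn(n, 2))
  best <- Inf
  for (sel in utils::combn(nrow(all_edges), n - 1, simplify = FALSE)) {
    e <- all_edges[sel, , drop = FALSE]
    # connectivity via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (r in seq_len(nrow(e))) {
      a <- find(e[r, 1]); b <- find(e[r, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (!ok) next
    w <- sum(d[e])
    if (w < best) best <- w
  }
  best
}

mst_weight <- function(graph) {
  d <- as.matrix(stats::dist(graph$centroids))
  sum(apply(graph$edges, 1, function(e) d[e[1], e[2]]))
}

# Cox partial log-likelihood (Breslow would differ with ties; fixtures are
# tie-free) for grid-search oracles
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
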