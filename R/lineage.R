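#' Minimum spanning tree over cluster centroids
#'
#' Computes cluster centroids in the 2-D embedding and connects them by a
#' Euclidean minimum spanning tree (Prim's algorithm, deterministic
#' lowest-index tie-break). This is the cluster-graph stage preceding lineage
#' inference.
#'
#' @param experiment a [cell_experiment()] whose cell table has `cluster`,
#'   `emb_1`, `emb_2`.
#' @return a `cluster_graph`: list with `centroids` (clusters x 2 matrix,
#'   rownames = cluster names) and `edges` (two-column character matrix).
#' @export
build_cluster_graph <- function(experiment) {
  cl <- experiment$cells$cluster
  emb <- cbind(experiment$cells$emb_1, experiment$cells$emb_2)
  if (is.null(cl) || is.null(experiment$cells$emb_1))
    stop("cell table needs 'cluster', 'emb_1' and 'emb_2' columns")
  sizes <- table(cl)
  if (length(sizes) < 2) stop("need at least 2 clusters")
  small <- names(sizes)[sizes < 3]
  if (length(small))
    stop("cluster(s) with fewer than 3 cells (centroid unstable): ",
         paste(small, collapse = ", "))
  cents <- do.call(rbind, lapply(sort(names(sizes)), function(k)
    colMeans(emb[cl == k, , drop = FALSE])))
  rownames(cents) <- sort(names(sizes))
  d <- as.matrix(stats::dist(cents))
  n <- nrow(cents)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(character(0), ncol = 2)
  for (step in seq_len(n - 1)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    k <- which(dd == min(dd), arr.ind = TRUE)[1, ]  # lowest-index tie-break
    from <- rownames(cents)[in_tree][k[1]]
    to <- rownames(cents)[!in_tree][k[2]]
    edges <- rbind(edges, c(from, to))
    in_tree[match(to, rownames(cents))] <- TRUE
  }
  structure(list(centroids = cents, edges = edges), class = "cluster_graph")
}

graph_adjacency <- function(graph) {
  nodes <- rownames(graph$centroids)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges[i, 1]; b <- graph$edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Extract rooted lineages from a cluster tree
#'
#' One lineage per leaf: the unique root-to-leaf cluster path. Lineages are
#' ordered (and named) lexicographically by their terminal cluster, so the
#' result is deterministic.
#'
#' @param graph a `cluster_graph` from [build_cluster_graph()].
#' @param root_cluster name of the starting cluster (in the study design, the
#'   classical-monocyte cluster).
#' @return a `lineage_set` with element `paths`, a named list of cluster
#'   vectors starting at the root.
#' @export
infer_lineages <- function(graph, root_cluster) {
  adj <- graph_adjacency(graph)
  if (!root_cluster %in% names(adj))
    stop("root cluster '", root_cluster, "' not found")
  paths <- list()
  walk <- function(node, path) {
    nxt <- setdiff(adj[[node]], path)
    if (!length(nxt)) {
      paths[[node]] <<- c(path, node)
    } else {
      for (child in nxt) walk(child, c(path, node))
    }
  }
  walk(root_cluster, character(0))
  paths <- paths[sort(names(paths))]
  names(paths) <- paste0("lin_", names(paths))
  structure(list(paths = paths, root = root_cluster,
                 centroids = graph$centroids),
            class = "lineage_set")
}

#' @export
print.lineage_set <- function(x, ...) {
  cat("lineage_set with", length(x$paths), "lineage(s), root =", x$root, "\n")
  for (nm in names(x$paths))
    cat("  ", nm, ": ", paste(x$paths[[nm]], collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# project points onto a polyline; returns arc length of projection and
# distance to the curve
project_polyline <- function(points, ctrl) {
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_arc <- rep(0, n)
  cum <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  for (s in seq_len(nrow(ctrl) - 1)) {
    a <- ctrl[s, ]; b <- ctrl[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, ((points[, 1] - a[1]) * ab[1] +
                       (points[, 2] - a[2]) * ab[2]) / len2))
    px <- a[1] + tt * ab[1]; py <- a[2] + tt * ab[2]
    d2 <- (points[, 1] - px)^2 + (points[, 2] - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[s] + tt[upd] * sqrt(len2)
  }
  list(arc = best_arc, d2 = best_d2)
}

#' Fit per-cell pseudotime and lineage weights
#'
#' Each lineage's curve is the piecewise-linear polyline through its ordered
#' cluster centroids; cells are projected onto every curve, pseudotime is the
#' arc length to the projection, and lineage weights are a softmax of the
#' negative squared distances (temperature = mean squared distance to the
#' nearest curve, which makes the weights invariant to rigid transforms and
#' to global rescaling of the embedding). Curves can optionally be refined by
#' recomputing control points as weighted cell means within arc-length bins.
#'
#' @param experiment a [cell_experiment()].
#' @param lineages a `lineage_set` from [infer_lineages()].
#' @param n_iter maximum refinement iterations (0 = keep centroid polylines).
#' @param tol convergence tolerance on the maximum control-point shift.
#' @return the `lineage_set` augmented with `curves` (control points),
#'   `pseudotime` and `weights` (cells x lineages matrices), `assignment`
#'   (hard argmax-weight lineage per cell, ties broken lexicographically) and
#'   `converged` (FALSE triggers a warning, never an error).
#' @export
fit_pseudotime <- function(experiment, lineages, n_iter = 0, tol = 1e-3) {
  pts <- cbind(experiment$cells$emb_1, experiment$cells$emb_2)
  lin_names <- names(lineages$paths)
  curves <- lapply(lineages$paths, function(p)
    lineages$centroids[p, , drop = FALSE])

  project_all <- function(curves) {
    arc <- d2 <- matrix(NA_real_, nrow(pts), length(curves),
                        dimnames = list(experiment$cells$id, lin_names))
    for (l in seq_along(curves)) {
      pr <- project_polyline(pts, curves[[l]])
      arc[, l] <- pr$arc; d2[, l] <- pr$d2
    }
    list(arc = arc, d2 = d2)
  }
  softmax_weights <- function(d2) {
    dmin <- apply(d2, 1, min)
    tau <- max(mean(dmin), 1e-12)
    w <- exp(-(d2 - dmin) / tau)
    w / rowSums(w)
  }

  pr <- project_all(curves)
  converged <- TRUE
  if (n_iter > 0) {
    converged <- FALSE
    for (it in seq_len(n_iter)) {
      w <- softmax_weights(pr$d2)
      shift <- 0
      for (l in seq_along(curves)) {
        ctrl <- curves[[l]]
        arcs <- pr$arc[, l]
        cum <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
        new_ctrl <- ctrl
        for (k in seq_len(nrow(ctrl))) {
          lo <- if (k == 1) -Inf else (cum[k - 1] + cum[k]) / 2
          hi <- if (k == nrow(ctrl)) Inf else (cum[k] + cum[k + 1]) / 2
          sel <- arcs >= lo & arcs < hi & w[, l] > 0.1
          if (sum(sel) >= 3)
            new_ctrl[k, ] <- colSums(pts[sel, , drop = FALSE] * w[sel, l]) /
              sum(w[sel, l])
        }
        shift <- max(shift, max(abs(new_ctrl - ctrl)))
        curves[[l]] <- new_ctrl
      }
      pr <- project_all(curves)
      if (shift < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("curve refinement did not converge in ", n_iter,
              " iterations; returning best iterate")
  }

  w <- softmax_weights(pr$d2)
  # hard assignment: argmax weight, exact ties to the lexicographically
  # first lineage (columns are already sorted)
  assignment <- lin_names[apply(w, 1, function(r)
    which(r >= max(r) - 1e-9)[1])]
  lineages$curves <- curves
  lineages$pseudotime <- pr$arc
  lineages$weights <- w
  lineages$assignment <- assignment
  lineages$converged <- converged
  lineages
}

#' Place a shared knot grid on pooled pseudotime
#'
#' Knots sit at the evenly spaced quantiles `0, 1/(K-1), ..., 1` of the
#' pooled pseudotime of confidently assigned cells: each cell whose maximum
#' lineage weight reaches 0.5 (up to numerical tolerance) contributes its
#' pseudotime on its assigned lineage once. The grid is shared across
#' lineages.
#'
#' @param lineages a `lineage_set` with pseudotime and weights (from
#'   [fit_pseudotime()]).
#' @param K number of knots (default 5; the tested segment is knots 3 to 4).
#' @return a `knot_grid`: list with `positions` (length K, strictly
#'   increasing) and `K`.
#' @export
place_knots <- function(lineages, K = 5) {
  stopifnot(K >= 2)
  w <- lineages$weights
  pt <- lineages$pseudotime
  assign_col <- match(lineages$assignment, colnames(pt))
  idx <- cbind(seq_len(nrow(pt)), assign_col)
  sel <- w[idx] >= 0.5 - 1e-8
  pooled <- pt[idx][sel]
  if (!length(pooled)) stop("no cell reaches lineage weight 0.5")
  knots <- unname(stats::quantile(pooled, probs = seq(0, 1, length.out = K),
                                  type = 7))
  if (any(diff(knots) <= 0))
    stop("knot positions are not strictly increasing; ",
         "pseudotime too concentrated for K = ", K)
  for (l in colnames(pt)) {
    lmax <- max(pt[lineages$assignment == l, l])
    if (lmax < knots[K - 1])
      stop("lineage '", l, "' ends before knot ", K - 1,
           "; too short to test a between-knot segment ending there")
  }
  structure(list(positions = knots, K = K), class = "knot_grid")
}
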