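#' Fit per-gene negative-binomial spline smoothers along lineages
#'
#' For every gene a single negative-binomial regression is fitted whose
#' design is a block cubic B-spline basis: one block per lineage (knots from
#' the shared [place_knots()] grid), with exactly one block active per cell
#' according to its hard lineage assignment, and an offset equal to the log
#' library size. The per-gene dispersion is a method-of-moments estimate from
#' a preliminary Poisson fit (floored at 1e-8) and is held fixed during the
#' negative-binomial IRLS, which keeps the fit stable at moderate cell
#' numbers. Coefficients and their joint covariance are stored so that
#' between-knot lineage contrasts can be Wald-tested afterwards.
#'
#' Genes whose fit does not converge are flagged and excluded from testing
#' (reported, not fatal); all-zero genes violate the upstream filter contract
#' and raise an error.
#'
#' @param experiment a [cell_experiment()], gene-filtered via
#'   [filter_genes_for_de()].
#' @param lineages a `lineage_set` with pseudotime and assignment
#'   ([fit_pseudotime()]).
#' @param knots a `knot_grid` from [place_knots()].
#' @param dispersion_method currently `"mom"` (method of moments).
#' @param libsize optional per-cell library sizes for the offset (default:
#'   column sums of the count matrix). Multiplying all library sizes by a
#'   constant leaves the Wald statistics unchanged (each lineage block
#'   absorbs the constant).
#' @return a `smoother_fit`: list with `coef` (genes x coefficients, aliased
#'   coefficients as 0), `vcov` (list of per-gene covariance matrices,
#'   aliased rows/columns 0), `theta` (per-gene NB size), `knots`,
#'   `lineage_names`, `basis` metadata and `flagged` (non-converged genes).
#' @export
fit_nb_smoothers <- function(experiment, lineages, knots,
                             dispersion_method = c("mom"), libsize = NULL) {
  dispersion_method <- match.arg(dispersion_method)
  counts <- as.matrix(experiment$counts)
  if (any(Matrix::rowSums(counts) == 0))
    stop("all-zero gene(s) present; run filter_genes_for_de() first")
  if (is.null(libsize)) libsize <- colSums(counts)
  stopifnot(length(libsize) == ncol(counts), all(libsize > 0))
  off <- log(libsize)

  lin_names <- colnames(lineages$pseudotime)
  assign_idx <- match(lineages$assignment, lin_names)
  pt <- lineages$pseudotime[cbind(seq_len(nrow(lineages$pseudotime)),
                                  assign_idx)]
  basis <- knot_basis(knots)
  B <- eval_knot_basis(basis, pt)
  p_block <- ncol(B)
  p <- p_block * length(lin_names)
  X <- matrix(0, nrow = length(pt), ncol = p)
  for (l in seq_along(lin_names)) {
    sel <- assign_idx == l
    X[sel, (l - 1) * p_block + seq_len(p_block)] <- B[sel, , drop = FALSE]
  }

  G <- nrow(counts)
  coefs <- matrix(0, G, p, dimnames = list(rownames(counts), NULL))
  vcovs <- vector("list", G)
  theta <- numeric(G)
  flagged <- character(0)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    fit <- tryCatch({
      pois <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::poisson(), offset = off))
      mu <- pois$fitted.values
      alpha <- max(sum((y - mu)^2 - mu) / sum(mu^2), 1e-8)
      th <- 1 / alpha
      suppressWarnings(
        stats::glm.fit(X, y, family = MASS::negative.binomial(theta = th),
                       offset = off, start = ifelse(is.na(pois$coefficients),
                                                    0, pois$coefficients)))
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      flagged <- c(flagged, rownames(counts)[g])
      vcovs[[g]] <- matrix(0, p, p)
      theta[g] <- NA_real_
      next
    }
    beta <- fit$coefficients
    ok <- !is.na(beta)
    coefs[g, ok] <- beta[ok]
    V <- matrix(0, p, p)
    XtWX <- crossprod(X[, ok, drop = FALSE] * sqrt(fit$weights))
    Vok <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(Vok)) {
      flagged <- c(flagged, rownames(counts)[g])
      coefs[g, ] <- 0
    } else {
      V[ok, ok] <- Vok
    }
    vcovs[[g]] <- V
    theta[g] <- 1 / max(sum((y - fit$fitted.values)^2 - fit$fitted.values) /
                          sum(fit$fitted.values^2), 1e-8)
  }
  structure(list(coef = coefs, vcov = vcovs, theta = theta, knots = knots,
                 lineage_names = lin_names, basis = basis,
                 p_block = p_block, flagged = unique(flagged)),
            class = "smoother_fit")
}

# cubic B-spline basis anchored on the knot grid (boundary knots = first and
# last knot, interior knots = the middle ones); evaluation clamps pseudotime
# to the grid range
knot_basis <- function(knots) {
  pos <- knots$positions
  list(boundary = pos[c(1, length(pos))],
       interior = if (length(pos) > 2) pos[-c(1, length(pos))] else numeric(0))
}

eval_knot_basis <- function(basis, t) {
  t <- pmin(pmax(t, basis$boundary[1]), basis$boundary[2])
  splines::bs(t, knots = basis$interior, degree = 3, intercept = TRUE,
              Boundary.knots = basis$boundary)
}

#' Evaluate fitted log-mean smoothers on a pseudotime grid
#'
#' @param fits a `smoother_fit`.
#' @param lineage lineage name.
#' @param t pseudotime values.
#' @param genes gene ids (default all).
#' @return genes x length(t) matrix of fitted natural-log means (offset at
#'   log library size 0).
#' @export
predict_smoother <- function(fits, lineage, t, genes = rownames(fits$coef)) {
  l <- match(lineage, fits$lineage_names)
  if (is.na(l)) stop("unknown lineage: ", lineage)
  B <- eval_knot_basis(fits$basis, t)
  cols <- (l - 1) * fits$p_block + seq_len(fits$p_block)
  fits$coef[genes, cols, drop = FALSE] %*% t(B)
}

#' Between-knot Wald test contrasting two lineages' smoothers
#'
#' The fitted log-mean difference (focal minus other) is evaluated at
#' `n_grid` equally spaced pseudotime points between two knots; the Wald
#' statistic is `d' pinv(Sigma_d) d` with the covariance propagated from the
#' joint coefficient covariance and degrees of freedom equal to the rank of
#' `Sigma_d`. Per-point log2 fold changes (positive = higher on the focal
#' lineage) are summarized by mean and median.
#'
#' @param fits a `smoother_fit`.
#' @param lineage_pair character of length 2: `c(other, focal)`.
#' @param knot_lo,knot_hi knot indices bounding the tested segment (default
#'   3 and 4 on a 5-knot grid).
#' @param n_grid grid points (default 2 * K).
#' @return a `de_result` data.frame: gene, comparison, wald, df, p, fdr
#'   (Benjamini-Hochberg within the comparison), log2fc_mean, log2fc_median.
#'   Genes flagged during fitting, or with a rank-0 contrast covariance, get
#'   NA statistics and are listed in attribute `"skipped"`.
#' @export
early_de_test <- function(fits, lineage_pair, knot_lo = 3, knot_hi = 4,
                          n_grid = 2 * fits$knots$K) {
  stopifnot(length(lineage_pair) == 2)
  other <- lineage_pair[1]; focal <- lineage_pair[2]
  K <- fits$knots$K
  if (knot_lo < 1 || knot_hi > K || knot_lo >= knot_hi)
    stop("need 1 <= knot_lo < knot_hi <= ", K)
  pos <- fits$knots$positions
  grid <- seq(pos[knot_lo], pos[knot_hi], length.out = n_grid)
  B <- eval_knot_basis(fits$basis, grid)
  p <- ncol(fits$coef)
  lf <- match(focal, fits$lineage_names)
  lo <- match(other, fits$lineage_names)
  if (is.na(lf) || is.na(lo)) stop("unknown lineage in pair")
  M <- matrix(0, nrow = n_grid, ncol = p)
  cols_f <- (lf - 1) * fits$p_block + seq_len(fits$p_block)
  cols_o <- (lo - 1) * fits$p_block + seq_len(fits$p_block)
  M[, cols_f] <- B
  M[, cols_o] <- -B

  genes <- rownames(fits$coef)
  G <- length(genes)
  wald <- df <- pval <- fc_mean <- fc_med <- rep(NA_real_, G)
  skipped <- character(0)
  for (g in seq_len(G)) {
    if (genes[g] %in% fits$flagged) { skipped <- c(skipped, genes[g]); next }
    # difference of block coefficients first: identical smoothers cancel
    # exactly, so W is exactly 0 rather than rounding noise
    d <- as.numeric(B %*% (fits$coef[g, cols_f] - fits$coef[g, cols_o]))
    Sd <- M %*% fits$vcov[[g]] %*% t(M)
    eg <- eigen(Sd, symmetric = TRUE)
    tol <- max(eg$values, 0) * 1e-8
    keep <- eg$values > tol
    r <- sum(keep)
    if (r == 0) { skipped <- c(skipped, genes[g]); next }
    u <- t(eg$vectors[, keep, drop = FALSE]) %*% d
    wald[g] <- sum(u^2 / eg$values[keep])
    df[g] <- r
    pval[g] <- stats::pchisq(wald[g], df = r, lower.tail = FALSE)
    fc <- d / log(2)
    fc_mean[g] <- mean(fc)
    fc_med[g] <- stats::median(fc)
  }
  out <- data.frame(gene = genes,
                    comparison = paste0(other, "_vs_", focal),
                    wald = wald, df = df, p = pval,
                    fdr = bh_adjust(pval),
                    log2fc_mean = fc_mean, log2fc_median = fc_med,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; NAs are
#' preserved.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")
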