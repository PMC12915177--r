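#' Stratified train/validation split of cells by type
#'
#' Randomly selects `train_frac` of the cells of every cell type (cluster)
#' for signature training, preserving the original type proportions; the
#' remainder forms the validation set. A ceiling rule guarantees every type
#' at least one training cell.
#'
#' @param experiment a [cell_experiment()] with a `cluster` cell column.
#' @param train_frac training fraction (default 0.05).
#' @param seed integer seed.
#' @return list with `train` and `validation` (both `cell_experiment`s);
#'   their cell ids partition the input.
#' @export
split_train_validation <- function(experiment, train_frac = 0.05, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(as.integer(seed))
  type <- experiment$cells$cluster
  train_idx <- unlist(lapply(sort(unique(type)), function(ty) {
    idx <- which(type == ty)
    sample(idx, max(1, ceiling(train_frac * length(idx))))
  }))
  train_idx <- sort(train_idx)
  list(train = experiment[, train_idx],
       validation = experiment[, setdiff(seq_len(ncol(experiment$counts)),
                                         train_idx)])
}

#' Build a CPM-scale cell-type signature matrix
#'
#' Cells are CPM-normalized, mean profiles are computed per type, and marker
#' genes are picked per type: candidates are genes whose highest-expressing
#' type is that type with mean CPM at or above `min_expression`; the `top_k`
#' candidates with the largest fold change of the top type over the
#' second-highest type are kept. The signature is the mean-profile matrix
#' restricted to the marker union.
#'
#' @param train a `cell_experiment` (the training split).
#' @param min_expression minimum mean CPM of a marker in its top type
#'   (default 0.25).
#' @param top_k_markers markers kept per type (default 50).
#' @return a `signature_matrix`: list with `profiles` (marker genes x types,
#'   CPM), `markers` (named list per type), `full_profiles` (all genes) and
#'   `condition_number` of the signature.
#' @export
build_signature <- function(train, min_expression = 0.25, top_k_markers = 50) {
  cpm <- cpm_normalize(train$counts)
  type <- train$cells$cluster
  types <- sort(unique(type))
  prof <- vapply(types, function(ty)
    Matrix::rowMeans(cpm[, type == ty, drop = FALSE]), numeric(nrow(cpm)))
  rownames(prof) <- train$genes$id
  ord <- t(apply(prof, 1, order, decreasing = TRUE))
  top_type <- types[ord[, 1]]
  top_val <- prof[cbind(seq_len(nrow(prof)), ord[, 1])]
  second_val <- prof[cbind(seq_len(nrow(prof)), ord[, 2])]
  fold <- top_val / pmax(second_val, 1e-8)
  markers <- lapply(types, function(ty) {
    cand <- which(top_type == ty & top_val >= min_expression)
    if (!length(cand))
      stop("cell type '", ty, "' has no candidate marker gene at ",
           "min_expression = ", min_expression)
    cand <- cand[order(fold[cand], decreasing = TRUE)]
    rownames(prof)[utils::head(cand, top_k_markers)]
  })
  names(markers) <- types
  sel <- sort(unique(unlist(markers)))
  sig <- prof[sel, , drop = FALSE]
  structure(list(profiles = sig, markers = markers, full_profiles = prof,
                 condition_number = kappa(sig, exact = TRUE)),
            class = "signature_matrix")
}

#' Simulate pseudobulk mixtures with known composition
#'
#' Validation cells' expression is CPM-normalized and averaged per type;
#' each mixture is a proportion-weighted sum of the type mean profiles, with
#' proportions drawn from a symmetric Dirichlet (flat simplex at
#' `alpha = 1`). Optional negative-binomial noise emulates bulk sampling
#' variability.
#'
#' @param validation a `cell_experiment` (the validation split).
#' @param M number of mixtures (default 100).
#' @param seed integer seed.
#' @param alpha Dirichlet concentration.
#' @param noise `"none"` for exact linear mixtures or `"nb"` for
#'   negative-binomial resampling around them.
#' @param nb_size NB size parameter for `"nb"` noise.
#' @return a `mixture_set`: list with `mixtures` (genes x M),
#'   `true_proportions` (M x types, rows summing to 1) and `type_profiles`.
#' @export
make_mixtures <- function(validation, M = 100, seed = 1L, alpha = 1,
                          noise = c("none", "nb"), nb_size = 20) {
  noise <- match.arg(noise)
  set.seed(as.integer(seed))
  cpm <- cpm_normalize(validation$counts)
  type <- validation$cells$cluster
  types <- sort(unique(type))
  prof <- vapply(types, function(ty)
    Matrix::rowMeans(cpm[, type == ty, drop = FALSE]), numeric(nrow(cpm)))
  rownames(prof) <- validation$genes$id
  props <- t(vapply(seq_len(M), function(i) {
    x <- stats::rgamma(length(types), shape = alpha)
    x / sum(x)
  }, numeric(length(types))))
  colnames(props) <- types
  mix <- prof %*% t(props)
  if (noise == "nb")
    mix <- matrix(stats::rnbinom(length(mix), mu = mix, size = nb_size),
                  nrow = nrow(mix), dimnames = dimnames(mix))
  colnames(mix) <- sprintf("mix%03d", seq_len(M))
  rownames(props) <- colnames(mix)
  structure(list(mixtures = mix, true_proportions = props,
                 type_profiles = prof),
            class = "mixture_set")
}

#' Estimate cell-type fractions by non-negative least squares
#'
#' Per bulk sample, solves `min || S x - b ||_2` subject to `x >= 0` over the
#' signature genes present in the bulk profile, then renormalizes `x` to sum
#' to 1. The solver is NNLS, a transparent open stand-in for proprietary
#' support-vector deconvolution; the benchmarking protocol around it is what
#' this module reproduces.
#'
#' @param signature a `signature_matrix` (or a plain genes x types matrix).
#' @param bulk genes x samples matrix (counts or CPM).
#' @return samples x types matrix of estimated proportions; attribute
#'   `"zero_solution"` names samples whose NNLS solution was all zero (left
#'   as zero rows, flagged).
#' @export
deconvolve_nnls <- function(signature, bulk) {
  S <- if (inherits(signature, "signature_matrix")) signature$profiles
       else as.matrix(signature)
  bulk <- as.matrix(bulk)
  common <- intersect(rownames(S), rownames(bulk))
  if (length(common) < 0.5 * nrow(S))
    stop("fewer than 50% of signature genes present in the bulk profile; ",
         "estimates would be unreliable")
  S <- S[common, , drop = FALSE]
  est <- matrix(0, ncol(bulk), ncol(S),
                dimnames = list(colnames(bulk), colnames(S)))
  zero <- character(0)
  for (j in seq_len(ncol(bulk))) {
    x <- pracma::lsqnonneg(S, bulk[common, j])$x
    if (sum(x) == 0) {
      zero <- c(zero, colnames(bulk)[j])
    } else {
      est[j, ] <- x / sum(x)
    }
  }
  attr(est, "zero_solution") <- zero
  est
}

#' Per-type Pearson validation of deconvolution estimates
#'
#' @param estimates samples x types matrix from [deconvolve_nnls()].
#' @param truth matching matrix of true proportions.
#' @return data.frame with per-type Pearson `r`, two-sided `p`, and a
#'   `reason` column (NA r when a type's estimates or truths are constant).
#' @export
validate_deconvolution <- function(estimates, truth) {
  types <- colnames(truth)
  stopifnot(all(types %in% colnames(estimates)),
            nrow(estimates) == nrow(truth))
  do.call(rbind, lapply(types, function(ty) {
    x <- estimates[, ty]; y <- truth[, ty]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(type = ty, r = NA_real_, p = NA_real_,
                        mean_share = mean(y),
                        reason = "zero variance", stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y)
    data.frame(type = ty, r = unname(ct$estimate), p = ct$p.value,
               mean_share = mean(y), reason = NA_character_,
               stringsAsFactors = FALSE)
  }))
}
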