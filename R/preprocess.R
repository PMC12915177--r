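#' Quality-control configuration
#'
#' Defaults follow the study design: cells with fewer than 300 or more than
#' 10,000 detected genes are excluded, as are blood cells with more than 10%
#' and biopsy cells with more than 25% mitochondrial transcripts. Boundary
#' values (exactly 300, exactly 10,000, mito fraction exactly at the cutoff)
#' are kept, since the exclusion rules are strict inequalities.
#'
#' @param min_genes,max_genes inclusive bounds on detected genes per cell
#'   (genes with count > 0).
#' @param mito_max_blood,mito_max_biopsy maximum tolerated mitochondrial
#'   fraction per tissue, in (0, 1].
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_genes = 300, max_genes = 10000,
                      mito_max_blood = 0.10, mito_max_biopsy = 0.25) {
  stopifnot(min_genes > 0, min_genes < max_genes,
            mito_max_blood > 0, mito_max_blood <= 1,
            mito_max_biopsy > 0, mito_max_biopsy <= 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 mito_max_blood = mito_max_blood,
                 mito_max_biopsy = mito_max_biopsy),
            class = "qc_config")
}

#' Filter cells on detected-gene count and mitochondrial fraction
#'
#' @param experiment a [cell_experiment()]; mito flags are filled via
#'   [flag_gene_classes()] if absent.
#' @param qc a [qc_config()].
#' @return the filtered experiment; attribute `"report"` holds the number of
#'   cells removed per rule (a cell removed by several rules counts once, in
#'   `removed_total`).
#' @export
qc_filter_cells <- function(experiment, qc = qc_config()) {
  experiment <- flag_gene_classes(experiment)
  counts <- experiment$counts
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[experiment$genes$is_mito, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 0)
  tissue <- experiment$cells$tissue
  if (is.null(tissue)) tissue <- rep("biopsy", ncol(counts))
  mito_cut <- ifelse(tissue == "blood", qc$mito_max_blood, qc$mito_max_biopsy)

  too_few <- detected < qc$min_genes
  too_many <- detected > qc$max_genes
  too_mito <- mito_frac > mito_cut
  keep <- !(too_few | too_many | too_mito)
  if (!any(keep)) stop("QC removed every cell; check thresholds and input")
  out <- experiment[, keep]
  attr(out, "report") <- list(
    removed_low_genes = sum(too_few),
    removed_high_genes = sum(too_many),
    removed_mito = sum(too_mito),
    removed_total = sum(!keep),
    kept = sum(keep))
  out
}

#' Filter genes prior to trajectory differential expression
#'
#' Keeps genes expressed (count > 0) in more than `min_cells` cells and drops
#' the gene classes in `drop_classes`.
#'
#' @param experiment a [cell_experiment()].
#' @param min_cells strict lower bound on the number of expressing cells.
#' @param drop_classes subset of `c("mito", "ribo", "noncoding")`.
#' @return the filtered experiment; attribute `"report"` counts removals per
#'   rule. If no gene survives, the (empty) experiment structure is returned
#'   with a warning and `report$empty = TRUE`.
#' @export
filter_genes_for_de <- function(experiment, min_cells = 10,
                                drop_classes = c("mito", "ribo", "noncoding")) {
  experiment <- flag_gene_classes(experiment)
  n_cells_expr <- Matrix::rowSums(experiment$counts > 0)
  rare <- n_cells_expr <= min_cells
  flagged <- rep(FALSE, nrow(experiment$counts))
  for (cl in drop_classes)
    flagged <- flagged | experiment$genes[[paste0("is_", cl)]]
  keep <- !(rare | flagged)
  report <- list(removed_rare = sum(rare), removed_flagged = sum(flagged),
                 removed_total = sum(!keep), kept = sum(keep),
                 empty = !any(keep))
  if (report$empty) warning("gene filter removed every gene")
  out <- experiment
  out$counts <- experiment$counts[keep, , drop = FALSE]
  out$genes <- experiment$genes[keep, , drop = FALSE]
  attr(out, "report") <- report
  out
}

#' Counts-per-million normalization
#'
#' Scales each column (cell or sample) to sum to the scale factor 1,000,000.
#' All-zero columns are left at zero and flagged with a warning.
#'
#' @param counts matrix or sparse matrix, genes x columns.
#' @param scale_factor target column sum.
#' @return matrix of the same class, CPM scale.
#' @export
cpm_normalize <- function(counts, scale_factor = 1e6) {
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero column(s) left unnormalized")
    totals[zero] <- 1
  }
  if (methods::is(counts, "sparseMatrix")) {
    counts %*% Matrix::Diagonal(x = scale_factor / totals)
  } else {
    sweep(counts, 2, totals / scale_factor, "/")
  }
}
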