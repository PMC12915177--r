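#' Container for a single-cell count experiment
#'
#' A light S3 container holding a sparse gene x cell count matrix together
#' with a gene annotation table and a cell metadata table. It is the common
#' currency of the QC, lineage, differential-expression, origin and
#' deconvolution stages.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes x cells.
#' @param genes data.frame with at least `id`; optional `symbol`, and logical
#'   flags `is_mito`, `is_ribo`, `is_noncoding`. Missing flags are filled by
#'   symbol-pattern fallback (prefixes `MT-`, `RPS`, `RPL`; configurable via
#'   [flag_gene_classes()]).
#' @param cells data.frame with at least `id`; typical columns: `sample`,
#'   `tissue` (`blood`/`biopsy`), `outcome` (`rejection`/`no_rejection`),
#'   `cluster`, `emb_1`, `emb_2`, `donor_sex`, `recipient_sex`.
#'
#' @return object of class `cell_experiment` with elements `counts`, `genes`,
#'   `cells`.
#' @export
cell_experiment <- function(counts, genes, cells) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (is.null(genes$id)) stop("gene table needs an 'id' column")
  if (is.null(cells$id)) stop("cell table needs an 'id' column")
  genes$id <- as.character(genes$id)
  cells$id <- as.character(cells$id)
  if (nrow(genes) != nrow(counts))
    stop("gene table has ", nrow(genes), " rows but counts has ",
         nrow(counts), " rows")
  if (nrow(cells) != ncol(counts))
    stop("cell table has ", nrow(cells), " rows but counts has ",
         ncol(counts), " columns")
  if (anyDuplicated(genes$id)) stop("duplicate gene ids")
  if (anyDuplicated(cells$id)) stop("duplicate cell ids")
  if (length(counts@x) && (min(counts@x) < 0 || any(counts@x != round(counts@x))))
    stop("counts must be non-negative integers")
  rownames(counts) <- genes$id
  colnames(counts) <- cells$id
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "cell_experiment")
}

#' @export
print.cell_experiment <- function(x, ...) {
  cat("cell_experiment: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  cat("  gene columns: ", paste(names(x$genes), collapse = ", "), "\n", sep = "")
  cat("  cell columns: ", paste(names(x$cells), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_experiment <- function(x) dim(x$counts)

#' Subset an experiment by gene and/or cell index
#'
#' @param x a `cell_experiment`.
#' @param i,j gene / cell indices (logical, integer or id character).
#' @param ... unused.
#' @export
`[.cell_experiment` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, x$genes$id)
  if (is.character(j)) j <- match(j, x$cells$id)
  cell_experiment(x$counts[i, j, drop = FALSE],
                  x$genes[i, , drop = FALSE],
                  x$cells[j, , drop = FALSE])
}

#' Fill mitochondrial / ribosomal / non-coding gene flags
#'
#' Flags are taken from existing logical columns when present; otherwise a
#' symbol-prefix fallback is applied (the upstream study does not publish its
#' gene lists, so the patterns are configurable).
#'
#' @param experiment a `cell_experiment`.
#' @param mito_pattern,ribo_pattern,noncoding_pattern regular expressions
#'   matched against gene symbols (or ids when no `symbol` column exists).
#' @return the experiment with logical `is_mito`, `is_ribo`, `is_noncoding`
#'   columns present in `genes`.
#' @export
flag_gene_classes <- function(experiment,
                              mito_pattern = "^MT-",
                              ribo_pattern = "^RP[SL]",
                              noncoding_pattern = "^(LINC|RNU|MIR)") {
  g <- experiment$genes
  sym <- if (!is.null(g$symbol)) g$symbol else g$id
  if (is.null(g$is_mito)) g$is_mito <- grepl(mito_pattern, sym)
  if (is.null(g$is_ribo)) g$is_ribo <- grepl(ribo_pattern, sym)
  if (is.null(g$is_noncoding)) g$is_noncoding <- grepl(noncoding_pattern, sym)
  experiment$genes <- g
  experiment
}

#' Read a cell experiment from Matrix Market + TSV sidecars
#'
#' Expects `matrix.mtx` (genes x cells, integer), `genes.tsv` and `cells.tsv`
#' (tab-separated, with header) in `dir`, as written by
#' [write_mtx_experiment()].
#'
#' @param dir directory containing the three files.
#' @return a `cell_experiment`.
#' @export
read_mtx_experiment <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  gf <- file.path(dir, "genes.tsv")
  cf <- file.path(dir, "cells.tsv")
  for (f in c(mtx, gf, cf)) if (!file.exists(f)) stop("missing file: ", f)
  counts <- Matrix::readMM(mtx)
  genes <- utils::read.delim(gf, stringsAsFactors = FALSE,
                             colClasses = NA, check.names = FALSE)
  cells <- utils::read.delim(cf, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(genes) != nrow(counts))
    stop("genes.tsv has ", nrow(genes), " rows but MTX declares ",
         nrow(counts), " genes")
  if (nrow(cells) != ncol(counts))
    stop("cells.tsv has ", nrow(cells), " rows but MTX declares ",
         ncol(counts), " cells")
  cell_experiment(counts, genes, cells)
}

#' Write a cell experiment as Matrix Market + TSV sidecars
#'
#' @param experiment a `cell_experiment`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written. Round-trips losslessly through
#'   [read_mtx_experiment()].
#' @export
write_mtx_experiment <- function(experiment, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  Matrix::writeMM(experiment$counts, paths[1])
  utils::write.table(experiment$genes, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(experiment$cells, paths[3], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
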