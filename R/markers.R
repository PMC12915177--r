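#' Configuration for rank-score marker selection
#'
#' @param q selection quantile in (0, 1); genes at or above the `q`-th
#'   empirical quantile of the rank score are selected (default 0.9, i.e. the
#'   90th percentile and up).
#' @param fc_summary which fold-change summary feeds the score: `"mean"`
#'   (default) or `"median"`.
#' @param tie_seed integer seed controlling random tie-breaking of ranks, so
#'   selections are reproducible (exact ties would otherwise make re-runs
#'   differ).
#' @return a `rank_config` list.
#' @export
rank_config <- function(q = 0.9, fc_summary = c("mean", "median"),
                        tie_seed = 42L) {
  stopifnot(q > 0, q < 1)
  structure(list(q = q, fc_summary = match.arg(fc_summary),
                 tie_seed = as.integer(tie_seed)),
            class = "rank_config")
}

#' Rank score combining Wald statistic and fold change
#'
#' Within one lineage-pair comparison, the Wald statistics and the chosen
#' log2 fold-change summaries are each ranked ascending (largest value gets
#' rank n, ties broken by a seeded random permutation) and combined as
#' `R = sqrt(rank(W)^2 + rank(FC)^2)`, so genes that are simultaneously
#' strongly significant and strongly focal-enriched score highest. `R` is
#' invariant to any strictly monotone transform of either statistic.
#'
#' @param de a `de_result` from [early_de_test()] (one comparison).
#' @param config a [rank_config()].
#' @return the `de_result` with a `rank_score` column; genes with NA
#'   statistics are excluded from ranking (NA score) and listed in attribute
#'   `"excluded"`.
#' @export
rank_score <- function(de, config = rank_config()) {
  stopifnot(length(unique(de$comparison)) <= 1)
  fc <- if (config$fc_summary == "mean") de$log2fc_mean else de$log2fc_median
  usable <- is.finite(de$wald) & is.finite(fc)
  r <- rep(NA_real_, nrow(de))
  if (any(usable)) {
    set.seed(config$tie_seed)
    rw <- rank(de$wald[usable], ties.method = "random")
    rf <- rank(fc[usable], ties.method = "random")
    r[usable] <- sqrt(rw^2 + rf^2)
  }
  de$rank_score <- r
  attr(de, "excluded") <- de$gene[!usable]
  de
}

#' Select genes at or above a score quantile
#'
#' The threshold is the empirical quantile with linear interpolation between
#' order statistics (type 7); selection uses `>=`, so "the q-th percentile
#' and up".
#'
#' @param scores named numeric vector (names = gene ids), e.g. the
#'   `rank_score` column of [rank_score()] output.
#' @param q probability in `[0, 1)`; 0 selects every gene.
#' @return list with `genes` (character) and `threshold`.
#' @export
top_quantile <- function(scores, q = 0.9) {
  stopifnot(q >= 0, q < 1)
  scores <- scores[is.finite(scores)]
  thr <- unname(stats::quantile(scores, probs = q, type = 7))
  list(genes = names(scores)[scores >= thr], threshold = thr)
}

#' Intersect per-comparison selections and tabulate Venn regions
#'
#' @param sets named list of character vectors (gene selections, one per
#'   comparison).
#' @return list with `core` (the intersection of all sets) and `venn_counts`,
#'   a data.frame with one row per non-empty membership pattern (columns:
#'   one logical per set, plus `count`).
#' @export
intersect_comparisons <- function(sets) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  core <- Reduce(intersect, sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1,
                                                  dimnames = list(NULL, names(sets)))
  pattern <- apply(membership, 1, function(r)
    paste(as.integer(r), collapse = ""))
  counts <- table(pattern)
  rows <- do.call(rbind, lapply(names(counts), function(p) {
    flags <- as.logical(as.integer(strsplit(p, "")[[1]]))
    c(as.list(flags), list(count = as.integer(counts[[p]])))
  }))
  venn <- as.data.frame(rows)
  names(venn) <- c(names(sets), "count")
  for (cl in names(sets)) venn[[cl]] <- unlist(venn[[cl]])
  venn$count <- unlist(venn$count)
  list(core = sort(core), venn_counts = venn)
}
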