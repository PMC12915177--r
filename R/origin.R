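#' Rank-based module score for a gene signature
#'
#' Per cell, all genes are ranked by descending expression (ties mid-ranked,
#' ranks capped at `rmax + 1`); the signature's Mann-Whitney U statistic is
#' `U = sum(ranks of signature genes) - n(n+1)/2` and the score is
#' `max(0, 1 - U / (n * rmax))`, so a signature occupying the top n ranks
#' scores 1 and an unexpressed (rank-capped) signature scores about 0. Being
#' rank-based, the score is invariant to library-size scaling.
#'
#' @param experiment a [cell_experiment()].
#' @param signature character vector of gene ids; genes absent from the
#'   matrix are dropped with a warning (an empty intersection is an error).
#' @param rmax rank cap (default 1500).
#' @return named numeric vector of scores in `[0, 1]`, one per cell; cells
#'   with zero total counts get NA (score undefined).
#' @export
module_score <- function(experiment, signature, rmax = 1500) {
  present <- intersect(signature, experiment$genes$id)
  if (!length(present))
    stop("none of the signature genes are present in the matrix")
  if (length(present) < length(signature))
    warning("signature gene(s) absent, scoring over the present subset: ",
            paste(setdiff(signature, present), collapse = ", "))
  counts <- as.matrix(experiment$counts)
  n <- length(present)
  sig_idx <- match(present, experiment$genes$id)
  totals <- colSums(counts)
  scores <- vapply(seq_len(ncol(counts)), function(j) {
    if (totals[j] == 0) return(NA_real_)
    r <- rank(-counts[, j], ties.method = "average")
    r <- pmin(r, rmax + 1)
    u <- sum(r[sig_idx]) - n * (n + 1) / 2
    min(1, max(0, 1 - u / (n * rmax)))
  }, numeric(1))
  stats::setNames(scores, experiment$cells$id)
}

#' Assign donor/recipient origin from X/Y signature scores
#'
#' A cell's sex is called female when the female-signature score exceeds the
#' male one by more than `margin` (and vice versa); cells within the margin
#' stay unassigned. Origin is `recipient` when the inferred sex matches the
#' recipient's, `donor` otherwise. Swapping donor and recipient sexes swaps
#' the origin labels exactly. Same-sex pairs are rejected: origin is not
#' identifiable from sex signatures.
#'
#' @param female_score,male_score numeric vectors (same cells, e.g. from
#'   [module_score()] with the X- and Y-linked signatures).
#' @param donor_sex,recipient_sex `"female"` or `"male"`; must differ.
#' @param margin minimum score difference to call a sex (default 0.2; the
#'   margin trades assignment rate against purity and is surfaced in the
#'   fraction table).
#' @param types optional cell-type vector for the per-type fraction table.
#' @return list with `labels` (data.frame: cell, female_score, male_score,
#'   sex, origin — `origin` NA for unassigned) and `fractions` (per-type
#'   donor/recipient/unassigned fractions, NULL without `types`).
#' @export
assign_origin <- function(female_score, male_score, donor_sex, recipient_sex,
                          margin = 0.2, types = NULL) {
  sexes <- c("female", "male")
  stopifnot(donor_sex %in% sexes, recipient_sex %in% sexes)
  if (donor_sex == recipient_sex)
    stop("donor and recipient have the same sex; ",
         "origin cannot be identified from X/Y signatures")
  stopifnot(length(female_score) == length(male_score))
  diff <- female_score - male_score
  sex <- ifelse(is.na(diff), NA_character_,
                ifelse(diff > margin, "female",
                       ifelse(-diff > margin, "male", NA_character_)))
  origin <- ifelse(is.na(sex), NA_character_,
                   ifelse(sex == recipient_sex, "recipient", "donor"))
  labels <- data.frame(cell = if (!is.null(names(female_score)))
                                names(female_score) else
                                seq_along(female_score),
                       female_score = female_score, male_score = male_score,
                       sex = sex, origin = origin,
                       row.names = NULL, stringsAsFactors = FALSE)
  fractions <- NULL
  if (!is.null(types)) {
    stopifnot(length(types) == length(origin))
    fractions <- do.call(rbind, lapply(sort(unique(types)), function(ty) {
      o <- origin[types == ty]
      data.frame(type = ty, n = length(o),
                 donor = mean(o == "donor", na.rm = TRUE),
                 recipient = mean(o == "recipient", na.rm = TRUE),
                 unassigned = mean(is.na(o)),
                 margin = margin, stringsAsFactors = FALSE)
    }))
  }
  list(labels = labels, fractions = fractions)
}
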