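#' Configuration for the branching-trajectory count simulator
#'
#' The generator emulates the data regime the downstream lineage / smoother /
#' marker-selection chain assumes: several lineages sharing a root segment in
#' a 2-D embedding, negative-binomial counts whose log-mean is a gene baseline
#' plus a smooth function of pseudotime plus a planted focal-lineage effect
#' localized between the knot-3 and knot-4 positions, and log-normal library
#' sizes entering as an offset.
#'
#' @param n_lineages number of lineages (>= 2); lineage 1 is the focal one.
#' @param cells_per_lineage cells drawn per lineage (>= 50, so pseudotime can
#'   be binned into clusters).
#' @param n_genes number of genes.
#' @param branch_time fraction of pseudotime, strictly in (0, 1), at which
#'   lineages diverge from the shared root segment.
#' @param n_planted_markers number of genes carrying the planted effect.
#' @param planted_log2fc planted effect size delta, in log2 units, reached at
#'   the knot-4 position on the focal lineage (linear ramp from 0 at knot 3,
#'   held at delta afterwards). The knot-3/knot-4 positions are the 50% and
#'   75% quantiles of post-branch pseudotime, matching where a 5-knot grid
#'   placed on the pooled lineage cells will test.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); must be > 0.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a `trajectory_sim_config` list.
#' @export
trajectory_sim_config <- function(n_lineages = 6, cells_per_lineage = 500,
                                  n_genes = 2000, branch_time = 0.25,
                                  n_planted_markers = 25, planted_log2fc = 2,
                                  nb_dispersion = 0.5,
                                  libsize_meanlog = log(2500),
                                  libsize_sdlog = 0.3, seed = 1L) {
  if (n_lineages < 2) stop("need at least 2 lineages")
  if (cells_per_lineage < 50)
    stop("cells_per_lineage must be >= 50 (too few cells to bin into 5 knots)")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (branch_time <= 0 || branch_time >= 1)
    stop("branch_time must be strictly inside (0, 1)")
  if (n_planted_markers > n_genes)
    stop("n_planted_markers cannot exceed n_genes")
  structure(list(n_lineages = n_lineages,
                 cells_per_lineage = cells_per_lineage,
                 n_genes = n_genes, branch_time = branch_time,
                 n_planted_markers = n_planted_markers,
                 planted_log2fc = planted_log2fc,
                 nb_dispersion = nb_dispersion,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog, seed = as.integer(seed)),
            class = "trajectory_sim_config")
}

# Linear ramp: 0 below lo, 1 above hi.
ramp01 <- function(t, lo, hi) pmin(1, pmax(0, (t - lo) / (hi - lo)))

# Recursive binary branching layout. Lineages share a root segment, then
# split in halves at evenly spaced divergence times; every split sends the
# two subgroups off at a wide angle from the parent direction, so the minimum
# spanning tree over cluster-bin centroids recovers the topology (the parent
# bin stays closer to each child's first bin than sibling bins are to each
# other). Returns one row per (lineage, segment): node id, time span, origin
# and direction of the straight segment, and its bin count.
build_branch_layout <- function(n_lineages, branch_time, speed = 10) {
  L <- n_lineages; tb <- branch_time
  D <- max(1, ceiling(log2(L)))
  split_times <- tb + (seq_len(D) - 1) * (1 - tb) / (D + 1)
  segs <- list()
  add_seg <- function(node, members, t0, t1, origin, angle, n_bins) {
    segs[[length(segs) + 1]] <<- list(node = node, members = members,
                                      t0 = t0, t1 = t1, origin = origin,
                                      angle = angle, n_bins = n_bins)
  }
  counter <- 0L
  recurse <- function(members, depth, origin, angle) {
    sizes <- c(ceiling(length(members) / 2), floor(length(members) / 2))
    groups <- split(members, rep(1:2, times = sizes))
    spread <- if (depth == 1) pi / 2 else 75 * pi / 180
    for (gi in 1:2) {
      g <- groups[[gi]]
      child_angle <- angle + c(1, -1)[gi] * spread
      t0 <- split_times[depth]
      if (length(g) == 1) {
        n_bins <- max(2, round((1 - t0) / 0.1875))
        add_seg(paste0("L", g), g, t0, 1, origin, child_angle, n_bins)
      } else {
        t1 <- split_times[depth + 1]
        counter <<- counter + 1L
        node <- sprintf("n%02d", counter)
        n_bins <- max(1, round((t1 - t0) / 0.125))
        add_seg(node, g, t0, t1, origin, child_angle, n_bins)
        end <- origin + speed * (t1 - t0) * c(cos(child_angle), sin(child_angle))
        recurse(g, depth + 1, end, child_angle)
      }
    }
  }
  add_seg("root", seq_len(L), 0, tb, c(0, 0), 0, 2L)
  recurse(seq_len(L), 1, c(speed * tb, 0), 0)
  segs
}

#' Simulate a branching single-cell trajectory dataset with ground truth
#'
#' @param config a [trajectory_sim_config()].
#' @return list with `experiment` (a [cell_experiment()]) and `truth`, a list
#'   holding per-cell true pseudotime and lineage, the planted marker ids, the
#'   planted-window positions (`ramp_lo`, `ramp_hi`, on the pseudotime
#'   fraction scale), the focal lineage name and the config.
#' @export
simulate_trajectory_dataset <- function(config) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  set.seed(config$seed)
  L <- config$n_lineages
  n_cells <- L * config$cells_per_lineage
  G <- config$n_genes
  tb <- config$branch_time

  lineage <- rep(paste0("L", seq_len(L)), each = config$cells_per_lineage)
  lin_idx <- rep(seq_len(L), each = config$cells_per_lineage)
  t_true <- stats::runif(n_cells)

  # embedding: straight segments along a binary branching tree, arc length
  # proportional to pseudotime, plus isotropic Gaussian noise; clusters are
  # equal-width pseudotime bins per tree segment (root and shared internal
  # segments give clusters shared between lineages)
  speed <- 10
  layout <- build_branch_layout(L, tb, speed)
  emb_x <- emb_y <- numeric(n_cells)
  cluster <- character(n_cells)
  for (seg in layout) {
    sel <- lin_idx %in% seg$members & t_true >= seg$t0 &
      (t_true < seg$t1 | (seg$t1 == 1 & t_true <= 1))
    if (!any(sel)) next
    dt <- t_true[sel] - seg$t0
    emb_x[sel] <- seg$origin[1] + speed * dt * cos(seg$angle)
    emb_y[sel] <- seg$origin[2] + speed * dt * sin(seg$angle)
    bin <- pmin(seg$n_bins, 1L + floor(dt / ((seg$t1 - seg$t0) / seg$n_bins)))
    cluster[sel] <- paste0(seg$node, "_b", bin)
  }
  emb_x <- emb_x + stats::rnorm(n_cells, sd = 0.4)
  emb_y <- emb_y + stats::rnorm(n_cells, sd = 0.4)

  # planted window = 50% and 75% quantiles of post-branch pseudotime, i.e.
  # where knots 3 and 4 of a 5-knot grid on the pooled lineage cells fall
  ramp_lo <- tb + 0.50 * (1 - tb)
  ramp_hi <- tb + 0.75 * (1 - tb)

  gene_ids <- sprintf("g%04d", seq_len(G))
  baseline <- stats::rnorm(G, mean = 0, sd = 1)
  a1 <- stats::rnorm(G, sd = 0.7)
  a2 <- stats::rnorm(G, sd = 0.7)
  planted <- sort(sample.int(G, config$n_planted_markers))

  libsize <- stats::rlnorm(n_cells, config$libsize_meanlog, config$libsize_sdlog)
  delta_ln <- config$planted_log2fc * log(2) *
    ramp01(t_true, ramp_lo, ramp_hi) * (lineage == "L1")

  # log mu = baseline + smooth curve + planted effect + log libsize - log C,
  # C a global constant making libsize the approximate expected total
  log_rel <- outer(baseline, rep(1, n_cells)) +
    outer(a1, t_true) + outer(a2, t_true^2)
  if (length(planted))
    log_rel[planted, ] <- log_rel[planted, , drop = FALSE] +
      matrix(delta_ln, nrow = length(planted), ncol = n_cells, byrow = TRUE)
  log_const <- log(sum(exp(baseline + a1 * 0.5 + a2 * 0.25)))
  mu <- exp(sweep(log_rel, 2, log(libsize) - log_const, "+"))

  counts <- matrix(stats::rnbinom(G * n_cells, mu = mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = G, ncol = n_cells)

  genes <- data.frame(id = gene_ids, symbol = gene_ids,
                      is_mito = FALSE, is_ribo = FALSE, is_noncoding = FALSE,
                      stringsAsFactors = FALSE)
  # outcome labels: focal-lineage cells past the planted window are enriched
  # in rejection, emulating the infiltration pattern composition tests use
  p_rej <- ifelse(lineage == "L1" & t_true > ramp_lo, 0.8, 0.5)
  outcome <- ifelse(stats::runif(n_cells) < p_rej, "rejection", "no_rejection")
  cells <- data.frame(id = sprintf("c%05d", seq_len(n_cells)),
                      sample = "sim1", tissue = "biopsy",
                      outcome = outcome, cluster = cluster,
                      emb_1 = emb_x, emb_2 = emb_y,
                      donor_sex = NA_character_, recipient_sex = NA_character_,
                      stringsAsFactors = FALSE)
  experiment <- cell_experiment(counts, genes, cells)
  truth <- list(pseudotime = t_true, lineage = lineage,
                planted_marker_ids = gene_ids[planted],
                ramp_lo = ramp_lo, ramp_hi = ramp_hi,
                focal_lineage = "L1", libsize = libsize, config = config)
  list(experiment = experiment, truth = truth)
}

#' Simulate a single-cell experiment with distinct annotated cell types
#'
#' Generates the kind of input the deconvolution benchmark assumes: a set of
#' discrete, annotated cell types (as an annotated atlas provides), each with
#' its own marker-gene block elevated over a shared log-normal baseline,
#' negative-binomial counts and log-normal library sizes. Unlike the
#' branching-trajectory generator, type profiles here are genuinely distinct,
#' which is what makes signature-based deconvolution identifiable.
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type.
#' @param n_genes number of genes.
#' @param markers_per_type marker genes per type (disjoint blocks).
#' @param marker_log2fc log2 elevation of a marker in its own type.
#' @param nb_dispersion negative-binomial dispersion.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param seed integer seed.
#' @return list with `experiment` (a [cell_experiment()], cluster = type)
#'   and `truth` (type per cell, marker gene ids per type).
#' @export
simulate_celltype_experiment <- function(n_types = 10, cells_per_type = 100,
                                         n_genes = 1500,
                                         markers_per_type = 30,
                                         marker_log2fc = 3,
                                         nb_dispersion = 0.5,
                                         libsize_meanlog = log(2500),
                                         libsize_sdlog = 0.3, seed = 1L) {
  if (n_types * markers_per_type > n_genes)
    stop("marker blocks exceed n_genes")
  set.seed(as.integer(seed))
  types <- sprintf("T%02d", seq_len(n_types))
  n_cells <- n_types * cells_per_type
  type <- rep(types, each = cells_per_type)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  baseline <- stats::rnorm(n_genes, 0, 1)
  markers <- split(gene_ids[seq_len(n_types * markers_per_type)],
                   rep(types, each = markers_per_type))
  log_rel <- matrix(baseline, n_genes, n_types,
                    dimnames = list(gene_ids, types))
  for (ty in types)
    log_rel[markers[[ty]], ty] <- log_rel[markers[[ty]], ty] +
      marker_log2fc * log(2)
  rel <- sweep(exp(log_rel), 2, colSums(exp(log_rel)), "/")
  libsize <- stats::rlnorm(n_cells, libsize_meanlog, libsize_sdlog)
  mu <- rel[, match(type, types)] * rep(libsize, each = n_genes)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / nb_dispersion),
                   nrow = n_genes)
  genes <- data.frame(id = gene_ids, symbol = gene_ids, is_mito = FALSE,
                      is_ribo = FALSE, is_noncoding = FALSE,
                      stringsAsFactors = FALSE)
  cells <- data.frame(id = sprintf("c%05d", seq_len(n_cells)),
                      sample = "atlas1", tissue = "biopsy",
                      outcome = "rejection", cluster = type,
                      emb_1 = 0, emb_2 = 0,
                      donor_sex = NA_character_,
                      recipient_sex = NA_character_,
                      stringsAsFactors = FALSE)
  list(experiment = cell_experiment(counts, genes, cells),
       truth = list(type = type, markers = markers))
}

#' Plant donor/recipient origin labels and X/Y signature expression
#'
#' Each cell is assigned donor or recipient origin by a Bernoulli draw with
#' its cell type's donor fraction; cells then receive added counts on the
#' X-linked signature (XIST, JPX, FTX) if their assigned individual is female,
#' or on the Y-linked signature (DDX3Y, KDM5D, USP9Y) if male. Same-sex
#' donor/recipient pairs are rejected: origin is unidentifiable from sex
#' signatures.
#'
#' @param experiment a [cell_experiment()] with a `cluster` cell column.
#' @param donor_fraction_by_type named numeric vector/list, donor fraction per
#'   cluster; types not named get `default_fraction`.
#' @param donor_sex,recipient_sex `"female"` or `"male"`; must differ.
#' @param default_fraction donor fraction for unnamed types.
#' @param sig_mean mean added count per signature gene on matching-sex cells.
#' @param seed integer seed.
#' @return list with `experiment` (signature genes appended if absent, counts
#'   boosted) and `truth` (per-cell `origin`, `sex`, the signature gene sets).
#' @export
simulate_origin_labels <- function(experiment, donor_fraction_by_type = list(),
                                   donor_sex = "male",
                                   recipient_sex = "female",
                                   default_fraction = 0.1,
                                   sig_mean = 10, seed = 1L) {
  sexes <- c("female", "male")
  stopifnot(donor_sex %in% sexes, recipient_sex %in% sexes)
  if (donor_sex == recipient_sex)
    stop("donor and recipient have the same sex; ",
         "origin cannot be identified from X/Y signatures")
  set.seed(as.integer(seed))
  x_sig <- c("XIST", "JPX", "FTX")
  y_sig <- c("DDX3Y", "KDM5D", "USP9Y")
  type <- experiment$cells$cluster
  frac <- vapply(type, function(ty) {
    f <- donor_fraction_by_type[[ty]]
    if (is.null(f)) default_fraction else f
  }, numeric(1))
  stopifnot(all(frac >= 0 & frac <= 1))
  is_donor <- stats::rbinom(length(type), 1, frac) == 1
  origin <- ifelse(is_donor, "donor", "recipient")
  cell_sex <- ifelse(is_donor, donor_sex, recipient_sex)

  counts <- as.matrix(experiment$counts)
  genes <- experiment$genes
  missing_sig <- setdiff(c(x_sig, y_sig), genes$id)
  if (length(missing_sig)) {
    add <- matrix(0, nrow = length(missing_sig), ncol = ncol(counts))
    counts <- rbind(counts, add)
    add_genes <- data.frame(id = missing_sig, symbol = missing_sig,
                            is_mito = FALSE, is_ribo = FALSE,
                            is_noncoding = missing_sig %in% c("XIST", "JPX", "FTX"),
                            stringsAsFactors = FALSE)
    for (cl in setdiff(names(genes), names(add_genes)))
      add_genes[[cl]] <- NA
    genes <- rbind(genes[names(genes)], add_genes[names(genes)])
  }
  boost <- function(sig, which_cells) {
    n <- sum(which_cells)
    if (n == 0) return()
    idx <- match(sig, genes$id)
    counts[idx, which_cells] <<- counts[idx, which_cells, drop = FALSE] +
      matrix(stats::rpois(length(sig) * n, sig_mean), nrow = length(sig))
  }
  boost(x_sig, cell_sex == "female")
  boost(y_sig, cell_sex == "male")

  cells <- experiment$cells
  cells$donor_sex <- donor_sex
  cells$recipient_sex <- recipient_sex
  out <- cell_experiment(counts, genes, cells)
  truth <- list(origin = origin, sex = cell_sex,
                female_signature = x_sig, male_signature = y_sig,
                donor_sex = donor_sex, recipient_sex = recipient_sex)
  list(experiment = out, truth = truth)
}

#' Simulate a bulk cohort with known cell fractions and survival outcomes
#'
#' Per-sample true cell-type proportions are drawn from a Dirichlet
#' distribution whose focal-type concentration is raised in "rejection"
#' samples; bulk counts are negative-binomial draws around the
#' proportion-weighted combination of the type profiles; event times are
#' exponential with hazard `h0 * exp(beta * 1[focal fraction > focal_cutoff])`
#' under independent exponential censoring truncated at an administrative
#' horizon. Ordinal Banff-style lesion scores (g, ptc, i, t) are generated as
#' noisy monotone functions of the focal fraction.
#'
#' @param profiles genes x cell-types matrix on CPM scale (e.g. a signature
#'   matrix); column names are the type names.
#' @param n_samples number of bulk samples.
#' @param focal_type column of `profiles` whose fraction drives the hazard.
#' @param beta true log hazard ratio of the high-fraction group; must be
#'   finite.
#' @param focal_cutoff fraction threshold defining the high-hazard group.
#' @param prop_alpha Dirichlet concentration for non-focal types.
#' @param focal_alpha Dirichlet concentration of the focal type in rejection
#'   samples (its share is thereby shifted upward).
#' @param rejection_fraction fraction of samples drawn from the rejection
#'   regime.
#' @param h0 baseline hazard per day.
#' @param censor_rate hazard of the independent exponential censoring process
#'   (0 disables random censoring).
#' @param admin_censor_days administrative censoring horizon (`Inf` disables).
#' @param depth expected bulk library size.
#' @param nb_size negative-binomial size of the bulk noise.
#' @param seed integer seed.
#' @return list with `bulk` (genes x samples count matrix), `survival` (a
#'   data.frame: sample, time_days, event, one fraction column per type, and
#'   lesion scores g, ptc, i, t) and `truth` (true proportions, group
#'   indicator, beta, focal_cutoff).
#' @export
simulate_bulk_cohort <- function(profiles, n_samples = 200,
                                 focal_type = colnames(profiles)[1],
                                 beta = log(5), focal_cutoff = 0.1,
                                 prop_alpha = 1, focal_alpha = 8,
                                 rejection_fraction = 0.5,
                                 h0 = 5e-4, censor_rate = 7e-4,
                                 admin_censor_days = 1825,
                                 depth = 1e6, nb_size = 20, seed = 1L) {
  if (!is.finite(beta)) stop("beta must be finite")
  stopifnot(focal_type %in% colnames(profiles))
  set.seed(as.integer(seed))
  types <- colnames(profiles)
  K <- length(types)
  rejection <- stats::runif(n_samples) < rejection_fraction

  rdirichlet1 <- function(alpha) {
    x <- stats::rgamma(length(alpha), shape = alpha)
    x / sum(x)
  }
  alpha_base <- rep(prop_alpha, K)
  alpha_rej <- alpha_base
  alpha_rej[types == focal_type] <- focal_alpha
  props <- t(vapply(seq_len(n_samples), function(i)
    rdirichlet1(if (rejection[i]) alpha_rej else alpha_base), numeric(K)))
  colnames(props) <- types
  stopifnot(all(abs(rowSums(props) - 1) < 1e-9))

  mu <- as.matrix(profiles) %*% t(props) * (depth / 1e6)
  bulk <- matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size),
                 nrow = nrow(mu),
                 dimnames = list(rownames(profiles),
                                 sprintf("s%04d", seq_len(n_samples))))

  z <- as.integer(props[, focal_type] > focal_cutoff)
  event_time <- stats::rexp(n_samples, rate = h0 * exp(beta * z))
  censor_time <- if (censor_rate > 0)
    stats::rexp(n_samples, rate = censor_rate) else rep(Inf, n_samples)
  censor_time <- pmin(censor_time, admin_censor_days)
  time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)

  lesion <- function() {
    latent <- as.numeric(scale(props[, focal_type])) + stats::rnorm(n_samples, sd = 0.6)
    as.integer(cut(latent, breaks = stats::quantile(latent, c(0, .4, .7, .9, 1)),
                   include.lowest = TRUE, labels = FALSE)) - 1L
  }
  surv <- data.frame(sample = colnames(bulk), time_days = time, event = event,
                     stringsAsFactors = FALSE)
  for (ty in types) surv[[ty]] <- props[, ty]
  surv$g <- lesion(); surv$ptc <- lesion(); surv$i <- lesion(); surv$t <- lesion()

  truth <- list(proportions = props, group = z, beta = beta,
                focal_type = focal_type, focal_cutoff = focal_cutoff,
                rejection = rejection)
  list(bulk = bulk, survival = surv, truth = truth)
}
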