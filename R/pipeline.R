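#' End-to-end pipeline configuration
#'
#' Collects every stage parameter in one place. Defaults equal the values
#' the analysis design fixes (5 knots, tested segment knots 3-4, 90th
#' percentile rank-score cut, 5% training split, 100 mixtures, horizons 365
#' and 1825 days); parameters the design leaves open are explicit named
#' options. The configuration round-trips losslessly through JSON.
#'
#' @param sim a [trajectory_sim_config()] for the bundled synthetic run.
#' @param qc a [qc_config()] for the cell-filtering stage.
#' @param K number of knots.
#' @param knot_lo,knot_hi tested segment.
#' @param q rank-score selection quantile.
#' @param fc_summary fold-change summary feeding the rank score.
#' @param tie_seed rank tie-break seed.
#' @param origin_margin module-score margin for sex calls.
#' @param train_frac signature training fraction.
#' @param M pseudobulk mixtures.
#' @param n_cohort bulk cohort size.
#' @param tau time-dependent ROC horizon (days).
#' @param censor_horizon Kaplan-Meier administrative censoring (days).
#' @param seed master seed for stage seeds.
#' @param stages named logical vector enabling stages; disabled stages
#'   re-use cached outputs in the run directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = trajectory_sim_config(),
                            qc = qc_config(),
                            K = 5, knot_lo = 3, knot_hi = 4,
                            q = 0.9, fc_summary = "mean", tie_seed = 42L,
                            origin_margin = 0.2, train_frac = 0.05, M = 100,
                            n_cohort = 200, tau = 365, censor_horizon = 1825,
                            seed = 1L,
                            stages = c(simulate = TRUE, qc = TRUE,
                                       lineage = TRUE, traj_de = TRUE,
                                       select = TRUE, origin = TRUE,
                                       deconv = TRUE, cohort = TRUE)) {
  structure(list(sim = sim, qc = qc, K = K, knot_lo = knot_lo, knot_hi = knot_hi,
                 q = q, fc_summary = fc_summary, tie_seed = as.integer(tie_seed),
                 origin_margin = origin_margin, train_frac = train_frac,
                 M = M, n_cohort = n_cohort, tau = tau,
                 censor_horizon = censor_horizon, seed = as.integer(seed),
                 stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> qc -> lineage -> trajectory DE -> marker selection ->
#' origin -> deconvolution benchmark -> cohort statistics, writing each
#' stage's outputs and a manifest (parameters, seeds, package version) into
#' `dir`. Re-running with the same configuration reproduces the outputs
#' bit-identically; a stage disabled in `config$stages` re-uses its cached
#' output files and errors if they are missing.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory (created if needed).
#' @return invisibly, a list of in-memory stage results; `dir` holds
#'   `manifest.json`, `pseudotime.tsv`, `de_results.tsv`, `core_genes.txt`,
#'   `venn_counts.tsv`, `origin_labels.tsv`, `validation_r.tsv`, `roc.tsv`,
#'   `cox.tsv` and `composition.tsv`.
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- list()
  on_stage <- function(name) isTRUE(config$stages[[name]])
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("stage '", stage, "' is disabled but its cached output ",
           basename(path), " is missing")
    path
  }

  # -- simulate ---------------------------------------------------------
  sim_dir <- file.path(dir, "sim")
  if (on_stage("simulate")) {
    sim <- simulate_trajectory_dataset(config$sim)
    org <- simulate_origin_labels(sim$experiment,
                                  donor_fraction_by_type = list(),
                                  donor_sex = "male",
                                  recipient_sex = "female",
                                  default_fraction = 0.1,
                                  seed = config$seed + 1L)
    sim$experiment <- org$experiment
    write_mtx_experiment(sim$experiment, sim_dir)
    jsonlite::write_json(list(planted_marker_ids = sim$truth$planted_marker_ids,
                              focal_lineage = sim$truth$focal_lineage,
                              pseudotime = sim$truth$pseudotime,
                              lineage = sim$truth$lineage,
                              origin = org$truth$origin),
                         file.path(sim_dir, "truth.json"), digits = NA)
  } else {
    need(file.path(sim_dir, "matrix.mtx"), "simulate")
    need(file.path(sim_dir, "truth.json"), "simulate")
    sim <- list(experiment = read_mtx_experiment(sim_dir))
    tr <- jsonlite::read_json(file.path(sim_dir, "truth.json"),
                              simplifyVector = TRUE)
    sim$truth <- tr
    org <- list(truth = list(origin = tr$origin))
  }
  res$sim <- sim

  # -- qc ---------------------------------------------------------------
  expt <- qc_filter_cells(sim$experiment, config$qc)
  de_expt <- filter_genes_for_de(expt)
  res$qc <- list(cells = attr(expt, "report"), genes = attr(de_expt, "report"))

  # -- lineage ----------------------------------------------------------
  graph <- build_cluster_graph(expt)
  lin <- infer_lineages(graph, root_cluster = "root_b1")
  lin <- fit_pseudotime(expt, lin)
  knots <- place_knots(lin, K = config$K)
  res$lineages <- lin; res$knots <- knots
  pt_tab <- data.frame(cell = expt$cells$id, lineage = lin$assignment,
                       pseudotime = lin$pseudotime[cbind(
                         seq_len(nrow(lin$pseudotime)),
                         match(lin$assignment, colnames(lin$pseudotime)))],
                       weight = lin$weights[cbind(
                         seq_len(nrow(lin$weights)),
                         match(lin$assignment, colnames(lin$weights)))])
  utils::write.table(pt_tab, file.path(dir, "pseudotime.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # focal lineage = the one whose terminal cluster carries the focal truth
  # label (synthetic runs); falls back to the first lineage
  focal <- grep(paste0("^lin_", sim$truth$focal_lineage, "_"),
                names(lin$paths), value = TRUE)[1]
  if (is.na(focal)) focal <- names(lin$paths)[1]
  others <- setdiff(names(lin$paths), focal)

  # -- trajectory DE ----------------------------------------------------
  fits <- fit_nb_smoothers(de_expt, lin, knots)
  de_list <- lapply(others, function(ol)
    early_de_test(fits, c(ol, focal), config$knot_lo, config$knot_hi))
  names(de_list) <- vapply(de_list, function(d) d$comparison[1], character(1))
  res$de <- de_list
  utils::write.table(do.call(rbind, de_list), file.path(dir, "de_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # -- marker selection -------------------------------------------------
  rc <- rank_config(q = config$q, fc_summary = config$fc_summary,
                    tie_seed = config$tie_seed)
  sets <- lapply(de_list, function(d) {
    scored <- rank_score(d, rc)
    top_quantile(stats::setNames(scored$rank_score, scored$gene),
                 config$q)$genes
  })
  sel <- intersect_comparisons(sets)
  res$markers <- sel
  writeLines(sel$core, file.path(dir, "core_genes.txt"))
  utils::write.table(sel$venn_counts, file.path(dir, "venn_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # -- origin -----------------------------------------------------------
  fscore <- module_score(expt, c("XIST", "JPX", "FTX"),
                         rmax = min(1500, nrow(expt$counts)))
  mscore <- module_score(expt, c("DDX3Y", "KDM5D", "USP9Y"),
                         rmax = min(1500, nrow(expt$counts)))
  orig <- assign_origin(fscore, mscore,
                        donor_sex = expt$cells$donor_sex[1],
                        recipient_sex = expt$cells$recipient_sex[1],
                        margin = config$origin_margin,
                        types = expt$cells$cluster)
  res$origin <- orig
  utils::write.table(orig$labels, file.path(dir, "origin_labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # -- deconvolution benchmark (distinct annotated cell types) ----------
  atlas <- simulate_celltype_experiment(seed = config$seed + 5L)
  split <- split_train_validation(atlas$experiment, config$train_frac,
                                  seed = config$seed + 2L)
  sig <- build_signature(split$train)
  mix <- make_mixtures(split$validation, M = config$M,
                       seed = config$seed + 3L, noise = "nb")
  est <- deconvolve_nnls(sig, mix$mixtures)
  val <- validate_deconvolution(est, mix$true_proportions)
  res$deconv <- list(signature = sig, mixtures = mix, estimates = est,
                     validation = val)
  utils::write.table(val, file.path(dir, "validation_r.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # -- cohort statistics ------------------------------------------------
  focal_type <- colnames(sig$profiles)[1]
  cohort <- simulate_bulk_cohort(sig$profiles, n_samples = config$n_cohort,
                                 focal_type = focal_type,
                                 seed = config$seed + 4L)
  frac <- deconvolve_nnls(sig, cohort$bulk)
  surv <- cohort$survival
  surv$est_focal <- frac[, focal_type]
  roc <- td_roc(surv, "est_focal", tau = config$tau)
  cut <- youden_cutoff(roc)
  grp <- ifelse(surv$est_focal > cut$cutoff, "high", "low")
  lr <- km_logrank(surv, grp, config$censor_horizon)
  surv$high <- as.integer(grp == "high")
  cox <- cox_fit(surv, "high", right_censor = config$tau)
  inf <- infiltration_score(expt$cells$cluster, expt$cells$outcome)
  lc <- lesion_correlation(surv, "est_focal")
  res$cohort <- list(roc = roc, youden = cut, logrank = lr, cox = cox,
                     lesion_cor = lc)
  utils::write.table(data.frame(cutoff = roc$cutoffs, sens = roc$sens,
                                spec = roc$spec, J = roc$J),
                     file.path(dir, "roc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cox, file.path(dir, "cox.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(inf, file.path(dir, "composition.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("myeloTraj")),
                   seed = config$seed,
                   sim = unclass(config$sim),
                   parameters = config[c("K", "knot_lo", "knot_hi", "q",
                                         "fc_summary", "tie_seed",
                                         "origin_margin", "train_frac", "M",
                                         "n_cohort", "tau", "censor_horizon")],
                   focal_lineage = focal,
                   core_genes = sel$core)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
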