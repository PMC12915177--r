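# Kaplan-Meier product-limit survival probability at a time point
km_at <- function(time, event, at) {
  if (!length(time)) return(NA_real_)
  ord <- order(time, -event)  # events precede censorings at tied times
  time <- time[ord]; event <- event[ord]
  s <- 1
  n_risk <- length(time)
  for (i in seq_along(time)) {
    if (time[i] > at) break
    if (event[i] == 1) s <- s * (1 - 1 / n_risk)
    n_risk <- n_risk - 1
  }
  s
}

#' Time-dependent ROC for right-censored survival data
#'
#' Cumulative/dynamic definition at horizon `tau`: sensitivity
#' `P(X > c | T <= tau)` and specificity `P(X <= c | T > tau)`, estimated
#' with the Kaplan-Meier estimator inside the marker strata (so censoring
#' before `tau` is handled): with `S_hi`, `S_lo` the KM survival at `tau`
#' among `X > c` and `X <= c` and `S` the overall KM survival,
#' `sens = (1 - S_hi) P(X > c) / (1 - S)` and
#' `spec = S_lo P(X <= c) / S`. Candidate cutoffs are the observed marker
#' values. With no censoring before `tau`, this reduces to the classical
#' empirical ROC of the binary outcome `1[T <= tau]`.
#'
#' @param table data.frame with `time_days` and `event` columns.
#' @param marker name of the marker column in `table`.
#' @param tau horizon in days (default 365).
#' @return a `roc_result`: list with `cutoffs` (ascending), `sens`, `spec`,
#'   `J = sens + spec - 1`, `auc` and `tau`.
#' @export
td_roc <- function(table, marker, tau = 365) {
  x <- table[[marker]]
  time <- table$time_days; event <- table$event
  stopifnot(!is.null(x), !is.null(time), !is.null(event))
  S_all <- km_at(time, event, tau)
  if (1 - S_all <= 0)
    stop("no events before tau = ", tau, "; sensitivity is undefined")
  cutoffs <- sort(unique(x))
  sens <- spec <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    c0 <- cutoffs[i]
    hi <- x > c0
    p_hi <- mean(hi)
    S_hi <- if (any(hi)) km_at(time[hi], event[hi], tau) else 1
    S_lo <- if (any(!hi)) km_at(time[!hi], event[!hi], tau) else 1
    sens[i] <- min(1, max(0, (1 - S_hi) * p_hi / (1 - S_all)))
    spec[i] <- min(1, max(0, S_lo * (1 - p_hi) / S_all))
  }
  fpr <- c(1, 1 - spec, 0); tpr <- c(1, sens, 0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                               utils::tail(tpr[ord], -1)) / 2)
  structure(list(cutoffs = cutoffs, sens = sens, spec = spec,
                 J = sens + spec - 1, auc = auc, tau = tau),
            class = "roc_result")
}

#' Youden-index-optimal cutoff
#'
#' Maximizes `J = sensitivity + specificity - 1`; exact ties go to the
#' smallest cutoff (which maximizes sensitivity at equal J).
#'
#' @param roc a `roc_result` from [td_roc()].
#' @return list with `cutoff` and `J`.
#' @export
youden_cutoff <- function(roc) {
  i <- which(roc$J >= max(roc$J) - 1e-12)[1]
  list(cutoff = roc$cutoffs[i], J = roc$J[i])
}

#' Kaplan-Meier curves and log-rank test with administrative censoring
#'
#' Events after `censor_horizon` are treated as censored at the horizon;
#' product-limit curves and the standard log-rank test are then computed.
#'
#' @param table data.frame with `time_days`, `event`.
#' @param groups group label per sample (2 or more groups).
#' @param censor_horizon administrative censoring time in days (default
#'   1825, i.e. 5 years).
#' @return list with `fit` (a [survival::survfit()] object), `chisq`, `df`
#'   and `p`.
#' @export
km_logrank <- function(table, groups, censor_horizon = 1825) {
  time <- pmin(table$time_days, censor_horizon)
  event <- ifelse(table$time_days > censor_horizon, 0L, table$event)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  df <- data.frame(time = time, event = event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(fit = fit, chisq = unname(lr$chisq), df = nlevels(groups) - 1,
       p = stats::pchisq(lr$chisq, nlevels(groups) - 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with administrative censoring
#'
#' Wraps the partial-likelihood fit (Efron tie handling by default) and
#' returns per-covariate hazard ratios with Wald 95% confidence intervals.
#' Complete separation (monotone likelihood) is reported via the `flagged`
#' attribute rather than an error.
#'
#' @param table data.frame with `time_days`, `event` and covariate columns.
#' @param covariates character vector of covariate column names (one for a
#'   univariate model, several for a multivariate one).
#' @param ties tie-handling method (default `"efron"`).
#' @param right_censor administrative censoring in days (default 365;
#'   `Inf` disables).
#' @return data.frame with `covariate`, `beta`, `se`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`; the fitted [survival::coxph()] object is in attribute
#'   `"fit"`, convergence/separation warnings in `"flagged"`.
#' @export
cox_fit <- function(table, covariates, ties = "efron", right_censor = 365) {
  time <- pmin(table$time_days, right_censor)
  event <- ifelse(table$time_days > right_censor, 0L, table$event)
  dat <- table[, covariates, drop = FALSE]
  constant <- vapply(dat, function(v) stats::var(as.numeric(v)) == 0,
                     logical(1))
  flags <- character(0)
  if (any(constant))
    flags <- c(flags, paste0("constant covariate (zero information): ",
                             paste(covariates[constant], collapse = ", ")))
  dat$time <- time; dat$event <- event
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  out <- data.frame(covariate = rownames(s$coefficients),
                    beta = s$coefficients[, "coef"],
                    se = s$coefficients[, "se(coef)"],
                    hr = exp(s$coefficients[, "coef"]),
                    ci_lo = exp(s$coefficients[, "coef"] -
                                1.96 * s$coefficients[, "se(coef)"]),
                    ci_hi = exp(s$coefficients[, "coef"] +
                                1.96 * s$coefficients[, "se(coef)"]),
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "flagged") <- flags
  out
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Scaled Schoenfeld residuals are regressed on event time (identity time
#' transform) and a score test per covariate is returned; small p-values
#' indicate a time-varying effect, i.e. a proportional-hazards violation.
#'
#' @param fit result of [cox_fit()] (or a `coxph` object).
#' @return data.frame with `covariate` and `p`.
#' @export
schoenfeld_check <- function(fit) {
  cox <- if (inherits(fit, "coxph")) fit else attr(fit, "fit")
  if (is.null(cox)) stop("no coxph fit found")
  if (sum(cox$nevent) == 0) stop("no events; Schoenfeld residuals undefined")
  z <- survival::cox.zph(cox, transform = "identity")
  tab <- z$table
  tab <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  data.frame(covariate = rownames(tab), p = tab[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Infiltration score: per-type proportion ratio between outcomes
#'
#' For each cell type, the ratio of its proportion among rejection cells to
#' its proportion among no-rejection cells (plus a pseudocount `eps`
#' protecting against empty types, which are flagged).
#'
#' @param types cell-type label per cell.
#' @param outcome outcome label per cell.
#' @param rejection_label,control_label the two outcome levels compared.
#' @param eps pseudocount on the proportion scale (default 1e-4).
#' @return data.frame with `type`, `prop_rejection`, `prop_control`,
#'   `score`, `flagged` (TRUE when the control proportion was zero).
#' @export
infiltration_score <- function(types, outcome, rejection_label = "rejection",
                               control_label = "no_rejection", eps = 1e-4) {
  rej <- types[outcome == rejection_label]
  ctl <- types[outcome == control_label]
  if (!length(rej) || !length(ctl))
    stop("both outcome groups must contain cells")
  all_types <- sort(unique(types))
  p_rej <- as.numeric(table(factor(rej, levels = all_types))) / length(rej)
  p_ctl <- as.numeric(table(factor(ctl, levels = all_types))) / length(ctl)
  data.frame(type = all_types, prop_rejection = p_rej, prop_control = p_ctl,
             score = p_rej / (p_ctl + eps), flagged = p_ctl == 0,
             stringsAsFactors = FALSE)
}

#' Correlation of a cell fraction with the acute Banff lesion sum
#'
#' The lesion burden per sample is `g + ptc + i + t` (glomerulitis,
#' peritubular capillaritis, interstitial inflammation, tubulitis); Pearson
#' correlation with the given fraction is returned with a Fisher-z 95%
#' confidence interval.
#'
#' @param table data.frame with columns `g`, `ptc`, `i`, `t` and the
#'   fraction column.
#' @param fraction_col name of the cell-fraction column.
#' @return list with `r`, `ci` (length 2), `p`, `n`.
#' @export
lesion_correlation <- function(table, fraction_col) {
  lesion_sum <- table$g + table$ptc + table$i + table$t
  y <- table[[fraction_col]]
  if (length(y) < 3) stop("need at least 3 samples")
  ct <- stats::cor.test(lesion_sum, y)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int), p = ct$p.value,
       n = length(y))
}

#' Two-group and k-group nonparametric comparisons
#'
#' Two groups: two-tailed Mann-Whitney U (exact when both groups have at
#' most 8 observations and there are no ties, normal approximation with tie
#' correction otherwise). Three or more groups: Kruskal-Wallis with tie
#' correction followed by Dunn pairwise z-tests, reported both unadjusted
#' and Benjamini-Hochberg adjusted.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return list; for two groups: `method`, `U`, `p`; otherwise `method`,
#'   `H`, `df`, `p` and `pairwise` (data.frame: group1, group2, z, p,
#'   p_adj).
#' @export
group_tests <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  if (k == 2) {
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    return(list(method = "mann-whitney", U = unname(wt$statistic),
                p = wt$p.value, exact = exact))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- sum(groups == a); nb <- sum(groups == b)
    z <- (mean(r[groups == a]) - mean(r[groups == b])) /
      sqrt(s2 * (1 / na + 1 / nb))
    data.frame(group1 = a, group2 = b, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
  list(method = "kruskal-dunn", H = unname(kw$statistic),
       df = unname(kw$parameter), p = kw$p.value, pairwise = pw)
}
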