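test_that("time-dependent ROC equals the classical ROC without censoring", {
  set.seed(51)
  n <- 150
  x <- runif(n)
  event_by_tau <- rbinom(n, 1, plogis(4 * x - 2))
  time <- ifelse(event_by_tau == 1, runif(n, 10, 300), runif(n, 400, 900))
  tab <- data.frame(time_days = time, event = 1L, marker = x)
  roc <- td_roc(tab, "marker", tau = 365)
  # classical empirical ROC of the binary outcome 1[T <= tau]
  D <- time <= 365
  for (i in seq_along(roc$cutoffs)) {
    c0 <- roc$cutoffs[i]
    expect_equal(roc$sens[i], mean(x[D] > c0), tolerance = 1e-12)
    expect_equal(roc$spec[i], mean(x[!D] <= c0), tolerance = 1e-12)
  }
})

test_that("a perfectly separating marker gives AUC 1 and J_max between the groups", {
  tab <- data.frame(time_days = c(100, 150, 200, 800, 900, 1000),
                    event = 1L, marker = c(5, 6, 7, 1, 2, 3))
  roc <- td_roc(tab, "marker", tau = 365)
  expect_equal(roc$auc, 1)
  yc <- youden_cutoff(roc)
  expect_equal(yc$J, 1)
  expect_gte(yc$cutoff, 3); expect_lt(yc$cutoff, 5)
})

test_that("an uninformative marker has AUC near one half", {
  set.seed(52)
  n <- 600
  tab <- data.frame(time_days = rexp(n, 1 / 400), event = 1L,
                    marker = runif(n))
  roc <- td_roc(tab, "marker", tau = 365)
  expect_lt(abs(roc$auc - 0.5), 0.08)
})

test_that("absence of events before the horizon is an error", {
  tab <- data.frame(time_days = rep(364, 10), event = 0L, marker = runif(10))
  expect_error(td_roc(tab, "marker", tau = 365), "no events")
})

test_that("Youden arithmetic and tie-breaking to the smallest cutoff", {
  roc <- structure(list(cutoffs = c(1, 2, 3), sens = c(0.8, 0.8, 0.2),
                        spec = c(0.9, 0.9, 0.9),
                        J = c(0.7, 0.7, 0.1)), class = "roc_result")
  yc <- youden_cutoff(roc)
  expect_equal(yc$J, 0.7)
  expect_equal(yc$cutoff, 1)
})

test_that("KM curves are monotone from 1 and the horizon censors later events", {
  set.seed(53)
  tab <- data.frame(time_days = c(rexp(40, 1 / 900), 2000, 2100),
                    event = c(rbinom(40, 1, 0.7), 1L, 1L))
  res <- km_logrank(tab, rep(c("a", "b"), 21), censor_horizon = 1825)
  s <- res$fit$surv
  expect_true(all(s <= 1 + 1e-12))
  for (str in split(seq_along(s), rep(seq_along(res$fit$strata),
                                      res$fit$strata)))
    expect_true(all(diff(s[str]) <= 1e-12))
  # the two events past 1825 days were treated as censored
  expect_equal(sum(res$fit$n.event), sum(tab$event[tab$time_days <= 1825]))
})

test_that("identical groups give a null log-rank statistic", {
  tab <- data.frame(time_days = rep(c(100, 200, 300, 400), 2),
                    event = rep(c(1L, 1L, 0L, 1L), 2))
  res <- km_logrank(tab, rep(c("a", "b"), each = 4))
  expect_lt(res$chisq, 1e-10)
  expect_gt(res$p, 0.999)
})

test_that("log-rank agrees with an exhaustive permutation reference at n = 12", {
  set.seed(54)
  time <- c(50, 80, 120, 160, 210, 260, 320, 400, 500, 650, 800, 1000)
  event <- rep(1L, 12)
  grp <- rep(c("a", "b"), 6)
  tab <- data.frame(time_days = time, event = event)
  obs <- km_logrank(tab, grp, censor_horizon = Inf)
  combos <- utils::combn(12, 6)
  stats <- apply(combos, 2, function(ix) {
    g <- rep("b", 12); g[ix] <- "a"
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  })
  p_perm <- mean(stats >= obs$chisq - 1e-9)
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("Cox fit solves the 4-subject fixture exactly (grid-search oracle)", {
  tab <- data.frame(time_days = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 1L),
                    x = c(1, 0, 1, 0))
  fit <- cox_fit(tab, "x", right_censor = Inf)
  expect_equal(fit$beta, log(sqrt(2)), tolerance = 1e-6)
  expect_equal(fit$hr, sqrt(2), tolerance = 1e-6)
  # independent oracle: maximize the partial likelihood on a grid
  grid <- seq(-1, 1.5, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = tab$time_days, event = tab$event, x = tab$x)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("Cox estimates match grid-search maxima on random small fixtures", {
  set.seed(55)
  for (i in 1:4) {
    n <- sample(6:10, 1)
    tab <- data.frame(time_days = sample(1000, n), event = rbinom(n, 1, 0.8),
                      x = rnorm(n))
    if (sum(tab$event) < 2) next
    fit <- tryCatch(cox_fit(tab, "x", right_censor = Inf),
                    warning = function(w) NULL)
    if (is.null(fit) || abs(fit$beta) > 3) next  # skip near-separation draws
    grid <- seq(fit$beta - 0.5, fit$beta + 0.5, by = 1e-4)
    ll <- vapply(grid, cox_partial_loglik, numeric(1),
                 time = tab$time_days, event = tab$event, x = tab$x)
    expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-4)
  }
})

test_that("constant covariates are flagged with zero information", {
  tab <- data.frame(time_days = c(10, 20, 30, 40), event = 1L, x = 1)
  fit <- suppressWarnings(cox_fit(tab, "x", right_censor = Inf))
  expect_true(any(grepl("constant covariate", attr(fit, "flagged"))))
})

test_that("Schoenfeld check keeps nominal size under proportional hazards and errors without events", {
  set.seed(56)
  rej <- replicate(60, {
    n <- 120
    x <- rnorm(n)
    tab <- data.frame(time_days = rexp(n, 1e-3 * exp(0.5 * x)),
                      event = 1L, x = x)
    fit <- cox_fit(tab, "x", right_censor = Inf)
    schoenfeld_check(fit)$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.07)
  none <- data.frame(time_days = c(5, 10), event = 0L, x = c(0, 1))
  fit0 <- suppressWarnings(cox_fit(none, "x", right_censor = Inf))
  expect_error(schoenfeld_check(fit0), "no events")
})

test_that("Schoenfeld check detects a strongly time-varying effect", {
  set.seed(57)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  # effect reverses over time: early hazard up, late hazard down for x = 1
  t1 <- rexp(n, 2e-3 * exp(1.5 * x))
  time <- ifelse(t1 < 300, t1, 300 + rexp(n, 2e-3 * exp(-1.5 * x)))
  tab <- data.frame(time_days = time, event = 1L, x = x)
  fit <- cox_fit(tab, "x", right_censor = Inf)
  expect_lt(schoenfeld_check(fit)$p, 0.05)
})

test_that("infiltration scores reproduce proportion ratios with a guarded zero", {
  types <- c(rep("mac", 64), rep("dc", 936),
             rep("mac", 13), rep("dc", 987))
  outcome <- c(rep("rejection", 1000), rep("no_rejection", 1000))
  inf <- infiltration_score(types, outcome, eps = 0)
  expect_equal(inf$score[inf$type == "mac"], 0.064 / 0.013, tolerance = 1e-9)
  # equal proportions give a ratio of 1
  eq <- infiltration_score(rep(c("a", "b"), 50),
                           rep(c("rejection", "no_rejection"), each = 50),
                           eps = 0)
  expect_equal(eq$score, c(1, 1))
  # a type absent from the control group is flagged, not infinite
  z <- infiltration_score(c("a", "a", "b", "a", "a", "a"),
                          c(rep("rejection", 3), rep("no_rejection", 3)),
                          eps = 1e-4)
  expect_true(z$flagged[z$type == "b"])
  expect_true(is.finite(z$score[z$type == "b"]))
})

test_that("lesion correlation is exact for linear dependence and guards small n", {
  tab <- data.frame(g = c(0, 1, 2, 3, 1), ptc = c(1, 0, 2, 2, 1),
                    i = c(0, 1, 1, 3, 0), t = c(0, 0, 2, 3, 1))
  tab$frac <- 0.01 * (tab$g + tab$ptc + tab$i + tab$t) + 0.002
  lc <- lesion_correlation(tab, "frac")
  expect_equal(lc$r, 1, tolerance = 1e-12)
  set.seed(58)
  tab2 <- data.frame(g = rpois(200, 1), ptc = rpois(200, 1),
                     i = rpois(200, 1), t = rpois(200, 1),
                     frac = runif(200))
  expect_lt(abs(lesion_correlation(tab2, "frac")$r), 0.2)
  expect_error(lesion_correlation(tab[1:2, ], "frac"), "at least 3")
})

test_that("Mann-Whitney results match exhaustive enumeration on the classic fixture", {
  res <- group_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2 * (1 / choose(6, 3))
  expect_true(res$exact)
  ident <- group_tests(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_gt(ident$p, 0.9)
})

test_that("Kruskal-Wallis with Dunn reports null and structured cases sensibly", {
  vals <- rep(c(1, 2, 3, 4), 3)
  res <- group_tests(vals, rep(c("a", "b", "c"), each = 4))
  expect_lt(res$H, 1e-10)
  expect_equal(nrow(res$pairwise), 3)
  set.seed(59)
  vals2 <- c(rnorm(30), rnorm(30, 2), rnorm(30, 4))
  res2 <- group_tests(vals2, rep(c("a", "b", "c"), each = 30))
  expect_lt(res2$p, 1e-6)
  expect_true(all(res2$pairwise$p_adj >= res2$pairwise$p - 1e-15))
  worst <- which.max(abs(res2$pairwise$z))
  expect_setequal(unlist(res2$pairwise[worst, c("group1", "group2")]),
                  c("a", "c"))
})
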