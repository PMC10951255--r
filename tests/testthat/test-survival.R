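surv_df <- function(time, event, ids = sprintf("P%02d", seq_along(time))) {
  data.frame(patient_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("presence_matrix binarises strictly and flags degenerate columns", {
  comp <- rbind(P1 = c(0.25, 0.50, 0.25),
                P2 = c(0.24, 0.38, 0.38),
                P3 = c(0.30, 0.40, 0.30))
  pm <- presence_matrix(comp, 0.24)
  expect_identical(unname(pm$matrix[, 1]), c(1L, 0L, 1L)) # 0.24 not > 0.24
  expect_identical(unname(pm$matrix[1, ]), c(1L, 1L, 1L)) # multi-assignment
  expect_identical(unname(pm$admissible), c(TRUE, FALSE, FALSE))
  # monotone: raising the threshold never adds assignments
  pm2 <- presence_matrix(comp, 0.30)
  expect_true(all(pm2$matrix <= pm$matrix))
})

test_that("cox_fit estimates hazard ratios with Breslow AIC bookkeeping", {
  expect_equal(aic_from_loglik(1, -10), 22)
  set.seed(21)
  hrs <- vapply(1:3, function(s) {
    set.seed(s)
    n <- 200
    x <- rbinom(n, 1, 0.4)
    time <- rexp(n, 0.05 * ifelse(x == 1, 3, 1))
    fit <- cox_fit(matrix(x, ncol = 1), surv_df(time, rep(1L, n)))
    expect_equal(fit$aic, 2 - 2 * fit$loglik)
    exp(fit$beta)
  }, numeric(1))
  expect_gt(exp(mean(log(hrs))), 2.4)
  expect_lt(exp(mean(log(hrs))), 3.75)
  # inadmissible constant covariate
  expect_error(cox_fit(matrix(1, 10, 1), surv_df(1:10, rep(1L, 10))),
               "constant|admissible")
  expect_error(cox_fit(matrix(rbinom(10, 1, .5), 10), surv_df(1:10, rep(0L, 10))),
               "events")
})

test_that("nested AIC difference follows the bookkeeping identity", {
  set.seed(5)
  n <- 80
  x <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
  sv <- surv_df(rexp(n, 0.1), rbinom(n, 1, 0.8))
  full <- cox_fit(x, sv)
  red <- cox_fit(x[, 1, drop = FALSE], sv)
  expect_equal(full$aic - red$aic,
               2 * (full$n_covariates - red$n_covariates) -
                 2 * (full$loglik - red$loglik), tolerance = 1e-10)
})

test_that("km_estimate reproduces hand-computed product limits", {
  expect_equal(nrow(km_estimate(c(5, 7), c(0, 0))), 0L) # no events: S == 1
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km2 <- km_estimate(c(1, 2, 3), c(0, 1, 1)) # 1+ censored
  expect_equal(km2$time, c(2, 3))
  expect_equal(km2$surv, c(1 / 2, 0))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  # agreement with survival::survfit on random data
  set.seed(9)
  tm <- round(rexp(40, 0.2), 1) + 0.1
  ev <- rbinom(40, 1, 0.7)
  km3 <- km_estimate(tm, ev)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(km3$surv, summary(sf, times = km3$time)$surv, tolerance = 1e-12)
})

test_that("logrank_test matches its contract and symmetries", {
  # two interleaved identical groups -> no separation
  lr <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # clear separation
  lr2 <- logrank_test(c(1, 2, 3, 10, 20, 30), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_lt(lr2$p, 0.05)
  # symmetry under label swap
  lr3 <- logrank_test(c(1, 2, 3, 10, 20, 30), rep(1, 6), rep(c("b", "a"), each = 3))
  expect_equal(lr2$statistic, lr3$statistic)
  expect_error(logrank_test(1:3, rep(1, 3), rep("a", 3)), "two levels")
})

test_that("logrank statistic equals the Cox score test on untied data", {
  set.seed(3)
  for (i in 1:10) {
    n <- 40
    time <- rexp(n) + seq_len(n) * 1e-9
    event <- rbinom(n, 1, 0.8)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (!any(event[g == "a"]) || !any(event[g == "b"])) next
    lr <- logrank_test(time, event, g)
    cf <- survival::coxph(survival::Surv(time, event) ~ I(g == "a"),
                          ties = "breslow")
    expect_equal(lr$statistic, cf$score, tolerance = 1e-6)
  }
})

test_that("aic_grid selects the planted subpopulation structure", {
  co <- generate_cohort(cohort_config(
    n_patients = 60, grid_shape = c(8, 8), n_channels = 60, k_true = 3,
    signature_effect = 4, noise_cv = 0.1, n_signature_channels_per_subpop = 6,
    hazard_ratio = 3, censoring_rate = 0.2, seed = 20))
  seg <- segment_cohort(lapply(co$datacubes, tic_normalize), k_range = 2:4,
                        seed = 20, n_init = 5)
  ag <- aic_grid(seg, co$survival, thresholds = seq(0.04, 0.40, 0.04))
  expect_s3_class(ag, "aic_grid")
  expect_equal(nrow(ag$grid), 3 * 10)
  # determinism
  ag2 <- aic_grid(seg, co$survival, thresholds = seq(0.04, 0.40, 0.04))
  expect_identical(ag$grid, ag2$grid)
  # scaled heat-map analogue spans [0, 1]
  expect_equal(min(ag$aic_scaled, na.rm = TRUE), 0)
  expect_equal(max(ag$aic_scaled, na.rm = TRUE), 1)
  # optimum beats the null model on planted data
  expect_lt(ag$optimum$aic, -2 * ag$loglik0)
  # tie-break fields present and optimum is the grid minimum
  expect_equal(ag$optimum$aic, min(ag$grid$aic, na.rm = TRUE))
})

test_that("pairwise comparisons reduce to the plain Cox fit for disjoint groups", {
  set.seed(6)
  n <- 24
  comp <- cbind(c(rep(0.6, 12), rep(0.1, 12)), c(rep(0.1, 12), rep(0.6, 12)))
  rownames(comp) <- sprintf("P%02d", 1:n)
  pm <- presence_matrix(comp, 0.25)
  sv <- surv_df(rexp(n, 0.1 * rep(c(3, 1), each = 12)), rep(1L, n))
  pw <- pairwise_subpop_survival(pm, sv)
  row <- pw[pw$cluster_i == 1 & pw$cluster_j == 2, ]
  expect_false(row$degenerate)
  # same records, same estimator, fitted directly
  dat <- data.frame(patient_id = sv$patient_id, time = sv$time, event = sv$event,
                    grp = rep(c(1, 0), each = 12))
  direct <- survival::coxph(survival::Surv(time, event) ~ grp +
                              survival::cluster(patient_id),
                            data = dat, ties = "breslow")
  expect_equal(row$hr, exp(unname(stats::coef(direct))), tolerance = 1e-10)
  expect_equal(row$p_wald, summary(direct)$coefficients["grp", 6],
               tolerance = 1e-10)
  # i == j is degenerate with p = 1
  self <- pw[pw$cluster_i == 1 & pw$cluster_j == 1, ]
  expect_true(self$degenerate)
  expect_equal(self$p_wald, 1)
})

test_that("planted prognosis difference yields significant Wald tests", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 100
    comp <- cbind(runif(n, 0, 0.6), runif(n, 0, 0.6))
    rownames(comp) <- sprintf("P%03d", 1:n)
    pm <- presence_matrix(comp, 0.25)
    risk <- pm$matrix[, 1] == 1
    sv <- surv_df(rexp(n, 0.05 * ifelse(risk, 3, 1)), rep(1L, n),
                  ids = rownames(comp))
    pw <- pairwise_subpop_survival(pm, sv)
    pw$p_wald[pw$cluster_i == 1 & pw$cluster_j == 2] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("response associations behave at the extremes and under the null", {
  pres <- c(1, 1, 1, 0, 0, 0)
  resp <- c(rep("sensitive", 3), rep("resistant", 3))
  ra <- response_association(pres, resp)
  expect_equal(ra$rho, 1)
  expect_error(response_association(rep(1, 6), resp), "degenerate")
  expect_error(response_association(pres, rep("sensitive", 6)), "response class")
  # unknowns are excluded
  ra2 <- response_association(c(pres, 1), c(resp, "unknown"))
  expect_equal(ra2$n, 6)

  # type-I error of the Spearman association near nominal
  set.seed(31)
  reps <- vapply(1:1000, function(i) {
    x <- rbinom(40, 1, 0.5)
    y <- sample(c("sensitive", "resistant"), 40, replace = TRUE)
    if (length(unique(x)) < 2 || min(table(y)) < 2) return(NA)
    response_association(x, y)$p < 0.05
  }, numeric(1))
  expect_lt(mean(reps, na.rm = TRUE), 0.08)
})

test_that("heterogeneity_response_fisher matches the enumeration oracle", {
  grp <- c(rep("high", 4), rep("low", 4))
  resp <- c(rep("sensitive", 3), "resistant", "sensitive", rep("resistant", 3))
  ft <- heterogeneity_response_fisher(grp, resp)
  expect_equal(ft$p, 34 / 70, tolerance = 1e-12)
  expect_equal(ft$p, fisher_enum_p(3, 1, 1, 3), tolerance = 1e-12)
})
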