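test_that("generation is deterministic and structurally valid", {
  co1 <- small_cohort(seed = 1)
  co2 <- small_cohort(seed = 1)
  expect_identical(co1$truth_labels, co2$truth_labels)
  expect_identical(co1$datacubes[[3]]$intensities, co2$datacubes[[3]]$intensities)
  expect_identical(co1$survival, co2$survival)

  expect_equal(unname(rowSums(co1$truth_composition)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(unlist(co1$truth_labels) %in% 1:3))
  expect_true(all(co1$survival$time > 0))
  # signature channel sets are disjoint and non-adjacent
  sig <- sort(as.vector(co1$signature_channels))
  expect_false(anyDuplicated(sig) > 0)
  expect_true(all(diff(sig) >= 2))
  # and the user's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); small_cohort(seed = 2); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(k_true = 1), "k_true")
  expect_error(cohort_config(k_true = 10, grid_shape = c(3, 3)), "pixels")
  expect_error(cohort_config(signature_effect = NaN), "non-finite")
  expect_error(cohort_config(censoring_rate = 1), "fraction")
  expect_error(cohort_config(n_channels = 20, k_true = 3,
                             n_signature_channels_per_subpop = 10), "disjoint")
  expect_error(cohort_config(risk_subpop = 5, k_true = 3), "risk_subpop")
})

test_that("null constructions plant no signal", {
  # signature_effect = 1: no channel separates planted subpopulations
  co <- small_cohort(seed = 3, signature_effect = 1, noise_cv = 0.2)
  pt <- pooled_truth(co)
  pv <- apply(pt$x[, 1:40], 2L, function(v)
    stats::t.test(v[pt$labels == 1], v[pt$labels != 1])$p.value)
  expect_gt(mean(pv < 0.05), 0.0 - 1e-9)
  expect_lt(mean(pv < 0.05), 0.15) # ~5% nominal over 40 channels
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)

  # hazard_ratio = 1, no censoring: log-rank p uniform over seeds
  pvals <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_config(
      n_patients = 30, grid_shape = c(4, 4), n_channels = 10, k_true = 2,
      n_signature_channels_per_subpop = 2, hazard_ratio = 1,
      censoring_rate = 0, seed = s))
    pres <- truth_presence(co, co$config$presence_fraction)[, 1]
    if (length(unique(pres)) < 2) return(NA_real_)
    logrank_test(co$survival$time, co$survival$event,
                 ifelse(pres == 1, "in", "out"))$p
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  expect_lt(mean(pvals < 0.05), 0.2)
})

test_that("truth_presence uses a strict boundary", {
  fake <- structure(list(truth_composition = rbind(c(0.30, 0.46, 0.24),
                                                   c(0.24, 0.52, 0.24))),
                    class = "msi_cohort")
  pm <- truth_presence(fake, 0.24)
  expect_identical(pm[1, 1], 1L) # 0.30 > 0.24
  expect_identical(pm[2, 1], 0L) # 0.24 is not > 0.24
  expect_identical(unname(pm[, 3]), c(0L, 0L))
  expect_true(all(truth_presence(fake, 0.999) == 0L))
  expect_error(truth_presence(fake, 1.2), "fraction")
})

test_that("spectral correlation is higher within than between subpopulations", {
  co <- small_cohort(seed = 4, signature_effect = 3, noise_cv = 0.2)
  pt <- pooled_truth(co)
  set.seed(1)
  idx <- sample(nrow(pt$x), 120)
  cc <- cor(t(pt$x[idx, ]))
  same <- outer(pt$labels[idx], pt$labels[idx], "==")
  ut <- upper.tri(cc)
  expect_gt(mean(cc[ut & same]), mean(cc[ut & !same]))
})

test_that("survival module recovers the planted hazard ratio", {
  hrs <- vapply(1:3, function(s) {
    co <- generate_cohort(cohort_config(
      n_patients = 200, grid_shape = c(6, 6), n_channels = 30, k_true = 3,
      n_signature_channels_per_subpop = 5, hazard_ratio = 3,
      censoring_rate = 0.2, seed = s))
    pres <- truth_presence(co, co$config$presence_fraction)
    exp(cox_fit(pres[, 1, drop = FALSE], co$survival)$beta)
  }, numeric(1))
  expect_gt(exp(mean(log(hrs))), 3 * 0.7)
  expect_lt(exp(mean(log(hrs))), 3 * 1.3)
})

test_that("response labels follow the survival cutoff convention", {
  expect_identical(derive_response(c(20, 10, 10, 13.9), c(0, 1, 0, 0)),
                   c("sensitive", "resistant", "unknown", "sensitive"))
  co <- small_cohort(seed = 5)
  with(co$survival, {
    expect_true(all(response[time > 13.8] == "sensitive"))
    expect_true(all(response[time <= 13.8 & event == 1] == "resistant"))
    expect_true(all(response[time <= 13.8 & event == 0] == "unknown"))
  })
})

test_that("cohort writer round-trips through the tabular format", {
  co <- small_cohort(seed = 6, n_patients = 3, grid = c(4, 4), n_channels = 20)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  cubes <- read_pixel_table(file.path(dir, "pixels.tsv"))
  expect_length(cubes, 3)
  orig <- co$datacubes[[1]]
  expect_equal(cubes[[1]]$intensities, orig$intensities,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(cubes[[1]]$coords, orig$coords)
  surv <- read_survival_table(file.path(dir, "metadata.tsv"))
  expect_equal(surv$time, co$survival$time, tolerance = 1e-6)
})
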