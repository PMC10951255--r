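test_that("adduct shifts match physical constants and worked examples", {
  rules <- adduct_rules()
  expect_setequal(rules$name, c("M-H", "M-H2O-H", "M+Na-2H", "M+K-2H", "M+Cl"))
  expect_true(all(rules$charge == -1L))
  shift <- setNames(rules$mass_shift, rules$name)
  # proton mass and the chloride shift, from independent constants
  expect_equal(shift[["M-H"]], -1.007276, tolerance = 1e-6)
  expect_equal(shift[["M+Cl"]], 34.969402, tolerance = 1e-6)
  # glucose examples
  expect_equal(adduct_mz(180.063388, "M-H"), 179.056112, tolerance = 1e-6)
  expect_equal(adduct_mz(180.063388, "M+Cl"), 215.032790, tolerance = 1e-6)
  expect_error(adduct_mz(180.06, "M+H"), "unknown")
  expect_error(adduct_mz(-1, "M-H"), "> 0")
})

test_that("formula_mass reproduces monoisotopic masses", {
  expect_equal(formula_mass("C6H12O6"), 180.063388, tolerance = 1e-6)
  expect_equal(formula_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_error(formula_mass("C6X2"), "unsupported")
  # the bundled demonstration table is internally consistent
  mt <- read_mass_table(system.file("extdata", "demo_metabolites.tsv",
                                    package = "msihetero"))
  expect_gte(nrow(mt), 50)
  expect_equal(formula_mass(mt$formula), mt$monoisotopic_mass, tolerance = 1e-7)
})

test_that("annotate_peaks finds hits within tolerance and ranks by ppm", {
  mt <- read_mass_table(system.file("extdata", "demo_metabolites.tsv",
                                    package = "msihetero"))
  hits <- annotate_peaks(179.056112, mt, tol_ppm = 4)
  expect_true(any(hits$metabolite_id == "C00031" & hits$adduct == "M-H"))
  expect_lt(abs(hits$ppm_error[1]), 0.1)
  # empty table, tolerance boundary
  expect_equal(nrow(annotate_peaks(179.056112, mt[0, ], 4)), 0L)
  off <- 179.056112 * (1 + 1e-6) # 1 ppm off
  expect_equal(nrow(annotate_peaks(off, mt[mt$id == "C00031", ], 0.1)), 0L)
  expect_gt(nrow(annotate_peaks(off, mt[mt$id == "C00031", ], 2)), 0L)
})

test_that("adduct/annotation round-trip recovers a synthetic mass table", {
  set.seed(14)
  masses <- sort(runif(40, 120, 900))
  masses <- masses[c(TRUE, diff(masses) > 0.5)] # non-colliding
  tab <- data.frame(id = sprintf("M%03d", seq_along(masses)),
                    monoisotopic_mass = masses)
  rules <- adduct_rules()
  for (rule in rules$name) {
    peaks <- vapply(masses, adduct_mz, numeric(1), rule = rule)
    hits <- annotate_peaks(peaks, tab, tol_ppm = 1)
    top <- hits[!duplicated(hits$observed_mz), ] # best hit per peak
    expect_identical(top$metabolite_id, tab$id)
    expect_true(all(top$adduct == rule))
    expect_true(all(abs(top$ppm_error) < 1e-6))
  }
})

test_that("enrich_pathways equals hypergeometric and Fisher one-sided", {
  universe <- sprintf("M%02d", 1:20)
  pw <- list(hit = universe[1:10], other = universe[16:20])
  res <- enrich_pathways(universe[1:10], universe, pw)
  row <- res[res$pathway == "hit", ]
  expect_equal(row$p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(row$p, 5.41254e-06, tolerance = 1e-4)
  # disjoint query -> p = 1
  expect_equal(res$p[res$pathway == "other"], 1)
  # agreement with fisher.test one-sided on the same 2x2
  ft <- fisher.test(matrix(c(10, 0, 0, 10), 2), alternative = "greater")
  expect_equal(row$p, ft$p.value, tolerance = 1e-12)
  expect_error(enrich_pathways("x", character(0), pw), "universe")
  expect_error(enrich_pathways("zz", universe, pw), "subset")
})

test_that("chance-level overlap is not called enriched", {
  set.seed(15)
  universe <- sprintf("M%03d", 1:100)
  pw <- list(p1 = sample(universe, 20))
  ps <- vapply(1:200, function(i)
    enrich_pathways(sample(universe, 15), universe, pw)$p, numeric(1))
  expect_gte(median(ps), 0.5)
})

test_that("GMT reader parses the bundled pathway sets", {
  gmt <- read_gmt(system.file("extdata", "demo_pathways.gmt",
                              package = "msihetero"))
  expect_gte(length(gmt), 5)
  expect_true("C00031" %in% gmt$demo_glycolysis)
  bad <- withr::local_tempfile(lines = "only_id\tdesc")
  expect_error(read_gmt(bad), "malformed")
})

test_that("correlation networks keep significant symmetric edges", {
  set.seed(16)
  n <- 1000
  latent <- rnorm(n)
  x <- cbind(a = latent + rnorm(n, sd = 0.5),
             b = latent + rnorm(n, sd = 0.5),
             c = rnorm(n), d = rnorm(n))
  x <- cbind(x, a2 = x[, "a"]) # duplicated channel
  net <- correlation_network(x, channel_ids = colnames(x))
  eid <- paste(net$edges$from, net$edges$to)
  expect_true("a a2" %in% eid)
  expect_equal(net$edges$rho[eid == "a a2"], 1)
  # planted co-regulated pair
  expect_true("a b" %in% eid)
  expect_gte(net$edges$weight[eid == "a b"], 0.5)
  expect_equal(net$edges$sign[eid == "a b"], "positive")
  expect_true(all(net$edges$weight == abs(net$edges$rho)))

  # independent channels: ~5% of pairs raw, far fewer after BH
  set.seed(17)
  z <- matrix(rnorm(1000 * 20), 1000, 20)
  rho <- cor(z, method = "spearman")
  r <- rho[upper.tri(rho)]
  tt <- r * sqrt(998 / (1 - r^2))
  raw <- mean(2 * pt(-abs(tt), 998) < 0.05)
  expect_lt(abs(raw - 0.05), 0.05)
  netz <- correlation_network(z)
  expect_lt(nrow(netz$edges) / choose(20, 2), 0.02)

  expect_error(correlation_network(x[1:5, ]), "pixels")
  expect_message(correlation_network(cbind(x[, 1:2], k = rep(1, n))),
                 "constant")
})

test_that("network export writes edge list and GraphML", {
  set.seed(18)
  x <- matrix(rnorm(600), 200, 3)
  x[, 2] <- x[, 1] + rnorm(200, sd = 0.2)
  net <- correlation_network(x, channel_ids = c("m1", "m2", "m3"),
                             direction = c(m1 = "increased"))
  expect_equal(net$nodes$direction[net$nodes$id == "m1"], "increased")
  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "edges.tsv"), file.path(dir, "net.graphml"))
  expect_true(file.exists(file.path(dir, "net.graphml")))
  back <- read.delim(file.path(dir, "edges.tsv"))
  expect_equal(nrow(back), nrow(net$edges))
})
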