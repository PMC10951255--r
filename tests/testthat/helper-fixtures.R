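# shared fixtures and independent oracles for the test suite

# a small, quick cohort with clear planted structure
small_cohort <- function(seed = 1, n_patients = 6, k_true = 3,
                         grid = c(8, 8), n_channels = 60,
                         signature_effect = 4, noise_cv = 0.1, ...) {
  generate_cohort(cohort_config(
    n_patients = n_patients, grid_shape = grid, n_channels = n_channels,
    k_true = k_true, signature_effect = signature_effect, noise_cv = noise_cv,
    n_signature_channels_per_subpop = 5, seed = seed, ...))
}

# pooled intensity matrix + planted labels, in segment_cohort's patient order
pooled_truth <- function(cohort, normalize = TRUE) {
  cubes <- cohort$datacubes
  if (normalize) cubes <- lapply(cubes, tic_normalize)
  ids <- vapply(cubes, function(cb) cb$patient_id, character(1))
  ord <- order(ids)
  list(x = do.call(rbind, lapply(cubes[ord], function(cb) cb$intensities)),
       labels = unlist(cohort$truth_labels[ids[ord]], use.names = FALSE))
}

# adjusted Rand index, straight from the contingency-table formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force two-sided Mann-Whitney p by full enumeration of group
# assignments (tie-free data)
mw_enum_p <- function(x, y) {
  nx <- length(x)
  v <- c(x, y)
  r <- rank(v)
  mu <- nx * length(y) / 2
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  cmb <- combn(length(v), nx)
  us <- apply(cmb, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# brute-force two-sided Fisher exact p: sum of hypergeometric tables (fixed
# margins) as or less probable than the observed one
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}
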