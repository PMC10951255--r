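#' Simpson's diversity index of a cluster composition
#'
#' `D = 1 - sum(p_i^2)`: the probability that two randomly chosen pixels of a
#' patient fall in different subpopulations. 0 means a single subpopulation;
#' the maximum for K clusters is `1 - 1/K`.
#'
#' @param comp a `cluster_composition`, or a numeric share vector summing to 1.
#' @param tol tolerance on `sum(shares) == 1` (default 1e-6).
#' @return Simpson's D (numeric scalar).
#' @export
simpson_index <- function(comp, tol = 1e-6) {
  shares <- if (inherits(comp, "cluster_composition")) comp$shares else as.numeric(comp)
  if (any(shares < 0)) stop("shares must be non-negative", call. = FALSE)
  if (abs(sum(shares) - 1) > tol)
    stop(sprintf("shares sum to %.8f, not 1", sum(shares)), call. = FALSE)
  1 - sum(shares^2)
}

#' Diversity scores for every patient of a segmentation
#'
#' @param seg one element of a `msi_segmentation_set` (or a composition matrix
#'   from [composition_matrix()]).
#' @return data.frame `patient_id`, `D`, `k_used`.
#' @export
diversity_scores <- function(seg) {
  m <- if (is.matrix(seg)) seg else composition_matrix(seg)
  data.frame(patient_id = rownames(m),
             D = apply(m, 1L, simpson_index),
             k_used = ncol(m),
             stringsAsFactors = FALSE)
}

#' Cutoff-optimised split into high/low heterogeneity
#'
#' Candidate cutoffs are midpoints between consecutive distinct sorted D
#' values for which each side holds at least `min_group_frac` of the patients
#' and at least one event. The returned cutoff minimises the two-group
#' log-rank p (ties broken toward the more balanced split, then the lower
#' cutoff). Robustness passes iff the two adjacent candidate cutoffs also give
#' p < 0.05. The optimised p is selection-biased: it is the minimum over
#' candidates and is reported non-adjusted, with an explicit caveat in the
#' output.
#'
#' @param scores data.frame `patient_id`, `D` (from [diversity_scores()]).
#' @param surv data.frame `patient_id`, `time`, `event`.
#' @param min_group_frac minimum fraction of patients per group (default 0.1).
#' @return object of class `diversity_split`: `cutoff`, `p_logrank`, `groups`
#'   (data.frame `patient_id`, `D`, `group` with high iff `D > cutoff`),
#'   `robustness` ("pass"/"fail"), `candidates` (cutoff, n_high, n_low, p) and
#'   `caveat`.
#' @export
optimize_diversity_cutoff <- function(scores, surv, min_group_frac = 0.1) {
  assert_fraction(min_group_frac, "min_group_frac", open = FALSE)
  df <- merge(scores[, c("patient_id", "D")], surv[, c("patient_id", "time", "event")],
              by = "patient_id")
  df <- df[order(df$patient_id), ]
  n <- nrow(df)
  if (n < 10L) stop("need at least 10 patients with survival data", call. = FALSE)
  dsort <- sort(unique(df$D))
  if (length(dsort) < 2L) stop("no admissible candidate cutoff", call. = FALSE)
  mids <- (dsort[-1L] + dsort[-length(dsort)]) / 2
  min_n <- max(1L, ceiling(min_group_frac * n))
  cand <- vapply(mids, function(cut) {
    hi <- df$D > cut
    c(n_high = sum(hi), n_low = sum(!hi),
      ev_high = sum(df$event[hi]), ev_low = sum(df$event[!hi]))
  }, numeric(4))
  ok <- cand["n_high", ] >= min_n & cand["n_low", ] >= min_n &
    cand["ev_high", ] >= 1 & cand["ev_low", ] >= 1
  if (!any(ok)) stop("no admissible candidate cutoff", call. = FALSE)
  mids <- mids[ok]
  cand <- cand[, ok, drop = FALSE]
  p <- vapply(mids, function(cut) {
    logrank_test(df$time, df$event, ifelse(df$D > cut, "high", "low"))$p
  }, numeric(1))
  balance <- abs(cand["n_high", ] - cand["n_low", ])
  best <- order(p, balance, mids)[1L]
  adj <- c(best - 1L, best + 1L)
  adj <- adj[adj >= 1L & adj <= length(mids)]
  robust <- length(adj) > 0 && all(p[adj] < 0.05)
  groups <- data.frame(patient_id = df$patient_id, D = df$D,
                       group = ifelse(df$D > mids[best], "high", "low"),
                       stringsAsFactors = FALSE)
  structure(list(
    cutoff = mids[best], p_logrank = p[best],
    groups = groups,
    robustness = if (robust) "pass" else "fail",
    candidates = data.frame(cutoff = mids, n_high = cand["n_high", ],
                            n_low = cand["n_low", ], p = p),
    caveat = paste("p_logrank is minimised over candidate cutoffs and is",
                   "selection-biased; it is reported non-adjusted")),
    class = "diversity_split")
}

#' @export
print.diversity_split <- function(x, ...) {
  cat(sprintf("<diversity_split> cutoff = %.4f, log-rank p = %.4g (%s), high %d / low %d\n",
              x$cutoff, x$p_logrank, x$robustness,
              sum(x$groups$group == "high"), sum(x$groups$group == "low")))
  cat("note:", x$caveat, "\n")
  invisible(x)
}

#' Write diversity scores and split summary
#'
#' @param split a `diversity_split`.
#' @param dir output directory; writes `diversity.tsv` and `split.json`.
#' @return `dir`, invisibly.
#' @export
write_diversity <- function(split, dir) {
  stopifnot(inherits(split, "diversity_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(split$groups, file.path(dir, "diversity.tsv"))
  jsonlite::write_json(
    list(cutoff = split$cutoff, p_logrank = split$p_logrank,
         robustness = split$robustness, caveat = split$caveat),
    file.path(dir, "split.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
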