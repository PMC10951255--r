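#' Mann-Whitney U test
#'
#' Exact two-sided p from the null distribution of U when
#' `min(n_x, n_y) <= 8` and the data are tie-free; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list `U` (for `x`), `p` (two-sided), `method` ("exact" or
#'   "normal").
#' @export
mannwhitney_u <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("both samples need >= 2 observations", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(nx, ny) <= 8L && !ties) {
    pl <- pwilcox(U, nx, ny)
    pu <- pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(pl, pu))
    return(list(U = U, p = p, method = "exact"))
  }
  n <- nx + ny
  tie_tab <- table(c(x, y))
  tiecor <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sig2 <- nx * ny / 12 * ((n + 1) - tiecor)
  mu <- nx * ny / 2
  d <- U - mu
  z <- if (sig2 > 0) (d - sign(d) * 0.5) / sqrt(sig2) else 0
  if (d == 0) z <- 0
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return adjusted p-values, monotone in rank and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  pv <- p[ok]
  n <- length(pv)
  if (n == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(n / (n:1) * pv[o]))[ro]
  out
}

# fast per-channel Mann-Whitney of group vs rest given precomputed ranks;
# mirrors the normal-approximation path of mannwhitney_u()
mw_from_ranks <- function(r, in_grp, tiecor) {
  nx <- sum(in_grp); n <- length(r); ny <- n - nx
  U <- sum(r[in_grp]) - nx * (nx + 1) / 2
  sig2 <- nx * ny / 12 * ((n + 1) - tiecor)
  mu <- nx * ny / 2
  d <- U - mu
  z <- if (sig2 > 0 && d != 0) (d - sign(d) * 0.5) / sqrt(sig2) else 0
  c(U = U, p = min(1, 2 * pnorm(-abs(z))))
}

#' Differential metabolite channels per subpopulation
#'
#' Pixel-wise Mann-Whitney U test of each subpopulation's pixels against all
#' other pixels pooled, per channel, with Benjamini-Hochberg adjustment within
#' each subpopulation's channel family and a fold-change filter. Direction is
#' `increased` iff adjusted p < `alpha` and FC >= `fc_threshold`, `decreased`
#' iff adjusted p < `alpha` and FC <= 1/`fc_threshold`, otherwise `ns`.
#' Channels with zero mean in either group are flagged untestable. Pixels are
#' the test unit (pseudoreplicated across patients, as in pixel-wise MSI
#' practice); `unit = "patient"` aggregates to per-patient medians first.
#'
#' @param intensities pixels x channels matrix (TIC-normalised).
#' @param labels subpopulation index per pixel (1..K).
#' @param subpops subpopulations to test (default all).
#' @param channels optional m/z values for reporting.
#' @param fc_threshold fold-change cutoff (default 1.5).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param unit `"pixel"` (default) or `"patient"` (requires `patient_id`).
#' @param patient_id per-pixel patient ids for `unit = "patient"`.
#' @param min_pixels minimum pixels per side (default 10).
#' @return data.frame of class `differential_table`: `subpop`, `channel`,
#'   `mz`, `U`, `p`, `p_adj`, `fc`, `direction`, `testable`.
#' @export
differential_metabolites <- function(intensities, labels, subpops = NULL,
                                     channels = NULL, fc_threshold = 1.5,
                                     alpha = 0.05, unit = c("pixel", "patient"),
                                     patient_id = NULL, min_pixels = 10L) {
  unit <- match.arg(unit)
  x <- as.matrix(intensities)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("labels must match rows", call. = FALSE)
  if (unit == "patient") {
    if (is.null(patient_id)) stop("unit = 'patient' needs patient_id", call. = FALSE)
    grp <- interaction(patient_id, labels, drop = TRUE)
    x <- apply(x, 2L, function(col) tapply(col, grp, median))
    labels <- as.integer(sub(".*\\.", "", levels(grp)))
    min_pixels <- 2L
  }
  K <- max(labels)
  subpops <- subpops %||% seq_len(K)
  if (is.null(channels)) channels <- seq_len(ncol(x))
  ranks <- apply(x, 2L, rank)
  n <- nrow(x)
  tiecors <- apply(x, 2L, function(col) {
    tt <- table(col); sum(tt^3 - tt) / (n * (n - 1))
  })
  rows <- list()
  for (s in subpops) {
    in_s <- labels == s
    if (sum(in_s) < min_pixels || sum(!in_s) < min_pixels)
      stop(sprintf("subpopulation %d has too few pixels for testing", s),
           call. = FALSE)
    m_in <- colMeans(x[in_s, , drop = FALSE])
    m_out <- colMeans(x[!in_s, , drop = FALSE])
    testable <- m_in > 0 & m_out > 0
    stats <- vapply(seq_len(ncol(x)), function(c)
      mw_from_ranks(ranks[, c], in_s, tiecors[c]), numeric(2))
    p <- ifelse(testable, stats["p", ], NA_real_)
    p_adj <- bh_adjust(p)
    fc <- ifelse(testable, m_in / m_out, NA_real_)
    direction <- ifelse(!testable | is.na(p_adj) | p_adj >= alpha, "ns",
                        ifelse(fc >= fc_threshold, "increased",
                               ifelse(fc <= 1 / fc_threshold, "decreased", "ns")))
    rows[[length(rows) + 1L]] <- data.frame(
      subpop = s, channel = seq_len(ncol(x)), mz = channels,
      U = stats["U", ], p = p, p_adj = p_adj, fc = fc,
      direction = direction, testable = testable)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Counts of altered channels per subpopulation
#'
#' The per-subpopulation tally of increased and decreased channels (the
#' heat-map style summary of discriminative metabolites).
#'
#' @param tab a `differential_table`.
#' @return data.frame `subpop`, `increased`, `decreased`.
#' @export
differential_counts <- function(tab) {
  sp <- sort(unique(tab$subpop))
  data.frame(
    subpop = sp,
    increased = vapply(sp, function(s)
      sum(tab$direction[tab$subpop == s] == "increased"), numeric(1)),
    decreased = vapply(sp, function(s)
      sum(tab$direction[tab$subpop == s] == "decreased"), numeric(1)))
}

#' Fligner-Killeen test of variance homogeneity
#'
#' Rank-based test on absolute deviations from group medians with
#' normal-scores weights, referred to chi-square with g - 1 df. Invariant to
#' per-group location shifts.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 groups, each >= 2 values).
#' @return list `statistic`, `p`, `df`.
#' @export
fligner_killeen <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tabulate(g) < 2L)) stop("each group needs >= 2 values", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p = 1, df = nlevels(g) - 1L))
  ft <- fligner.test(values, g)
  list(statistic = unname(ft$statistic), p = ft$p.value,
       df = unname(ft$parameter))
}
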