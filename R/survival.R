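#' Cluster presence matrix
#'
#' A patient is assigned to a cluster iff its pixel share strictly exceeds the
#' presence threshold; a patient may be assigned to several clusters.
#' Columns that are all 0 or all 1 carry no information for regression and are
#' flagged inadmissible.
#'
#' @param compositions patients x K share matrix ([composition_matrix()]).
#' @param threshold fraction in (0, 1).
#' @return object of class `presence_matrix`: binary `matrix`, `threshold`,
#'   and logical `admissible` per cluster column.
#' @export
presence_matrix <- function(compositions, threshold) {
  assert_fraction(threshold, "threshold")
  m <- (compositions > threshold) * 1L
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  colnames(m) <- colnames(m) %||% sprintf("cluster_%d", seq_len(ncol(m)))
  admissible <- apply(m, 2L, function(col) any(col == 1L) && any(col == 0L))
  structure(list(matrix = m, threshold = threshold, admissible = admissible),
            class = "presence_matrix")
}

# Breslow null partial log-likelihood: each event contributes -log(risk-set size)
null_logpl <- function(time, event) {
  ev <- which(event == 1)
  -sum(vapply(ev, function(i) log(sum(time >= time[i])), numeric(1)))
}

#' Cox proportional-hazards fit with AIC
#'
#' Maximum partial likelihood (Breslow tie handling, via the survival
#' package), with `AIC = 2p - 2 logPL` at the maximum. Constant covariate
#' columns are inadmissible; monotone-likelihood non-convergence is reported
#' via `converged = FALSE` so grid code can exclude the entry.
#'
#' @param covariates patients x p numeric matrix (typically binary presence
#'   indicators); column names are kept.
#' @param surv data.frame with `time` and `event` aligned to the rows.
#' @return object of class `cox_fit`: `beta`, `se`, `loglik` (at maximum),
#'   `loglik0` (null), `aic`, `score` (score/log-rank chi-square at beta = 0),
#'   `p_wald` per covariate, `n_covariates`, `converged`.
#' @export
cox_fit <- function(covariates, surv) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- sprintf("x%d", seq_len(ncol(x)))
  if (nrow(x) != nrow(surv)) stop("covariates and surv must align", call. = FALSE)
  if (sum(surv$event) < 1) stop("no events in the survival data", call. = FALSE)
  keep <- apply(x, 2L, function(col) length(unique(col)) > 1L)
  if (!any(keep)) stop("no admissible covariate (all columns constant)", call. = FALSE)
  if (!all(keep))
    stop(sprintf("constant covariate(s) inadmissible: %s",
                 paste(colnames(x)[!keep], collapse = ", ")), call. = FALSE)
  converged <- TRUE
  fit_once <- function(xm) {
    dat <- cbind(data.frame(time = surv$time, event = surv$event),
                 as.data.frame(xm))
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(sprintf("`%s`", colnames(xm)),
                                         collapse = " + ")))
    withCallingHandlers(
      survival::coxph(fml, data = dat, ties = "breslow"),
      warning = function(w) {
        if (grepl("infinite|did not converge|beta may be infinite",
                  conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
  }
  fit <- fit_once(x)
  if (anyNA(stats::coef(fit))) {
    # collinear (e.g. duplicated) presence columns are unidentifiable: drop
    x <- x[, !is.na(stats::coef(fit)), drop = FALSE]
    if (!ncol(x)) stop("singular information matrix", call. = FALSE)
    converged <- TRUE
    fit <- fit_once(x)
    if (anyNA(stats::coef(fit))) stop("singular information matrix", call. = FALSE)
  }
  if (any(abs(stats::coef(fit)) > 15)) converged <- FALSE
  p <- length(stats::coef(fit))
  ll <- fit$loglik[2L]
  structure(list(beta = stats::coef(fit),
                 se = sqrt(diag(fit$var)),
                 loglik = ll, loglik0 = fit$loglik[1L],
                 aic = 2 * p - 2 * ll,
                 score = fit$score,
                 p_wald = 2 * pnorm(-abs(stats::coef(fit) / sqrt(diag(fit$var)))),
                 n_covariates = p, converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> p = %d covariate(s), logPL = %.3f, AIC = %.3f%s\n",
              x$n_covariates, x$loglik, x$aic,
              if (x$converged) "" else " [non-convergent]"))
  print(data.frame(beta = x$beta, HR = exp(x$beta), se = x$se, p = x$p_wald))
  invisible(x)
}

#' AIC from a partial log-likelihood
#'
#' @param n_covariates number of model parameters p.
#' @param logpl maximised partial log-likelihood.
#' @return `2 * p - 2 * logpl`.
#' @export
aic_from_loglik <- function(n_covariates, logpl) 2 * n_covariates - 2 * logpl

#' Cluster-presence-threshold by K Cox-AIC grid
#'
#' For every segmentation K and every presence threshold, fits one
#' multivariable Cox model containing all admissible cluster-presence
#' indicators of that segmentation and records its AIC. A cell with no
#' admissible indicator is the null model (AIC = -2 logPL0); non-convergent
#' fits are excluded (NA). The optimum is the global AIC minimum, ties broken
#' toward smaller K then smaller threshold. The grid scaled to 0-1 is kept for
#' the heat-map analogue.
#'
#' @param segset an `msi_segmentation_set` ([segment_cohort()]).
#' @param surv data.frame `patient_id`, `time`, `event` covering all
#'   segmented patients.
#' @param thresholds candidate presence thresholds (default 4-40% step 2%).
#' @return object of class `aic_grid`: `grid` (data.frame `k`, `threshold`,
#'   `aic`, `n_admissible_covariates`, `converged`), `aic_matrix`,
#'   `aic_scaled` (0-1), `optimum` (list `k`, `threshold`, `aic`), `loglik0`.
#' @export
aic_grid <- function(segset, surv, thresholds = seq(0.04, 0.40, by = 0.02)) {
  stopifnot(inherits(segset, "msi_segmentation_set"))
  ks <- vapply(segset, `[[`, numeric(1), "k")
  rows <- list()
  ll0 <- NULL
  for (nm in names(segset)) {
    comp <- composition_matrix(segset[[nm]])
    srt <- surv[match(rownames(comp), surv$patient_id), ]
    if (anyNA(srt$time)) stop("survival data missing for segmented patients", call. = FALSE)
    if (is.null(ll0)) ll0 <- null_logpl(srt$time, srt$event)
    for (th in thresholds) {
      pm <- presence_matrix(comp, th)
      adm <- which(pm$admissible)
      if (!length(adm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          k = segset[[nm]]$k, threshold = th, aic = -2 * ll0,
          n_admissible_covariates = 0L, converged = TRUE)
        next
      }
      fit <- cox_fit(pm$matrix[, adm, drop = FALSE], srt)
      rows[[length(rows) + 1L]] <- data.frame(
        k = segset[[nm]]$k, threshold = th,
        aic = if (fit$converged) fit$aic else NA_real_,
        n_admissible_covariates = fit$n_covariates,
        converged = fit$converged)
    }
  }
  grid <- do.call(rbind, rows)
  if (all(is.na(grid$aic))) stop("all grid entries non-convergent", call. = FALSE)
  amat <- matrix(NA_real_, length(ks), length(thresholds),
                 dimnames = list(sprintf("K%d", ks), sprintf("%.2f", thresholds)))
  amat[cbind(match(grid$k, ks), match(grid$threshold, thresholds))] <- grid$aic
  rng <- range(grid$aic, na.rm = TRUE)
  scaled <- if (diff(rng) > 0) (amat - rng[1L]) / diff(rng) else amat * 0
  ok <- which(!is.na(grid$aic))
  best <- ok[order(grid$aic[ok], grid$k[ok], grid$threshold[ok])][1L]
  structure(list(grid = grid, aic_matrix = amat, aic_scaled = scaled,
                 optimum = list(k = grid$k[best], threshold = grid$threshold[best],
                                aic = grid$aic[best]),
                 loglik0 = ll0),
            class = "aic_grid")
}

#' @export
print.aic_grid <- function(x, ...) {
  cat(sprintf("<aic_grid> %d cells; optimum K* = %d at threshold %.0f%% (AIC %.3f; null %.3f)\n",
              nrow(x$grid), x$optimum$k, 100 * x$optimum$threshold,
              x$optimum$aic, -2 * x$loglik0))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time observed times > 0.
#' @param event event indicators (0 censored / 1 event).
#' @return data.frame `time` (distinct event times, ascending), `n_risk`,
#'   `n_event`, `surv` (right-continuous step values S(t)).
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("empty input", call. = FALSE)
  if (any(time <= 0)) stop("times must be > 0", call. = FALSE)
  et <- sort(unique(time[event == 1]))
  if (!length(et))
    return(data.frame(time = numeric(0), n_risk = numeric(0),
                      n_event = numeric(0), surv = numeric(0)))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  data.frame(time = et, n_risk = n_risk, n_event = n_event,
             surv = cumprod(1 - n_event / n_risk))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic from the hypergeometric observed-minus-expected
#' formulation; p from the chi-square distribution with 1 df.
#'
#' @param time,event survival data.
#' @param group vector with exactly two distinct values.
#' @return list `statistic` (chi-square), `p`, `observed`, `expected` (for
#'   the first group in sort order).
#' @export
logrank_test <- function(time, event, group) {
  g <- as.character(group)
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  if (!any(event[g == lv[1L]] == 1) && !any(event[g == lv[2L]] == 1))
    stop("need at least one event", call. = FALSE)
  is1 <- g == lv[1L]
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & is1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & is1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Pairwise subpopulation survival comparison (Andersen-Gill stacking)
#'
#' For each cluster pair (i, j), stacks one record per patient-membership (a
#' patient assigned to both clusters contributes two records), codes a group
#' indicator and fits a Cox model with robust sandwich variance clustered by
#' patient; the robust Wald p for the indicator is reported. `i == j` is
#' degenerate and returns p = 1.
#'
#' @param presence a `presence_matrix`.
#' @param surv data.frame `patient_id`, `time`, `event` with rows matching the
#'   presence matrix row names.
#' @param min_members minimum member patients per cluster (default 3, each
#'   compared cluster also needs >= 1 event).
#' @return data.frame `cluster_i`, `cluster_j`, `n_i`, `n_j`, `hr`, `p_wald`,
#'   `degenerate` for every comparable pair.
#' @export
pairwise_subpop_survival <- function(presence, surv, min_members = 3L) {
  stopifnot(inherits(presence, "presence_matrix"))
  m <- presence$matrix
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  srt <- surv[match(ids, surv$patient_id), ]
  if (anyNA(srt$time))
    stop("survival data missing for presence-matrix patients", call. = FALSE)
  K <- ncol(m)
  out <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (j < i) next
    ni <- sum(m[, i]); nj <- sum(m[, j])
    if (i == j) {
      out[[length(out) + 1L]] <- data.frame(cluster_i = i, cluster_j = j,
                                            n_i = ni, n_j = nj, hr = 1,
                                            p_wald = 1, degenerate = TRUE)
      next
    }
    mi <- m[, i] == 1L; mj <- m[, j] == 1L
    ev_i <- sum(srt$event[mi]); ev_j <- sum(srt$event[mj])
    if (ni < min_members || nj < min_members || ev_i < 1 || ev_j < 1) next
    dat <- rbind(
      data.frame(patient_id = ids[mi], time = srt$time[mi], event = srt$event[mi],
                 grp = 1),
      data.frame(patient_id = ids[mj], time = srt$time[mj], event = srt$event[mj],
                 grp = 0))
    fit <- tryCatch(suppressWarnings(
      survival::coxph(survival::Surv(time, event) ~ grp +
                        survival::cluster(patient_id),
                      data = dat, ties = "breslow")),
      error = function(e) NULL)
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    out[[length(out) + 1L]] <- data.frame(
      cluster_i = i, cluster_j = j, n_i = ni, n_j = nj,
      hr = exp(stats::coef(fit)[["grp"]]),
      p_wald = sm["grp", ncol(sm)],
      degenerate = FALSE)
  }
  do.call(rbind, out)
}

#' Association of cluster presence with treatment response
#'
#' Spearman rank correlation of the binary presence indicator with the binary
#' response (equals the phi coefficient for two binaries), two-sided p by the
#' asymptotic t approximation. Response-unknown patients are excluded.
#'
#' @param presence_col binary vector (one presence-matrix column).
#' @param response character vector ("sensitive"/"resistant"/"unknown").
#' @return list `rho`, `p`, `n`.
#' @export
response_association <- function(presence_col, response) {
  keep <- response %in% c("sensitive", "resistant")
  x <- presence_col[keep]
  y <- as.integer(response[keep] == "sensitive")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 patients per response class", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("degenerate presence column (all patients identical)", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fisher exact test of heterogeneity group versus response
#'
#' Exact hypergeometric two-sided p (sum of tables as or less probable than
#' the observed one) on the 2x2 table of high/low heterogeneity against
#' sensitive/resistant response.
#'
#' @param group character vector "high"/"low".
#' @param response character vector ("sensitive"/"resistant"/"unknown";
#'   unknown excluded).
#' @return list `table`, `odds_ratio` (conditional MLE), `p`.
#' @export
heterogeneity_response_fisher <- function(group, response) {
  keep <- response %in% c("sensitive", "resistant")
  tab <- table(factor(group[keep], levels = c("high", "low")),
               factor(response[keep], levels = c("sensitive", "resistant")))
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}
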