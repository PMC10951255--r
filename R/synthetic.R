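#' Configuration for the synthetic MSI cohort generator
#'
#' The defaults describe the stated world used throughout the test surface: a
#' trastuzumab-style cohort of ~45 patients, each a small pixel grid measured
#' over binned m/z channels in 50-1000 Da, composed of `k_true` spatially
#' coherent metabolic subpopulations with disjoint signature-channel sets,
#' survival tied to the presence of one risk subpopulation, and a binary
#' response label derived from survival at 13.8 months.
#'
#' @param n_patients number of patients.
#' @param grid_shape integer `(rows, cols)` of each patient's pixel grid.
#' @param n_channels number of m/z channels.
#' @param mz_range numeric `(low, high)` m/z bounds in Da.
#' @param k_true planted subpopulation count (>= 2).
#' @param signature_effect multiplicative intensity shift applied to a
#'   subpopulation's signature channels (> 0; 1 plants no signal).
#' @param n_signature_channels_per_subpop signature channels per subpopulation;
#'   sets are disjoint across subpopulations.
#' @param dirichlet_alpha symmetric Dirichlet concentration for per-patient
#'   subpopulation composition.
#' @param risk_subpop index of the subpopulation whose presence multiplies the
#'   hazard.
#' @param hazard_ratio hazard multiplier (> 0) when the risk subpopulation's
#'   true share exceeds `presence_fraction`.
#' @param presence_fraction share above which the generator considers the risk
#'   subpopulation present.
#' @param baseline_median_survival baseline median survival in months
#'   (exponential event model).
#' @param censoring_rate target fraction of independently right-censored
#'   patients, in `[0, 1)`.
#' @param response_cutoff months; sensitive iff observed survival exceeds it.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   pixel noise.
#' @param channel_log_mean,channel_log_sd mean and sd of per-channel log
#'   baseline intensities, drawn once per cohort.
#' @param seed integer RNG seed; the cohort is a deterministic function of the
#'   configuration.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 45L,
                          grid_shape = c(20L, 20L),
                          n_channels = 300L,
                          mz_range = c(50, 1000),
                          k_true = 4L,
                          signature_effect = 3,
                          n_signature_channels_per_subpop = 10L,
                          dirichlet_alpha = 0.5,
                          risk_subpop = 1L,
                          hazard_ratio = 3,
                          presence_fraction = 0.25,
                          baseline_median_survival = 14,
                          censoring_rate = 0.2,
                          response_cutoff = 13.8,
                          noise_cv = 0.2,
                          channel_log_mean = log(100),
                          channel_log_sd = 0.15,
                          seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients", 2L),
    grid_shape = c(assert_count(grid_shape[1], "grid_shape[1]"),
                   assert_count(grid_shape[2], "grid_shape[2]")),
    n_channels = assert_count(n_channels, "n_channels", 3L),
    mz_range = as.numeric(mz_range),
    k_true = assert_count(k_true, "k_true", 2L),
    signature_effect = signature_effect,
    n_signature_channels_per_subpop =
      assert_count(n_signature_channels_per_subpop, "n_signature_channels_per_subpop"),
    dirichlet_alpha = dirichlet_alpha,
    risk_subpop = assert_count(risk_subpop, "risk_subpop"),
    hazard_ratio = hazard_ratio,
    presence_fraction = assert_fraction(presence_fraction, "presence_fraction"),
    baseline_median_survival = baseline_median_survival,
    censoring_rate = assert_fraction(censoring_rate, "censoring_rate", open = FALSE),
    response_cutoff = response_cutoff,
    noise_cv = noise_cv,
    channel_log_mean = channel_log_mean,
    channel_log_sd = channel_log_sd,
    seed = as.integer(seed))
  num <- unlist(cfg[c("mz_range", "signature_effect", "dirichlet_alpha",
                      "hazard_ratio", "baseline_median_survival",
                      "response_cutoff", "noise_cv", "channel_log_mean",
                      "channel_log_sd")])
  if (!all(is.finite(num))) stop("non-finite value in cohort configuration", call. = FALSE)
  if (cfg$mz_range[2] <= cfg$mz_range[1]) stop("mz_range must be increasing", call. = FALSE)
  if (cfg$signature_effect <= 0) stop("signature_effect must be > 0", call. = FALSE)
  if (cfg$dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0", call. = FALSE)
  if (cfg$hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (cfg$baseline_median_survival <= 0)
    stop("baseline_median_survival must be > 0", call. = FALSE)
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (cfg$k_true > prod(cfg$grid_shape))
    stop("k_true exceeds the number of pixels per patient", call. = FALSE)
  if (cfg$risk_subpop > cfg$k_true)
    stop("risk_subpop must be <= k_true", call. = FALSE)
  if (cfg$k_true * cfg$n_signature_channels_per_subpop > cfg$n_channels)
    stop("disjoint signature sets need k_true * n_signature_channels_per_subpop <= n_channels",
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, k) # numerically degenerate draw; fall back to uniform
  g / sum(g)
}

#' Generate a synthetic MSI cohort with planted ground truth
#'
#' Each patient's grid is partitioned into spatially coherent Voronoi patches
#' (3 x `k_true` seeds per patient); every patch is assigned a subpopulation
#' sampled from the patient's Dirichlet composition. Pixel spectra are
#' per-channel log-normal baselines with the pixel subpopulation's signature
#' channels multiplied by `signature_effect`, then multiplicative log-normal
#' noise (unit mean, CV = `noise_cv`). Survival is exponential with median
#' `baseline_median_survival`, hazard multiplied by `hazard_ratio` when the
#' true share of `risk_subpop` exceeds `presence_fraction`; censoring is an
#' independent exponential calibrated to `censoring_rate`. Response is
#' sensitive iff observed time exceeds `response_cutoff`; resistant iff an
#' event occurred at or before the cutoff; patients censored before the cutoff
#' are response-unknown.
#'
#' @param config a [cohort_config()].
#' @return an object of class `msi_cohort` with elements `config`, `datacubes`
#'   (list of `msi_cube`), `truth_labels` (list of integer vectors per pixel),
#'   `truth_composition` (patients x k_true share matrix), `signature_channels`
#'   (k_true x n_signature matrix of channel indices), `survival` (data.frame
#'   `patient_id`, `time`, `event`, `response`) and `channels`.
#' @export
generate_cohort <- function(config) {
  cfg <- if (inherits(config, "cohort_config")) config else do.call(cohort_config, config)
  with_seed(cfg$seed, {
    nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
    npix <- nr * nc
    nch <- cfg$n_channels
    channels <- sort(runif(nch, cfg$mz_range[1], cfg$mz_range[2]))
    mu <- rnorm(nch, cfg$channel_log_mean, cfg$channel_log_sd)
    base <- exp(mu)
    # signature channels are distinct resolvable peaks: drawn without
    # replacement and never on adjacent bins, so each remains a local maximum
    # of the mean spectrum
    n_sig_total <- cfg$k_true * cfg$n_signature_channels_per_subpop
    sig_pool <- if (nch >= 2L * n_sig_total - 1L) {
      sort(sample.int(nch - n_sig_total + 1L, n_sig_total)) +
        seq_len(n_sig_total) - 1L
    } else sort(sample.int(nch, n_sig_total))
    sig <- matrix(sample(sig_pool), nrow = cfg$k_true)
    sdlog <- sqrt(log1p(cfg$noise_cv^2))
    ids <- sprintf("P%03d", seq_len(cfg$n_patients))
    px <- rep(seq_len(nc) - 1L, times = nr)
    py <- rep(seq_len(nr) - 1L, each = nc)
    n_patch <- 3L * cfg$k_true
    datacubes <- vector("list", cfg$n_patients)
    truth_labels <- vector("list", cfg$n_patients)
    comp <- matrix(0, cfg$n_patients, cfg$k_true)
    for (i in seq_len(cfg$n_patients)) {
      p <- rdirichlet1(cfg$k_true, cfg$dirichlet_alpha)
      sx <- runif(n_patch, 0, nc)
      sy <- runif(n_patch, 0, nr)
      patch_sub <- sample.int(cfg$k_true, n_patch, replace = TRUE, prob = p)
      d2 <- outer(px + 0.5, sx, `-`)^2 + outer(py + 0.5, sy, `-`)^2
      lab <- patch_sub[max.col(-d2, ties.method = "first")]
      inten <- matrix(base, npix, nch, byrow = TRUE)
      for (s in seq_len(cfg$k_true)) {
        rows <- lab == s
        if (any(rows))
          inten[rows, sig[s, ]] <- inten[rows, sig[s, ]] * cfg$signature_effect
      }
      if (cfg$noise_cv > 0)
        inten <- inten * matrix(exp(rnorm(npix * nch, -sdlog^2 / 2, sdlog)), npix, nch)
      datacubes[[i]] <- patient_datacube(ids[i], data.frame(x = px, y = py),
                                         channels, inten)
      truth_labels[[i]] <- lab
      comp[i, ] <- tabulate(lab, cfg$k_true) / npix
    }
    base_rate <- log(2) / cfg$baseline_median_survival
    at_risk <- comp[, cfg$risk_subpop] > cfg$presence_fraction
    rate <- base_rate * ifelse(at_risk, cfg$hazard_ratio, 1)
    t_event <- rexp(cfg$n_patients, rate)
    if (cfg$censoring_rate > 0) {
      c_rate <- base_rate * cfg$censoring_rate / (1 - cfg$censoring_rate)
      t_cens <- rexp(cfg$n_patients, c_rate)
    } else t_cens <- rep(Inf, cfg$n_patients)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    survival <- data.frame(patient_id = ids, time = time, event = event,
                           response = derive_response(time, event, cfg$response_cutoff),
                           stringsAsFactors = FALSE)
    names(truth_labels) <- ids
    rownames(comp) <- ids
    structure(list(config = cfg, datacubes = datacubes, truth_labels = truth_labels,
                   truth_composition = comp, signature_channels = sig,
                   survival = survival, channels = channels),
              class = "msi_cohort")
  })
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat(sprintf(paste0("<msi_cohort> %d patients, %dx%d pixels, %d channels, ",
                     "k_true = %d, events %d/%d\n"),
              x$config$n_patients, x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$n_channels, x$config$k_true,
              sum(x$survival$event), nrow(x$survival)))
  invisible(x)
}

#' Derive treatment-response labels from survival
#'
#' Sensitive iff observed survival exceeds `cutoff` months; resistant iff an
#' event occurred at or before the cutoff; patients censored at or before the
#' cutoff cannot be classified and are labelled unknown.
#'
#' @param time,event observed times (months) and event indicators (0/1).
#' @param cutoff months (default 13.8).
#' @return character vector in `c("sensitive", "resistant", "unknown")`.
#' @export
derive_response <- function(time, event, cutoff = 13.8) {
  ifelse(time > cutoff, "sensitive",
         ifelse(event == 1, "resistant", "unknown"))
}

#' Ground-truth presence matrix of planted subpopulations
#'
#' @param cohort an `msi_cohort`.
#' @param threshold fraction in (0, 1); entry is 1 iff the true share strictly
#'   exceeds it.
#' @return binary patients x k_true matrix.
#' @export
truth_presence <- function(cohort, threshold) {
  stopifnot(inherits(cohort, "msi_cohort"))
  assert_fraction(threshold, "threshold")
  (cohort$truth_composition > threshold) * 1L
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `pixels.tsv` (tabular pixel format), `metadata.tsv` (patient_id,
#' time_months, event, response), `truth_labels.tsv` and
#' `truth_composition.tsv` into `dir`.
#'
#' @param cohort an `msi_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "msi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pixel_table(cohort$datacubes, file.path(dir, "pixels.tsv"))
  meta <- data.frame(patient_id = cohort$survival$patient_id,
                     time_months = cohort$survival$time,
                     event = cohort$survival$event,
                     response = cohort$survival$response)
  write_tsv(meta, file.path(dir, "metadata.tsv"))
  lab <- do.call(rbind, lapply(seq_along(cohort$datacubes), function(i) {
    cb <- cohort$datacubes[[i]]
    data.frame(patient_id = cb$patient_id, x = cb$coords$x, y = cb$coords$y,
               truth_label = cohort$truth_labels[[i]])
  }))
  write_tsv(lab, file.path(dir, "truth_labels.tsv"))
  comp <- data.frame(patient_id = rownames(cohort$truth_composition),
                     cohort$truth_composition)
  names(comp)[-1] <- sprintf("share_%d", seq_len(ncol(cohort$truth_composition)))
  write_tsv(comp, file.path(dir, "truth_composition.tsv"))
  invisible(dir)
}

#' Read a survival metadata table
#'
#' @param path TSV with columns `patient_id`, `time_months` (or `time`),
#'   `event` and optionally `response`.
#' @return data.frame `patient_id`, `time`, `event`, `response`.
#' @export
read_survival_table <- function(path) {
  df <- read_tsv(path)
  tcol <- if ("time_months" %in% names(df)) "time_months" else "time"
  if (!all(c("patient_id", tcol, "event") %in% names(df)))
    stop("survival table needs patient_id, time_months (or time), event", call. = FALSE)
  out <- data.frame(patient_id = as.character(df$patient_id),
                    time = as.numeric(df[[tcol]]),
                    event = as.integer(df$event),
                    stringsAsFactors = FALSE)
  out$response <- if ("response" %in% names(df)) as.character(df$response) else "unknown"
  if (any(out$time <= 0)) stop("survival times must be > 0", call. = FALSE)
  out
}
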