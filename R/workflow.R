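#' Default pipeline configuration
#'
#' @return nested list of per-stage defaults; override via the `config`
#'   argument of [run_pipeline()] or a JSON file with the same structure.
#' @export
default_pipeline_config <- function() {
  list(
    cohort = list(n_patients = 45L, grid_shape = c(20L, 20L), n_channels = 300L,
                  k_true = 4L, signature_effect = 3, noise_cv = 0.2),
    preprocess = list(n_peaks = 150L, denoise_window = 3L),
    segment = list(k_min = 2L, k_max = 10L, n_init = 10L),
    survival_grid = list(t_min = 0.04, t_max = 0.40, t_step = 0.02),
    diversity = list(min_group_frac = 0.1),
    differential = list(fc_threshold = 1.5, alpha = 0.05),
    annotation = list(tol_ppm = 4, mass_table = NULL, gmt = NULL))
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

stage_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

file_hashes <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(paths))
}

#' Run the full heterogeneity pipeline
#'
#' Orchestrates simulate -> preprocess -> segment -> survival grid ->
#' diversity (at the AIC-optimal K) -> differential -> annotate/enrich/network
#' on a synthetic cohort, writing plain-text outputs and a manifest with
#' content hashes of every output file. Stages whose input hash matches the
#' previous manifest are skipped; a stage failure aborts with the stage named,
#' preserving partial outputs.
#'
#' @param config nested list (or path to a JSON file) overriding
#'   [default_pipeline_config()].
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- deep_merge(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  manifest <- list(config = cfg, seed = seed,
                   package_version = as.character(utils::packageVersion("msihetero")),
                   stages = list(),
                   warnings = c(
                     "cutoff-optimised log-rank p is selection-biased and non-adjusted",
                     "pixel-wise differential tests are pseudoreplicated across patients"))
  run_stage <- function(name, inputs_hash, outputs, fun) {
    cached <- !is.null(prev) &&
      identical(prev$stages[[name]]$input_hash, inputs_hash) &&
      all(file.exists(file.path(out_dir, outputs)))
    if (cached) {
      manifest$stages[[name]] <<- prev$stages[[name]]
      manifest$stages[[name]]$cached <<- TRUE
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      input_hash = inputs_hash, cached = FALSE,
      outputs = as.list(file_hashes(file.path(out_dir, outputs))))
    invisible(res)
  }

  # simulate
  h_sim <- stage_hash(stage = "simulate", cohort = cfg$cohort, seed = seed)
  sim_out <- c("cohort/pixels.tsv", "cohort/metadata.tsv",
               "cohort/truth_labels.tsv", "cohort/truth_composition.tsv")
  run_stage("simulate", h_sim, sim_out, function() {
    cc <- do.call(cohort_config, c(cfg$cohort, list(seed = seed)))
    write_cohort(generate_cohort(cc), file.path(out_dir, "cohort"))
  })
  cubes <- read_pixel_table(file.path(out_dir, "cohort", "pixels.tsv"))
  surv <- read_survival_table(file.path(out_dir, "cohort", "metadata.tsv"))

  # preprocess
  h_pre <- stage_hash(stage = "preprocess", cfg = cfg$preprocess, up = h_sim)
  run_stage("preprocess", h_pre, "cube.tsv", function() {
    pp <- preprocess_cohort(cubes, n_peaks = cfg$preprocess$n_peaks,
                            denoise_window = cfg$preprocess$denoise_window)
    write_pixel_table(pp$cubes, file.path(out_dir, "cube.tsv"))
  })
  cubes_pp <- read_pixel_table(file.path(out_dir, "cube.tsv"))

  # segment
  k_range <- seq(cfg$segment$k_min, cfg$segment$k_max)
  h_seg <- stage_hash(stage = "segment", cfg = cfg$segment, up = h_pre, seed = seed)
  seg_out <- c("seg/labels.tsv", sprintf("seg/centroids_K%d.tsv", k_range))
  segset <- NULL
  run_stage("segment", h_seg, seg_out, function() {
    segset <<- segment_cohort(cubes_pp, k_range = k_range,
                              seed = derive_seed(seed, 101L),
                              n_init = cfg$segment$n_init)
    write_segmentation(segset, file.path(out_dir, "seg"))
  })
  if (is.null(segset))
    segset <- segmentation_from_files(file.path(out_dir, "seg"), k_range, cubes_pp)

  # survival grid
  thresholds <- seq(cfg$survival_grid$t_min, cfg$survival_grid$t_max,
                    by = cfg$survival_grid$t_step)
  h_grid <- stage_hash(stage = "survival_grid", cfg = cfg$survival_grid, up = h_seg)
  run_stage("survival_grid", h_grid, c("aic_grid.tsv", "aic_optimum.json"),
            function() {
    ag <- aic_grid(segset, surv, thresholds)
    write_tsv(ag$grid, file.path(out_dir, "aic_grid.tsv"))
    jsonlite::write_json(ag$optimum, file.path(out_dir, "aic_optimum.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  opt <- jsonlite::read_json(file.path(out_dir, "aic_optimum.json"),
                             simplifyVector = TRUE)
  seg_star <- segset[[sprintf("K%d", opt$k)]]

  # diversity at the AIC-optimal K
  h_div <- stage_hash(stage = "diversity", cfg = cfg$diversity, up = h_grid)
  run_stage("diversity", h_div, c("diversity/diversity.tsv", "diversity/split.json"),
            function() {
    ds <- diversity_scores(seg_star)
    split <- optimize_diversity_cutoff(ds, surv,
                                       min_group_frac = cfg$diversity$min_group_frac)
    write_diversity(split, file.path(out_dir, "diversity"))
  })

  # differential at the AIC-optimal K
  h_diff <- stage_hash(stage = "differential", cfg = cfg$differential, up = h_grid)
  run_stage("differential", h_diff, c("differential.tsv", "differential_counts.tsv"),
            function() {
    pooled <- do.call(rbind, lapply(cubes_pp, function(cb) cb$intensities))
    tab <- differential_metabolites(pooled, seg_star$assignments$label,
                                    channels = cubes_pp[[1L]]$channels,
                                    fc_threshold = cfg$differential$fc_threshold,
                                    alpha = cfg$differential$alpha)
    write_tsv(tab, file.path(out_dir, "differential.tsv"))
    write_tsv(differential_counts(tab), file.path(out_dir, "differential_counts.tsv"))
  })

  # annotation / enrichment / networks (optional: needs a mass table)
  if (!is.null(cfg$annotation$mass_table)) {
    h_ann <- stage_hash(stage = "annotation", cfg = cfg$annotation, up = h_diff)
    run_stage("annotation", h_ann, "annotation.tsv", function() {
      mt <- read_mass_table(cfg$annotation$mass_table)
      hits <- annotate_peaks(cubes_pp[[1L]]$channels, mt,
                             tol_ppm = cfg$annotation$tol_ppm)
      write_tsv(hits, file.path(out_dir, "annotation.tsv"))
      if (!is.null(cfg$annotation$gmt) && nrow(hits)) {
        gmt <- read_gmt(cfg$annotation$gmt)
        universe <- unique(hits$metabolite_id)
        tab <- read_tsv(file.path(out_dir, "differential.tsv"))
        sig_mz <- unique(tab$mz[tab$direction != "ns"])
        query <- unique(hits$metabolite_id[hits$observed_mz %in% sig_mz])
        if (length(query))
          write_tsv(enrich_pathways(query, universe, gmt),
                    file.path(out_dir, "enrichment.tsv"))
      }
    })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# rebuild an msi_segmentation_set from written labels (cache path)
segmentation_from_files <- function(dir, k_range, cubes) {
  lab <- read_tsv(file.path(dir, "labels.tsv"))
  ch <- cubes[[1L]]$channels
  res <- lapply(k_range, function(k) {
    cent <- read_tsv(file.path(dir, sprintf("centroids_K%d.tsv", k)))
    list(k = k,
         assignments = data.frame(patient_id = as.character(lab$patient_id),
                                  x = lab$x, y = lab$y,
                                  label = lab[[sprintf("label_K%d", k)]],
                                  stringsAsFactors = FALSE),
         centroids = as.matrix(cent[, -1L]),
         inertia = NA_real_,
         sizes = tabulate(lab[[sprintf("label_K%d", k)]], k))
  })
  names(res) <- sprintf("K%d", k_range)
  structure(res, class = "msi_segmentation_set", channels = ch,
            patients = sort(unique(as.character(lab$patient_id))))
}
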