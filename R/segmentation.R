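#' Correlation distance between two spectra
#'
#' `1 - Pearson correlation`, in `[0, 2]`: 0 for proportional spectra, 2 for
#' perfectly anticorrelated ones. Scale- and offset-invariant, which is why it
#' is the distance of choice for segmenting TIC-normalised MSI pixels.
#'
#' @param a,b numeric vectors of length >= 3 with non-zero variance.
#' @return the correlation distance.
#' @export
correlation_distance <- function(a, b) {
  if (length(a) < 3L || length(b) != length(a))
    stop("vectors must share a length >= 3", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance vector: filter constant spectra upstream", call. = FALSE)
  1 - cor(a, b)
}

# centre rows to mean 0 and scale to unit norm; correlation distance between
# rows is then ||u - v||^2 / 2, so Lloyd's algorithm in Euclidean geometry
# minimises total correlation distance.
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0))
    stop(sprintf("%d zero-variance row(s): filter constant spectra upstream",
                 sum(nrm == 0)), call. = FALSE)
  x / nrm
}

# one spherical Lloyd run on standardized (zero-mean, unit-norm) rows.
# Centroids are renormalised to unit vectors each update, so the Euclidean
# argmin equals the correlation-distance argmin exactly and the inertia is
# the total correlation distance to assigned centroids.
lloyd_corr <- function(u, k, max_iter) {
  n <- nrow(u)
  centers <- u[sample.int(n, k), , drop = FALSE]
  assign_old <- integer(n)
  for (it in seq_len(max_iter)) {
    score <- u %*% t(centers) # cosine = Pearson r for standardized rows
    assign_new <- max.col(score, ties.method = "first")
    # repair empty clusters by reseeding from the farthest point
    repeat {
      sizes <- tabulate(assign_new, k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      cur <- score[cbind(seq_len(n), assign_new)]
      far <- which.min(cur) # lowest cosine = largest distance to its centroid
      centers[empty[1L], ] <- u[far, ]
      score[, empty[1L]] <- u %*% centers[empty[1L], ]
      assign_new[far] <- empty[1L]
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      cj <- colMeans(u[assign_new == j, , drop = FALSE])
      nrm <- sqrt(sum(cj^2))
      centers[j, ] <- if (nrm > 0) cj / nrm else u[sample.int(n, 1L), ]
    }
  }
  corr <- score[cbind(seq_len(n), assign_new)]
  list(labels = assign_new, centers = centers, inertia = sum(1 - corr))
}

#' K-means clustering under correlation distance
#'
#' Lloyd's algorithm on row-standardised spectra (each row centred to mean 0
#' and scaled to unit norm), which makes squared Euclidean distance monotone in
#' correlation distance. The best of `n_init` random initialisations by total
#' correlation-distance inertia is kept; empty clusters are repaired by
#' reseeding from the farthest pixel; labels are renumbered by descending
#' cluster size. Deterministic given `seed`.
#'
#' @param x numeric matrix, pixels x channels; rows must have non-zero
#'   variance.
#' @param k number of clusters, `2 <= k <= nrow(x)`.
#' @param seed integer seed.
#' @param n_init random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return object of class `msi_kmeans`: `k`, `labels` (1..k per row),
#'   `centroids` (k x channels mean raw spectra), `centroids_std` (the
#'   zero-mean unit-norm centroids that define the assignment), `inertia`
#'   (sum of correlation distances to assigned centroids) and `sizes`.
#' @export
kmeans_correlation <- function(x, k, seed = 1L, n_init = 10L, max_iter = 300L) {
  x <- as.matrix(x)
  k <- assert_count(k, "k", 2L)
  if (k > nrow(x)) stop("k exceeds the number of rows", call. = FALSE)
  n_init <- assert_count(n_init, "n_init")
  u <- standardize_rows(x)
  best <- with_seed(seed, {
    b <- NULL
    for (i in seq_len(n_init)) {
      run <- lloyd_corr(u, k, max_iter)
      if (is.null(b) || run$inertia < b$inertia) b <- run
    }
    b
  })
  # renumber by descending global pixel count (ties: original order)
  sizes <- tabulate(best$labels, k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k); remap[ord] <- seq_len(k)
  labels <- remap[best$labels]
  centroids <- t(vapply(seq_len(k),
                        function(j) colMeans(x[labels == j, , drop = FALSE]),
                        numeric(ncol(x))))
  structure(list(k = k, labels = labels, centroids = centroids,
                 centroids_std = best$centers[ord, , drop = FALSE],
                 inertia = best$inertia, sizes = tabulate(labels, k)),
            class = "msi_kmeans")
}

#' @export
print.msi_kmeans <- function(x, ...) {
  cat(sprintf("<msi_kmeans> k = %d, inertia = %.4f, sizes: %s\n",
              x$k, x$inertia, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Segment a cohort into metabolic subpopulations
#'
#' Pools the pixels of all patients (sorted by patient id, so the result is
#' invariant to input ordering) and runs [kmeans_correlation()] for each K in
#' `k_range`. Pooling before clustering makes subpopulation labels comparable
#' across patients. Zero-variance pixels are dropped with a message.
#'
#' @param cubes list of `msi_cube` sharing channels (preprocessed).
#' @param k_range integer vector of cluster counts (default `2:10`).
#' @param seed integer seed.
#' @param n_init random restarts per K.
#' @return object of class `msi_segmentation_set`: a named list (`K2`, ...)
#'   of per-K results, each with `k`, `assignments` (data.frame `patient_id`,
#'   `x`, `y`, `label`), `centroids`, `inertia`, `sizes`; plus attributes
#'   `channels` and `patients`.
#' @export
segment_cohort <- function(cubes, k_range = 2:10, seed = 1L, n_init = 10L) {
  if (inherits(cubes, "msi_cube")) cubes <- list(cubes)
  ch <- stop_unless_shared_channels(cubes)
  ids <- vapply(cubes, function(cb) cb$patient_id, character(1))
  cubes <- cubes[order(ids)]
  pooled <- do.call(rbind, lapply(cubes, function(cb) cb$intensities))
  index <- do.call(rbind, lapply(cubes, function(cb)
    data.frame(patient_id = cb$patient_id, x = cb$coords$x, y = cb$coords$y,
               stringsAsFactors = FALSE)))
  cent <- pooled - rowMeans(pooled)
  keep <- rowSums(cent^2) > 0
  if (!all(keep)) {
    message(sprintf("dropping %d zero-variance pixel(s) before clustering",
                    sum(!keep)))
    pooled <- pooled[keep, , drop = FALSE]
    index <- index[keep, , drop = FALSE]
  }
  res <- lapply(k_range, function(k) {
    km <- kmeans_correlation(pooled, k, seed = derive_seed(seed, k),
                             n_init = n_init)
    list(k = k,
         assignments = cbind(index, label = km$labels),
         centroids = km$centroids, inertia = km$inertia, sizes = km$sizes)
  })
  names(res) <- sprintf("K%d", k_range)
  structure(res, class = "msi_segmentation_set", channels = ch,
            patients = sort(unique(index$patient_id)))
}

#' Per-patient cluster composition
#'
#' Share of a patient's pixels in each of the K subpopulations of one
#' segmentation; zeros are allowed and shares sum to 1.
#'
#' @param seg one element of a `msi_segmentation_set` (fields `k`,
#'   `assignments`).
#' @param patient_id patient identifier present in the segmentation.
#' @return list of class `cluster_composition`: `patient_id`, `shares`
#'   (length-K numeric) and `n_pixels`.
#' @export
composition <- function(seg, patient_id) {
  a <- seg$assignments
  rows <- a$patient_id == patient_id
  if (!any(rows)) stop(sprintf("unknown patient '%s'", patient_id), call. = FALSE)
  n <- sum(rows)
  shares <- tabulate(a$label[rows], seg$k) / n
  structure(list(patient_id = patient_id, shares = shares, n_pixels = n),
            class = "cluster_composition")
}

#' Composition matrix of all patients
#'
#' @param seg one element of a `msi_segmentation_set`.
#' @return patients x K matrix of pixel shares (rows sum to 1), with patient
#'   ids as row names and an attribute `n_pixels`.
#' @export
composition_matrix <- function(seg) {
  ids <- sort(unique(seg$assignments$patient_id))
  comps <- lapply(ids, composition, seg = seg)
  m <- do.call(rbind, lapply(comps, `[[`, "shares"))
  rownames(m) <- ids
  attr(m, "n_pixels") <- vapply(comps, `[[`, numeric(1), "n_pixels")
  m
}

#' Write segmentation label maps and centroids
#'
#' @param segset an `msi_segmentation_set`.
#' @param dir output directory; writes `labels.tsv` (patient_id, x, y, one
#'   `label_K*` column per K) and `centroids_K*.tsv`.
#' @return `dir`, invisibly.
#' @export
write_segmentation <- function(segset, dir) {
  stopifnot(inherits(segset, "msi_segmentation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- segset[[1L]]$assignments[, c("patient_id", "x", "y")]
  for (nm in names(segset)) base[[paste0("label_", nm)]] <- segset[[nm]]$assignments$label
  write_tsv(base, file.path(dir, "labels.tsv"))
  ch <- attr(segset, "channels")
  for (nm in names(segset)) {
    cent <- as.data.frame(segset[[nm]]$centroids)
    names(cent) <- sprintf("mz_%.6f", ch)
    cent <- cbind(data.frame(cluster = seq_len(segset[[nm]]$k)), cent)
    write_tsv(cent, file.path(dir, sprintf("centroids_%s.tsv", nm)))
  }
  invisible(dir)
}
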