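#' Total-ion-count normalisation
#'
#' Divides each pixel's spectrum by its total intensity so that every pixel
#' sums to 1; relative channel proportions within a pixel are unchanged and the
#' operation is idempotent.
#'
#' @param cube an `msi_cube`.
#' @param drop_empty if `TRUE`, pixels with zero total intensity are dropped
#'   (with a message); if `FALSE` (default) such a pixel is an error naming its
#'   coordinates.
#' @return a TIC-normalised `msi_cube`.
#' @export
tic_normalize <- function(cube, drop_empty = FALSE) {
  stopifnot(inherits(cube, "msi_cube"))
  tot <- rowSums(cube$intensities)
  zero <- tot <= 0
  if (any(zero)) {
    if (!drop_empty) {
      bad <- which(zero)[1L]
      stop(sprintf("pixel (x=%d, y=%d) of patient %s has zero total intensity",
                   cube$coords$x[bad], cube$coords$y[bad], cube$patient_id),
           call. = FALSE)
    }
    message(sprintf("dropping %d all-zero pixel(s) from patient %s",
                    sum(zero), cube$patient_id))
    cube$coords <- cube$coords[!zero, , drop = FALSE]
    cube$intensities <- cube$intensities[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  cube$intensities <- cube$intensities / tot
  cube
}

#' Cohort-wide peak selection
#'
#' Computes the cohort-mean spectrum over all pixels of all patients and keeps
#' the `n_peaks` channels with the highest mean intensity among local maxima of
#' that mean spectrum (boundary channels compare against their single
#' neighbour). Ties are broken toward lower m/z. Deterministic and invariant to
#' patient ordering.
#'
#' @param cubes list of `msi_cube` sharing channels (normalise first).
#' @param n_peaks number of peaks to keep (>= 1).
#' @return data.frame of class `peak_list` with columns `mz` (ascending) and
#'   `statistic` (cohort-mean intensity).
#' @export
select_peaks <- function(cubes, n_peaks) {
  if (inherits(cubes, "msi_cube")) cubes <- list(cubes)
  ch <- stop_unless_shared_channels(cubes)
  # fixed summation order keeps the statistic bit-identical under reordering
  cubes <- cubes[order(vapply(cubes, function(cb) cb$patient_id, character(1)))]
  n_peaks <- assert_count(n_peaks, "n_peaks")
  if (n_peaks > length(ch)) stop("n_peaks exceeds the channel count", call. = FALSE)
  sums <- Reduce(`+`, lapply(cubes, function(cb) colSums(cb$intensities)))
  npx <- sum(vapply(cubes, function(cb) nrow(cb$intensities), numeric(1)))
  m <- sums / npx
  nc <- length(m)
  left <- c(-Inf, m[-nc])
  right <- c(m[-1L], -Inf)
  is_max <- m >= left & m >= right
  cand <- which(is_max)
  if (length(cand) < n_peaks) {
    warning(sprintf("only %d local maxima available; returning all of them",
                    length(cand)))
    n_peaks <- length(cand)
  }
  keep <- cand[order(-m[cand], ch[cand])][seq_len(n_peaks)]
  keep <- sort(keep)
  structure(data.frame(mz = ch[keep], statistic = m[keep]),
            class = c("peak_list", "data.frame"))
}

#' Reduce a datacube to a selected peak list
#'
#' Keeps only the channels of `peaks`, matched to the cube's axis by nearest
#' channel within `tol_ppm`.
#'
#' @param cube an `msi_cube`.
#' @param peaks a `peak_list` (or numeric m/z vector).
#' @param tol_ppm matching tolerance in ppm.
#' @return the reduced `msi_cube`.
#' @export
reduce_to_peaks <- function(cube, peaks, tol_ppm = 5) {
  stopifnot(inherits(cube, "msi_cube"))
  mz <- if (is.numeric(peaks)) peaks else peaks$mz
  idx <- vapply(mz, function(m) which.min(abs(cube$channels - m)), integer(1))
  off <- abs(cube$channels[idx] - mz) / mz * 1e6
  if (any(off > tol_ppm))
    stop("peak list does not match the cube's channel axis within tolerance",
         call. = FALSE)
  cube$channels <- cube$channels[idx]
  cube$intensities <- cube$intensities[, idx, drop = FALSE]
  cube
}

#' Edge-preserving spatial denoising of ion images
#'
#' Replaces each pixel's value, per channel, with the median over the
#' `window` x `window` spatial neighbourhood of pixels present in the cube
#' (missing neighbours are ignored). `window = 1` is the identity. Median
#' filtering preserves edges and never leaves the per-channel intensity range.
#'
#' @param cube an `msi_cube`.
#' @param window odd integer window side length.
#' @return the denoised `msi_cube`.
#' @export
denoise_ion_images <- function(cube, window = 3L) {
  stopifnot(inherits(cube, "msi_cube"))
  window <- assert_count(window, "window")
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window == 1L) return(cube)
  r <- window %/% 2L
  x <- cube$coords$x; y <- cube$coords$y
  key <- paste(x, y)
  lut <- setNames(seq_along(key), key)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  nb <- matrix(NA_integer_, nrow(cube$coords), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    k <- paste(x + offs$dx[j], y + offs$dy[j])
    hit <- lut[k]
    nb[, j] <- ifelse(is.na(hit), NA_integer_, hit)
  }
  out <- cube$intensities
  for (c in seq_along(cube$channels)) {
    v <- cube$intensities[, c]
    vm <- matrix(v[nb], nrow(nb), ncol(nb))
    out[, c] <- apply(vm, 1L, median, na.rm = TRUE)
  }
  cube$intensities <- out
  cube
}

#' Moving-minimum baseline subtraction
#'
#' Optional baseline removal for profile-mode spectra: subtracts, per pixel,
#' the running minimum of the spectrum over a channel window. A no-op for
#' peak-picked data whose baseline is already removed.
#'
#' @param cube an `msi_cube`.
#' @param window odd integer window in channels.
#' @return baseline-subtracted `msi_cube`.
#' @export
baseline_subtract <- function(cube, window = 51L) {
  stopifnot(inherits(cube, "msi_cube"))
  window <- assert_count(window, "window")
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window == 1L) return(cube)
  r <- window %/% 2L
  nch <- length(cube$channels)
  inten <- cube$intensities
  base <- inten
  for (c in seq_len(nch)) {
    lo <- max(1L, c - r); hi <- min(nch, c + r)
    sub <- inten[, lo:hi, drop = FALSE]
    base[, c] <- do.call(pmin, as.data.frame(sub))
  }
  cube$intensities <- inten - base
  cube
}

#' Preprocess a cohort of datacubes
#'
#' TIC-normalises every cube, selects cohort-wide peaks, reduces each cube to
#' the shared peak axis and applies spatial median denoising.
#'
#' @param cubes list of `msi_cube` with a shared channel axis.
#' @param n_peaks peaks to keep (default half of the channels).
#' @param denoise_window odd window for [denoise_ion_images()]; 1 disables.
#' @param drop_empty passed to [tic_normalize()].
#' @return list with `cubes` (processed list) and `peaks` (the `peak_list`).
#' @export
preprocess_cohort <- function(cubes, n_peaks = NULL, denoise_window = 3L,
                              drop_empty = TRUE) {
  if (inherits(cubes, "msi_cube")) cubes <- list(cubes)
  stop_unless_shared_channels(cubes)
  cubes <- lapply(cubes, tic_normalize, drop_empty = drop_empty)
  if (is.null(n_peaks)) n_peaks <- max(2L, length(cubes[[1L]]$channels) %/% 2L)
  peaks <- select_peaks(cubes, n_peaks)
  cubes <- lapply(cubes, reduce_to_peaks, peaks = peaks)
  if (denoise_window > 1L)
    cubes <- lapply(cubes, denoise_ion_images, window = denoise_window)
  list(cubes = cubes, peaks = peaks)
}
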