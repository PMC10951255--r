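#' Construct a patient MSI datacube
#'
#' A datacube holds one patient's imaging-MS data: integer pixel coordinates
#' (0-based, `x` = column, `y` = row) and one intensity vector per pixel over a
#' shared, strictly increasing m/z channel axis.
#'
#' @param patient_id character scalar identifier.
#' @param coords data.frame with integer columns `x`, `y`; no duplicates.
#' @param channels numeric vector of m/z values (Da), strictly increasing.
#' @param intensities numeric matrix, `nrow(coords)` x `length(channels)`,
#'   finite and non-negative.
#' @return an object of class `msi_cube`.
#' @export
patient_datacube <- function(patient_id, coords, channels, intensities) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords)))
    stop("`coords` must have columns x and y", call. = FALSE)
  coords <- data.frame(x = as.integer(coords$x), y = as.integer(coords$y))
  if (anyDuplicated(coords))
    stop("duplicate pixel coordinates in `coords`", call. = FALSE)
  channels <- as.numeric(channels)
  if (length(channels) < 1L || is.unsorted(channels, strictly = TRUE))
    stop("`channels` must be strictly increasing", call. = FALSE)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(coords) || ncol(intensities) != length(channels))
    stop("`intensities` must be pixels x channels", call. = FALSE)
  if (!all(is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  structure(list(patient_id = patient_id, coords = coords,
                 channels = channels, intensities = intensities),
            class = "msi_cube")
}

#' @export
print.msi_cube <- function(x, ...) {
  cat(sprintf("<msi_cube> patient %s: %d pixels x %d channels (m/z %.3f-%.3f)\n",
              x$patient_id, nrow(x$coords), length(x$channels),
              min(x$channels), max(x$channels)))
  invisible(x)
}

#' @export
dim.msi_cube <- function(x) c(nrow(x$coords), length(x$channels))

stop_unless_shared_channels <- function(cubes) {
  ch <- cubes[[1L]]$channels
  same <- vapply(cubes, function(cb)
    length(cb$channels) == length(ch) && all(cb$channels == ch), logical(1))
  if (!all(same)) stop("all datacubes must share an identical channel axis",
                       call. = FALSE)
  ch
}

#' Write datacubes to the tabular pixel format
#'
#' One row per pixel: `patient_id`, `x`, `y`, then one intensity column per
#' m/z channel named `mz_<value>`.
#'
#' @param cubes a list of `msi_cube` objects sharing channels.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pixel_table <- function(cubes, path) {
  if (inherits(cubes, "msi_cube")) cubes <- list(cubes)
  ch <- stop_unless_shared_channels(cubes)
  tabs <- lapply(cubes, function(cb) {
    df <- data.frame(patient_id = cb$patient_id, x = cb$coords$x, y = cb$coords$y)
    cbind(df, as.data.frame(cb$intensities))
  })
  out <- do.call(rbind, tabs)
  names(out)[-(1:3)] <- sprintf("mz_%.6f", ch)
  write_tsv(out, path)
}

#' Read datacubes from the tabular pixel format
#'
#' @param path TSV path written by [write_pixel_table()] (columns `patient_id`,
#'   `x`, `y`, `mz_*`).
#' @return list of `msi_cube`, one per patient, ordered by patient id.
#' @export
read_pixel_table <- function(path) {
  df <- read_tsv(path)
  need <- c("patient_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("pixel table must have columns patient_id, x, y", call. = FALSE)
  mzcols <- grep("^mz_", names(df), value = TRUE)
  if (!length(mzcols)) stop("pixel table has no mz_* intensity columns", call. = FALSE)
  channels <- as.numeric(sub("^mz_", "", mzcols))
  ord <- order(channels)
  channels <- channels[ord]
  mzcols <- mzcols[ord]
  ids <- sort(unique(as.character(df$patient_id)))
  lapply(ids, function(id) {
    sub <- df[df$patient_id == id, , drop = FALSE]
    patient_datacube(id, sub[, c("x", "y")], channels,
                     as.matrix(sub[, mzcols, drop = FALSE]))
  })
}
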