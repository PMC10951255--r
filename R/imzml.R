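# Minimal imzML support: enough of the imaging MS interchange format to
# round-trip peak-picked datacubes (continuous mode: one shared m/z axis;
# processed mode: a per-spectrum m/z axis). Values are stored as 64-bit
# floats in the external .ibd file, which starts with the 16-byte UUID also
# recorded in the XML.

imzml_uuid <- function() {
  paste(sprintf("%02x", as.integer(sample(0:255, 16, replace = TRUE))),
        collapse = "")
}

#' Write a datacube as an imzML/ibd file pair
#'
#' @param cube an `msi_cube`.
#' @param path_base path without extension; writes `<path_base>.imzML` and
#'   `<path_base>.ibd`.
#' @param mode `"continuous"` (shared m/z axis stored once) or `"processed"`
#'   (m/z axis repeated per spectrum).
#' @return the imzML path, invisibly.
#' @export
write_imzml <- function(cube, path_base, mode = c("continuous", "processed")) {
  stopifnot(inherits(cube, "msi_cube"))
  mode <- match.arg(mode)
  xml_path <- paste0(path_base, ".imzML")
  ibd_path <- paste0(path_base, ".ibd")
  uuid <- with_seed(sum(utf8ToInt(cube$patient_id)), imzml_uuid())
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)), 16L)), con)
  offset <- 16
  n_px <- nrow(cube$coords)
  n_ch <- length(cube$channels)
  mz_off <- int_off <- mz_len <- numeric(n_px)
  if (mode == "continuous") {
    writeBin(cube$channels, con, size = 8, endian = "little")
    shared_mz_off <- offset
    offset <- offset + 8 * n_ch
  }
  for (i in seq_len(n_px)) {
    if (mode == "processed") {
      writeBin(cube$channels, con, size = 8, endian = "little")
      mz_off[i] <- offset
      offset <- offset + 8 * n_ch
    } else mz_off[i] <- shared_mz_off
    writeBin(as.numeric(cube$intensities[i, ]), con, size = 8, endian = "little")
    int_off[i] <- offset
    offset <- offset + 8 * n_ch
    mz_len[i] <- n_ch
  }
  spec <- vapply(seq_len(n_px), function(i) sprintf(
    paste0(
      '  <spectrum index="%d">\n',
      '   <scanList count="1"><scan>\n',
      '    <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '    <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '   </scan></scanList>\n',
      '   <binaryDataArrayList count="2">\n',
      '    <binaryDataArray><referenceableParamGroupRef ref="mzArray"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '    </binaryDataArray>\n',
      '    <binaryDataArray><referenceableParamGroupRef ref="intensityArray"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
      '     <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '    </binaryDataArray>\n',
      '   </binaryDataArrayList>\n',
      '  </spectrum>'),
    i - 1L, cube$coords$x[i] + 1L, cube$coords$y[i] + 1L,
    mz_off[i], n_ch, int_off[i], n_ch), character(1))
  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  xml <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    ' <fileDescription><fileContent>',
    sprintf('  <cvParam cvRef="IMS" accession="%s" name="%s"/>', mode_acc, mode),
    sprintf('  <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', uuid),
    ' </fileContent></fileDescription>',
    ' <referenceableParamGroupList count="2">',
    '  <referenceableParamGroup id="mzArray">',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '  </referenceableParamGroup>',
    '  <referenceableParamGroup id="intensityArray">',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '  </referenceableParamGroup>',
    ' </referenceableParamGroupList>',
    sprintf(' <run id="%s">', cube$patient_id),
    sprintf(' <spectrumList count="%d">', n_px),
    spec,
    ' </spectrumList>',
    ' </run>',
    '</mzML>')
  writeLines(xml, xml_path)
  invisible(xml_path)
}

#' Read an imzML/ibd file pair into a datacube
#'
#' Supports the continuous and processed modes written by [write_imzml()]
#' (64-bit float arrays). Processed-mode per-spectrum m/z axes are binned onto
#' the first spectrum's axis by nearest channel within `tol_ppm`.
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit alongside).
#' @param patient_id identifier for the resulting cube (default: file stem).
#' @param tol_ppm merge tolerance for processed-mode axes (default 5 ppm).
#' @return an `msi_cube`.
#' @export
read_imzml <- function(path, patient_id = NULL,
                       tol_ppm = 5) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing .ibd file next to the imzML", call. = FALSE)
  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (!length(spectra)) stop("imzML contains no spectra", call. = FALSE)
  get_pos <- function(sp, acc) as.integer(xml2::xml_attr(
    xml2::xml_find_first(sp, sprintf(".//cvParam[@accession='%s']", acc)), "value"))
  get_arr <- function(sp, ref) {
    node <- xml2::xml_find_first(sp, sprintf(
      ".//binaryDataArray[referenceableParamGroupRef/@ref='%s']", ref))
    c(offset = as.numeric(xml2::xml_attr(xml2::xml_find_first(
        node, ".//cvParam[@accession='IMS:1000102']"), "value")),
      length = as.numeric(xml2::xml_attr(xml2::xml_find_first(
        node, ".//cvParam[@accession='IMS:1000103']"), "value")))
  }
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  read_arr <- function(a) {
    seek(con, a[["offset"]])
    readBin(con, "double", n = a[["length"]], size = 8, endian = "little")
  }
  first_mz <- read_arr(get_arr(spectra[[1L]], "mzArray"))
  n_px <- length(spectra)
  inten <- matrix(0, n_px, length(first_mz))
  xs <- ys <- integer(n_px)
  for (i in seq_len(n_px)) {
    sp <- spectra[[i]]
    xs[i] <- get_pos(sp, "IMS:1000050") - 1L
    ys[i] <- get_pos(sp, "IMS:1000051") - 1L
    mz_i <- read_arr(get_arr(sp, "mzArray"))
    v <- read_arr(get_arr(sp, "intensityArray"))
    if (length(mz_i) == length(first_mz) && all(mz_i == first_mz)) {
      inten[i, ] <- v
    } else {
      # processed mode with a differing axis: nearest-channel binning
      for (j in seq_along(mz_i)) {
        tgt <- which.min(abs(first_mz - mz_i[j]))
        if (abs(first_mz[tgt] - mz_i[j]) / mz_i[j] * 1e6 <= tol_ppm)
          inten[i, tgt] <- inten[i, tgt] + v[j]
      }
    }
  }
  patient_datacube(patient_id %||% sub("\\.imzML$", "", basename(path),
                                       ignore.case = TRUE),
                   data.frame(x = xs, y = ys), first_mz, inten)
}
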