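#' @name imzml
#' @title imzML input/output for simulated EA-IMS datasets
#'
#' @description Minimal continuous-mode imzML 1.1 writer and reader.  The
#' `.ibd` binary companion stores the 16-byte UUID, the shared m/z axis as
#' 64-bit floats and one 32-bit float intensity array per pixel; the XML
#' carries coordinates, external-offset bookkeeping, the ibd MD5 checksum,
#' and the simulation condition metadata as user parameters so that a
#' write/read round trip restores the dataset.
NULL

# deterministic 16-byte uuid from the dataset seed
.make_uuid <- function(seed) {
  state <- as.numeric(seed %% 2147483629)
  bytes <- integer(16)
  for (i in 1:16) {
    state <- (state * 48271 + 11) %% 2147483629
    bytes[i] <- as.integer(state %% 256)
  }
  # RFC 4122-style version/variant bits
  bytes[7] <- bitwOr(bitwAnd(bytes[7], 15L), 64L)
  bytes[9] <- bitwOr(bitwAnd(bytes[9], 63L), 128L)
  as.raw(bytes)
}

.format_uuid <- function(raw16) {
  hex <- paste(sprintf("%02x", as.integer(raw16)), collapse = "")
  paste(substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
        substr(hex, 17, 20), substr(hex, 21, 32), sep = "-")
}

#' Write a dataset as an imzML/ibd pair
#'
#' @param dataset An `ims_dataset` (see [render_dataset()]).
#' @param path Output path without extension; `<path>.imzML` and
#'   `<path>.ibd` are produced.
#' @return Invisibly, the imzML path.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "ims_dataset"))
  n_pix <- ncol(dataset$intensity)
  n_mz <- length(dataset$mz)
  if (n_pix == 0 || n_mz == 0) stop("cannot write an empty dataset")
  if (anyDuplicated(dataset$coords[, c("x", "y")])) {
    stop("coordinate collision: duplicated pixel positions")
  }

  path <- sub("\\.imzML$", "", path)
  ibd_path <- paste0(path, ".ibd")
  xml_path <- paste0(path, ".imzML")

  uuid <- .make_uuid(dataset$metadata$seed %||% 1L)
  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  writeBin(as.numeric(dataset$mz), con, size = 8, endian = "little")
  for (p in seq_len(n_pix)) {
    writeBin(as.numeric(dataset$intensity[, p]), con, size = 4,
             endian = "little")
  }
  close(con)
  md5 <- toupper(unname(tools::md5sum(ibd_path)))

  mz_offset <- 16
  mz_bytes <- 8 * n_mz
  int_bytes <- 4 * n_mz
  int_offsets <- 16 + mz_bytes + int_bytes * (seq_len(n_pix) - 1)

  meta <- dataset$metadata
  user_params <- paste0(
    sprintf('        <userParam name="condition" value="%s"/>\n', meta$condition),
    sprintf('        <userParam name="incubation_time_min" value="%g"/>\n', meta$time_min),
    sprintf('        <userParam name="attenuation" value="%g"/>\n', meta$attenuation %||% 1),
    sprintf('        <userParam name="seed" value="%d"/>\n', meta$seed %||% 1L),
    sprintf('        <userParam name="grid_height" value="%d"/>\n', meta$height),
    sprintf('        <userParam name="grid_width" value="%d"/>', meta$width)
  )

  spectra <- sprintf(paste0(
    '      <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">\n',
    '        <referenceableParamGroupRef ref="spectrum1"/>\n',
    '        <scanList count="1">\n',
    '          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>\n',
    '          <scan>\n',
    '            <referenceableParamGroupRef ref="scan1"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
    '          </scan>\n',
    '        </scanList>\n',
    '        <binaryDataArrayList count="2">\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="mzArray"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="intensityArray"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>'),
    seq_len(n_pix), n_mz, seq_len(n_pix) - 1L,
    dataset$coords$x, dataset$coords$y,
    mz_offset, n_mz, mz_bytes,
    int_offsets, n_mz, int_bytes
  )

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '  <cvList count="3">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.cvs.sourceforge.net/*checkout*/psidev/psi/psi-ms/mzML/controlledVocabulary/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription>\n',
    '    <fileContent>\n',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
            .format_uuid(uuid)),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>\n', md5),
    user_params, '\n',
    '    </fileContent>\n',
    '  </fileDescription>\n',
    '  <referenceableParamGroupList count="4">\n',
    '    <referenceableParamGroup id="spectrum1">\n',
    '      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="scan1">\n',
    '      <cvParam cvRef="MS" accession="MS:1000093" name="increasing m/z scan" value=""/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="mzArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '    <referenceableParamGroup id="intensityArray">\n',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>\n',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    '    </referenceableParamGroup>\n',
    '  </referenceableParamGroupList>\n',
    '  <softwareList count="1">\n',
    '    <software id="eaims" version="0.1.0">\n',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="eaims"/>\n',
    '    </software>\n',
    '  </softwareList>\n',
    '  <scanSettingsList count="1">\n',
    '    <scanSettings id="scanSettings1">\n',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
            dataset$metadata$width),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
            dataset$metadata$height),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g"/>\n',
            dataset$metadata$pixel_size),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>\n',
            dataset$metadata$pixel_size),
    '    </scanSettings>\n',
    '  </scanSettingsList>\n',
    '  <instrumentConfigurationList count="1">\n',
    '    <instrumentConfiguration id="IC1"/>\n',
    '  </instrumentConfigurationList>\n',
    '  <dataProcessingList count="1">\n',
    '    <dataProcessing id="export">\n',
    '      <processingMethod order="1" softwareRef="eaims">\n',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
    '      </processingMethod>\n',
    '    </dataProcessing>\n',
    '  </dataProcessingList>\n',
    sprintf('  <run defaultInstrumentConfigurationRef="IC1" id="%s">\n',
            basename(path)),
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="export">\n', n_pix),
    paste(spectra, collapse = "\n"), '\n',
    '    </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n'
  )
  writeLines(xml, xml_path, sep = "")
  invisible(xml_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an imzML/ibd pair
#'
#' Reads a continuous-mode imzML file (as written by [write_imzml()] or
#' other continuous-mode writers) back into an `ims_dataset`.
#'
#' @param path Path to the `.imzML` file (or base path without extension).
#' @return An `ims_dataset`.
#' @export
read_imzml <- function(path) {
  if (!grepl("\\.imzML$", path)) path <- paste0(path, ".imzML")
  if (!file.exists(path)) stop("imzML file not found: ", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path)
  if (!file.exists(ibd_path)) stop("ibd file not found: ", ibd_path)

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  cv <- function(node, accession) {
    n <- xml2::xml_find_first(
      node, sprintf('.//cvParam[@accession="%s"]', accession))
    if (inherits(n, "xml_missing")) NULL else xml2::xml_attr(n, "value")
  }
  if (is.null(cv(doc, "IMS:1000030"))) {
    stop("only continuous-mode imzML is supported")
  }

  # number formats from the referenceable param groups
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  mz_size <- int_size <- NULL
  mz_group <- int_group <- NULL
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    has <- function(acc) !is.null(cv(g, acc))
    size <- if (has("MS:1000523")) 8L else if (has("MS:1000521")) 4L else NULL
    if (has("MS:1000514")) { mz_group <- id; mz_size <- size }
    if (has("MS:1000515")) { int_group <- id; int_size <- size }
  }
  if (is.null(mz_size) || is.null(int_size)) {
    stop("could not determine binary number formats")
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0) stop("imzML file contains no spectra")
  n_pix <- length(spectra)
  xs <- ys <- integer(n_pix)
  mz_off <- mz_len <- int_off <- int_len <- numeric(n_pix)
  for (i in seq_len(n_pix)) {
    sp <- spectra[[i]]
    scan <- xml2::xml_find_first(sp, ".//scan")
    xs[i] <- as.integer(cv(scan, "IMS:1000050"))
    ys[i] <- as.integer(cv(scan, "IMS:1000051"))
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, "referenceableParamGroupRef"), "ref")
      off <- as.numeric(cv(bda, "IMS:1000102"))
      len <- as.numeric(cv(bda, "IMS:1000103"))
      if (identical(ref, mz_group)) { mz_off[i] <- off; mz_len[i] <- len }
      if (identical(ref, int_group)) { int_off[i] <- off; int_len[i] <- len }
    }
  }

  con <- file(ibd_path, "rb")
  on.exit(close(con))
  ibd_uuid <- readBin(con, "raw", 16)
  xml_uuid <- cv(doc, "IMS:1000080")
  if (!is.null(xml_uuid)) {
    clean <- gsub("[{}-]", "", xml_uuid)
    if (tolower(clean) != paste(sprintf("%02x", as.integer(ibd_uuid)),
                                collapse = "")) {
      stop("UUID mismatch between imzML and ibd")
    }
  }
  seek(con, mz_off[1])
  mz <- readBin(con, "double", n = mz_len[1], size = mz_size,
                endian = "little")
  intensity <- matrix(0, nrow = mz_len[1], ncol = n_pix)
  for (i in seq_len(n_pix)) {
    seek(con, int_off[i])
    intensity[, i] <- readBin(con, "double", n = int_len[i], size = int_size,
                              endian = "little")
  }

  up <- function(name) {
    n <- xml2::xml_find_first(doc, sprintf('.//userParam[@name="%s"]', name))
    if (inherits(n, "xml_missing")) NULL else xml2::xml_attr(n, "value")
  }
  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  metadata <- list(
    condition = up("condition") %||% "unknown",
    time_min = num_or_null(up("incubation_time_min")) %||% NA_real_,
    attenuation = num_or_null(up("attenuation")) %||% 1,
    seed = num_or_null(up("seed")) %||% NA_real_,
    pixel_size = num_or_null(cv(doc, "IMS:1000046")) %||% NA_real_,
    height = as.integer(up("grid_height") %||% max(ys)),
    width = as.integer(up("grid_width") %||% max(xs))
  )

  structure(
    list(mz = mz, intensity = intensity,
         coords = data.frame(x = xs, y = ys), metadata = metadata),
    class = "ims_dataset"
  )
}
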