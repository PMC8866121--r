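#' Read mass spectra from mzML or MGF
#'
#' mzML files are read through `mzR` (proteowizard backend); MGF files by
#' a built-in parser of the `BEGIN IONS`/`END IONS` block format. Every
#' scan yields one [ms_spectrum()] in file order. MS2 scans lacking a
#' recorded precursor m/z are read with `precursor_mz = NA` under a
#' warning; downstream precursor filtering excludes them.
#'
#' @param path File path.
#' @param format `"mzml"`, `"mgf"`, or `"auto"` to resolve from the file
#'   extension.
#' @return A list of `ms_spectrum` objects.
#' @export
read_spectra <- function(path, format = c("auto", "mzml", "mgf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  switch(format, mzml = .read_mzml(path), mgf = .read_mgf(path))
}

#' Write mass spectra to mzML or MGF
#'
#' Inverse of [read_spectra()]: peak m/z and intensities round-trip within
#' 1e-6, as does precursor metadata. MGF is an MS2-only format, so writing
#' an MS1 spectrum to MGF is an error; a spectrum without a recorded
#' charge is written without a `CHARGE` line and reads back as `NA`.
#'
#' @param spectra A list of [ms_spectrum()] objects (possibly empty).
#' @param path Output file path.
#' @param format `"mzml"`, `"mgf"`, or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("auto", "mzml", "mgf")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  stopifnot(is.list(spectra),
            all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
  switch(format, mzml = .write_mzml(spectra, path),
         mgf = .write_mgf(spectra, path))
  invisible(path)
}

.guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "mzml") return("mzml")
  if (ext == "mgf") return("mgf")
  stop("cannot resolve spectrum format from extension: ", path)
}

# ---- mzML via mzR ----------------------------------------------------------

.read_mzml <- function(path) {
  fh <- tryCatch(mzR::openMSfile(path, backend = "pwiz"),
                 error = function(e)
                   stop("cannot read mzML file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0L) return(list())
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  out <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    id <- hdr$spectrumId[i]
    if (is.null(id) || is.na(id) || !nzchar(id))
      id <- paste0("scan=", hdr$acquisitionNum[i])
    lvl <- hdr$msLevel[i]
    pmz <- hdr$precursorMZ[i]
    if (!is.na(pmz) && pmz <= 0) pmz <- NA_real_
    if (lvl == 2L && is.na(pmz))
      warning("MS2 scan '", id, "' has no precursor m/z; ",
              "it will be excluded from precursor-based selection")
    z <- hdr$precursorCharge[i]
    if (!is.na(z) && z <= 0) z <- NA_integer_
    # a spectrum counts as profile only when the file says so explicitly
    centroided <- !isFALSE(hdr$centroided[i])
    m <- pk[[i]]
    out[[i]] <- ms_spectrum(
      scan_id = id, ms_level = lvl,
      peaks = data.frame(mz = m[, 1], intensity = m[, 2]),
      precursor_mz = if (lvl == 2L) pmz else NA_real_,
      precursor_charge = if (lvl == 2L) z else NA_integer_,
      retention_time = hdr$retentionTime[i],
      is_centroided = centroided
    )
  }
  out
}

.write_mzml <- function(spectra, path) {
  n <- length(spectra)
  empty <- function(x) rep(x, n)
  lvl <- vapply(spectra, `[[`, integer(1), "ms_level")
  npk <- vapply(spectra, function(s) nrow(s$peaks), integer(1))
  tic <- vapply(spectra, total_ion_current, numeric(1))
  rt <- vapply(spectra, `[[`, numeric(1), "retention_time")
  pmz <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  pz <- vapply(spectra, `[[`, integer(1), "precursor_charge")
  cen <- vapply(spectra, `[[`, logical(1), "is_centroided")
  bp <- t(vapply(spectra, function(s) {
    if (nrow(s$peaks) == 0L) return(c(0, 0))
    i <- which.max(s$peaks$intensity)
    c(s$peaks$mz[i], s$peaks$intensity[i])
  }, numeric(2)))
  rng <- t(vapply(spectra, function(s) {
    if (nrow(s$peaks) == 0L) return(c(0, 0))
    range(s$peaks$mz)
  }, numeric(2)))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = empty(1L), peaksCount = npk, totIonCurrent = tic,
    retentionTime = ifelse(is.na(rt), 0, rt),
    basePeakMZ = bp[, 1], basePeakIntensity = bp[, 2],
    collisionEnergy = empty(0), ionisationEnergy = empty(0),
    lowMZ = rng[, 1], highMZ = rng[, 2],
    precursorScanNum = empty(0L),
    precursorMZ = ifelse(lvl == 2L & !is.na(pmz), pmz, 0),
    precursorCharge = ifelse(lvl == 2L & !is.na(pz), pz, 0L),
    precursorIntensity = empty(0),
    mergedScan = empty(0L), mergedResultScanNum = empty(0L),
    mergedResultStartScanNum = empty(0L), mergedResultEndScanNum = empty(0L),
    injectionTime = empty(0), filterString = empty(NA_character_),
    spectrumId = vapply(spectra, `[[`, character(1), "scan_id"),
    centroided = cen, ionMobilityDriftTime = empty(NA_real_),
    isolationWindowTargetMZ = ifelse(lvl == 2L & !is.na(pmz), pmz, NA_real_),
    isolationWindowLowerOffset = ifelse(lvl == 2L, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(lvl == 2L, 1, NA_real_),
    scanWindowLowerLimit = empty(NA_real_),
    scanWindowUpperLimit = empty(NA_real_),
    stringsAsFactors = FALSE
  )
  pks <- lapply(spectra, function(s)
    cbind(mz = s$peaks$mz, intensity = s$peaks$intensity))
  if (n == 0L) {
    # mzR cannot write a zero-spectrum file; emit a minimal valid mzML
    writeLines(c(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="empty">',
      '  <cvList count="1">',
      '    <cv id="MS" fullName="PSI-MS" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '  </cvList>',
      '  <fileDescription><fileContent>',
      '    <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
      '  </fileContent></fileDescription>',
      '  <softwareList count="1"><software id="sw" version="0">',
      '    <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value=""/>',
      '  </software></softwareList>',
      '  <instrumentConfigurationList count="1">',
      '    <instrumentConfiguration id="IC">',
      '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
      '    </instrumentConfiguration>',
      '  </instrumentConfigurationList>',
      '  <dataProcessingList count="1"><dataProcessing id="dp">',
      '    <processingMethod order="0" softwareRef="sw">',
      '      <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
      '    </processingMethod>',
      '  </dataProcessing></dataProcessingList>',
      '  <run id="run" defaultInstrumentConfigurationRef="IC">',
      '    <spectrumList count="0" defaultDataProcessingRef="dp">',
      '    </spectrumList>',
      '  </run>',
      '</mzML>'), path)
    return(invisible(path))
  }
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

# ---- MGF -------------------------------------------------------------------

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) ||
      (length(begins) && any(ends < begins)))
    stop("malformed MGF file '", path, "': unmatched BEGIN IONS/END IONS ",
         "around block ", max(length(ends), length(begins)))
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "#")]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getval <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    title <- getval("TITLE")
    if (is.na(title)) title <- paste0("index=", b)
    pep <- getval("PEPMASS")
    pmz <- if (is.na(pep)) NA_real_ else
      as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1])
    if (is.na(pmz))
      warning("MS2 scan '", title, "' has no precursor m/z; ",
              "it will be excluded from precursor-based selection")
    ch <- getval("CHARGE")
    z <- if (is.na(ch)) NA_integer_ else {
      zv <- suppressWarnings(as.integer(sub("\\+$", "", trimws(ch))))
      if (is.na(zv) || zv < 1L) NA_integer_ else zv
    }
    rtv <- getval("RTINSECONDS")
    rt <- if (is.na(rtv)) NA_real_ else as.numeric(rtv)
    pkl <- block[!is_kv]
    if (length(pkl)) {
      fields <- strsplit(pkl, "[ \t]+")
      mz <- as.numeric(vapply(fields, `[`, character(1), 1))
      it <- as.numeric(vapply(fields, `[`, character(1), 2))
      if (any(is.na(mz)) || any(is.na(it)))
        stop("malformed MGF peak line in scan '", title, "' of '", path, "'")
      peaks <- data.frame(mz = mz, intensity = it)
    } else {
      peaks <- data.frame(mz = numeric(), intensity = numeric())
    }
    out[[b]] <- ms_spectrum(title, 2L, peaks, precursor_mz = pmz,
                            precursor_charge = z, retention_time = rt,
                            is_centroided = TRUE)
  }
  out
}

.write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (s in spectra) {
    if (s$ms_level != 2L)
      stop("MGF holds MS2 spectra only; scan '", s$scan_id, "' is MS",
           s$ms_level)
    lines <- c("BEGIN IONS", paste0("TITLE=", s$scan_id))
    if (!is.na(s$precursor_mz))
      lines <- c(lines, sprintf("PEPMASS=%.6f", s$precursor_mz))
    if (!is.na(s$precursor_charge))
      lines <- c(lines, sprintf("CHARGE=%d+", s$precursor_charge))
    if (!is.na(s$retention_time))
      lines <- c(lines, sprintf("RTINSECONDS=%.3f", s$retention_time))
    if (nrow(s$peaks))
      lines <- c(lines, sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity))
    lines <- c(lines, "END IONS", "")
    writeLines(lines, con)
  }
  invisible(path)
}
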