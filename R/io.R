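# mzML and CSV input/output.

#' Read an mzML run
#'
#' Reads every scan of an mzML file (indexed or plain, as written by
#' MSConvert or by [write_mzml()]) into a list of [profile_spectrum()]
#' objects. Metadata present in the file (MS level, retention time in
#' seconds, TIC, collision energy, isolation window, scan window, centroid
#' flag) is carried over; metadata mzML cannot express (e.g. microscan
#' count) is recorded as `NA`, never defaulted silently.
#'
#' @param path Path to an mzML file.
#' @return List of [profile_spectrum()] with class `ms_run`; attribute
#'   `source` holds the path. A centroid-only run triggers a warning (the
#'   fine-structure fitter will refuse those scans).
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  n <- length(handle)
  if (n == 0) {
    return(structure(list(), class = "ms_run", source = path))
  }
  hd <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  col <- function(nm, default = NA_real_) {
    if (nm %in% names(hd)) hd[[nm]] else rep(default, n)
  }
  iso_lo <- col("isolationWindowLowerOffset")
  iso_hi <- col("isolationWindowUpperOffset")
  run <- lapply(seq_len(n), function(i) {
    s <- profile_spectrum(
      mz = pk[[i]][, 1], intensity = pk[[i]][, 2],
      scan = col("acquisitionNum", NA_integer_)[i],
      rt = col("retentionTime")[i],
      ms_level = col("msLevel", NA_integer_)[i],
      hcd = col("collisionEnergy")[i],
      iso_center = col("isolationWindowTargetMZ")[i],
      iso_width = iso_lo[i] + iso_hi[i],
      microscans = NA_integer_,
      tic = col("totIonCurrent")[i],
      scan_window = c(col("scanWindowLowerLimit")[i], col("scanWindowUpperLimit")[i]),
      centroided = isTRUE(col("centroided", NA)[i])
    )
    fs <- col("filterString", NA_character_)[i]
    if (!is.na(fs)) attr(s, "filter_string") <- fs
    s
  })
  if (all(vapply(run, function(s) isTRUE(s$centroided), logical(1)))) {
    warning("run contains only centroid scans; fine-structure fitting will refuse them")
  }
  structure(run, class = "ms_run", source = path)
}

#' Write spectra to mzML
#'
#' Writes a list of [profile_spectrum()] objects (or a [simulate_run()]
#' result) as mzML 1.1, readable by [read_run()] and by standard mzML
#' consumers.
#'
#' @param run List of spectra or a `sim_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  if (inherits(run, "sim_run")) run <- run$spectra
  n <- length(run)
  if (n == 0) {
    # the mzML writer needs >= 1 spectrum, so a structurally complete
    # zero-spectrum document is emitted directly
    empty <- paste(
      '<?xml version="1.0" encoding="utf-8"?>',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0" id="empty">',
      '  <cvList count="2">',
      '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" version="4.1.0" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '    <cv id="UO" fullName="Unit Ontology" version="09:04:2014" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
      '  </cvList>',
      '  <fileDescription>',
      '    <fileContent>',
      '      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
      '    </fileContent>',
      '  </fileDescription>',
      '  <softwareList count="1">',
      '    <software id="sw" version="0.1.0">',
      '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="isofine"/>',
      '    </software>',
      '  </softwareList>',
      '  <instrumentConfigurationList count="1">',
      '    <instrumentConfiguration id="IC1">',
      '      <cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
      '    </instrumentConfiguration>',
      '  </instrumentConfigurationList>',
      '  <dataProcessingList count="1">',
      '    <dataProcessing id="dp">',
      '      <processingMethod order="1" softwareRef="sw">',
      '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
      '      </processingMethod>',
      '    </dataProcessing>',
      '  </dataProcessingList>',
      '  <run id="run" defaultInstrumentConfigurationRef="IC1">',
      '    <spectrumList count="0" defaultDataProcessingRef="dp"/>',
      '  </run>',
      '</mzML>', sep = "\n")
    writeLines(empty, path)
    return(invisible(path))
  }
  num <- function(field) vapply(run, function(s) as.numeric(s[[field]] %||% NA), numeric(1))
  tics <- num("tic")
  base_idx <- lapply(run, function(s) if (length(s$intensity)) which.max(s$intensity) else NA_integer_)
  scans <- num("scan")
  scans[is.na(scans)] <- seq_len(n)[is.na(scans)]
  ms_level <- as.integer(num("ms_level"))
  iso_w <- num("iso_width")
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = as.integer(scans),
    msLevel = ms_level, polarity = rep(1L, n),
    peaksCount = vapply(run, function(s) length(s$mz), integer(1)),
    totIonCurrent = tics, retentionTime = num("rt"),
    basePeakMZ = vapply(seq_len(n), function(i) if (is.na(base_idx[[i]])) 0 else run[[i]]$mz[base_idx[[i]]], numeric(1)),
    basePeakIntensity = vapply(seq_len(n), function(i) if (is.na(base_idx[[i]])) 0 else run[[i]]$intensity[base_idx[[i]]], numeric(1)),
    collisionEnergy = num("hcd"), ionisationEnergy = rep(0, n),
    lowMZ = vapply(run, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = rep(NA_integer_, n),
    precursorMZ = ifelse(ms_level > 1, num("iso_center"), NA_real_),
    precursorCharge = ifelse(ms_level > 1, 1L, NA_integer_),
    precursorIntensity = ifelse(ms_level > 1, 0, NA_real_),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(10, n),
    filterString = vapply(run, function(s) attr(s, "filter_string") %||% NA_character_, character(1)),
    spectrumId = paste0("scan=", as.integer(scans)),
    centroided = vapply(run, function(s) isTRUE(s$centroided), logical(1)),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = num("iso_center"),
    isolationWindowLowerOffset = iso_w / 2,
    isolationWindowUpperOffset = iso_w / 2,
    scanWindowLowerLimit = vapply(run, function(s) s$scan_window[1], numeric(1)),
    scanWindowUpperLimit = vapply(run, function(s) s$scan_window[2], numeric(1)),
    stringsAsFactors = FALSE
  )
  pks <- lapply(run, function(s) cbind(s$mz, s$intensity))
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

# canonical ratio-record schema; extract functions produce these columns
.record_columns <- c("scan", "rt", "tic", "species", "area_M",
                     "r_C", "r_H_raw", "r_N", "r_O",
                     "mass_error_ppm", "qc_pass", "flags")

#' Read and write ratio-record tables
#'
#' One row per (scan, species) "datapoint". Written as RFC 4180 CSV (UTF-8,
#' "." decimal) with full double precision, so a round-trip reproduces the
#' field values bit-for-bit. Unknown extra columns are preserved.
#'
#' @param records Tibble of ratio records.
#' @param path CSV path.
#' @return `read_records_csv()` returns the records tibble.
#' @export
write_records_csv <- function(records, path) {
  missing <- setdiff(.record_columns, names(records))
  if (length(missing) > 0) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "))
  }
  # %.17g guarantees a bit-exact double round-trip through the CSV
  out <- records
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    s
  })
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # base strtod parsing: bit-exact doubles (readr's fast parser drops the
  # final bit)
  rec <- tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
  missing <- setdiff(.record_columns, names(rec))
  if (length(missing) > 0) {
    stop("not a ratio-record CSV; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  rec
}

#' Read an experiment-design table
#'
#' The design CSV maps data files to samples, groups and replicates and
#' carries per-sample processing inputs. Required columns: `file`, `sample`,
#' `group`, `replicate`. Optional: `solvent_ppm` (solvent 2H/1H in ppm for
#' the exchangeable-hydrogen correction), `media_ppm` (growth-media 2H for
#' titration designs), `species` (semicolon-separated subset), `notes`.
#'
#' @param path CSV path.
#' @param check_files Error if referenced data files are absent.
#' @return Tibble with class `experiment_design`.
#' @export
read_design <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("file", "sample", "group", "replicate")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("design file missing column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(d$file, d$sample, d$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (file, sample, replicate) rows in design")
  }
  if (check_files && !all(file.exists(d$file))) {
    stop("design references missing file(s): ",
         paste(d$file[!file.exists(d$file)], collapse = ", "))
  }
  structure(d, class = c("experiment_design", class(d)))
}
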