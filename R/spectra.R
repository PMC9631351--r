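# Profile spectra and scan selection.

#' A profile-mode mass spectrum
#'
#' @param mz Numeric vector of m/z values (Th), strictly increasing. Sparse
#'   spectra (disjoint rendered windows) are fine as long as ordering holds.
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param scan Scan index / acquisition number.
#' @param rt Retention time in seconds.
#' @param ms_level MS level (isoMS scans are MS2).
#' @param hcd Normalized HCD collision energy (%).
#' @param iso_center,iso_width Isolation window center and full width (Th).
#' @param microscans Number of co-added microscans (NA when the source file
#'   does not carry it; mzML has no standard slot for it).
#' @param tic Total ion current; defaults to the summed intensity.
#' @param resolution Nominal resolving power setting at m/z 200.
#' @param scan_window Detected m/z range of the acquisition, `c(low, high)`.
#' @param centroided Logical; the fine-structure fitter refuses centroid data.
#' @return List with class `profile_spectrum`.
#' @export
profile_spectrum <- function(mz, intensity, scan = NA_integer_, rt = NA_real_,
                             ms_level = 2L, hcd = NA_real_,
                             iso_center = NA_real_, iso_width = NA_real_,
                             microscans = NA_integer_, tic = NULL,
                             resolution = NA_real_, scan_window = c(NA_real_, NA_real_),
                             centroided = FALSE) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (length(mz) > 1 && any(diff(mz) <= 0)) stop("mz must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(
    mz = mz, intensity = intensity, scan = scan, rt = rt,
    ms_level = as.integer(ms_level), hcd = hcd,
    iso_center = iso_center, iso_width = iso_width,
    microscans = microscans,
    tic = if (is.null(tic)) sum(intensity) else tic,
    resolution = resolution, scan_window = scan_window,
    centroided = isTRUE(centroided)
  ), class = "profile_spectrum")
}

#' @export
print.profile_spectrum <- function(x, ...) {
  cat(sprintf("<profile_spectrum> scan %s  MS%d  %d points  rt %.1fs  TIC %.3g%s\n",
              as.character(x$scan), x$ms_level, length(x$mz), x$rt, x$tic,
              if (x$centroided) "  [centroid]" else ""))
  if (!is.na(x$iso_width)) {
    cat(sprintf("  isolation %.1f +/- %.1f Th, HCD %.0f%%, %s microscans\n",
                x$iso_center, x$iso_width / 2, x$hcd, as.character(x$microscans)))
  }
  invisible(x)
}

#' Scan-selection criteria for isoMS events
#'
#' isoMS scans are broad-isolation (the acquisition uses a 1000 Th wide
#' window), high-energy (HCD 50%) profile MS2 scans detected over m/z
#' 50-200. The defaults select those; direct-infusion runs use a 150 Th
#' window, so `min_iso_width = 100` accepts both.
#'
#' @param ms_level Required MS level.
#' @param min_iso_width Minimum isolation-window full width (Th).
#' @param hcd_range Accepted normalized HCD range (%).
#' @param mz_range Interval the scan's detection window must cover (Th);
#'   `NULL` to skip the check.
#' @param profile_only Drop centroid scans.
#' @param filter_regex Optional regex applied to a vendor filter string when
#'   one is attached to the spectrum (attribute `filter_string`).
#' @return List with class `scan_criteria`.
#' @export
scan_criteria <- function(ms_level = 2L, min_iso_width = 100,
                          hcd_range = c(30, 100), mz_range = c(50, 200),
                          profile_only = TRUE, filter_regex = NULL) {
  if (min_iso_width < 0) stop("min_iso_width must be >= 0")
  if (!is.null(mz_range) && diff(mz_range) <= 0) stop("mz_range must be increasing")
  structure(list(ms_level = as.integer(ms_level), min_iso_width = min_iso_width,
                 hcd_range = hcd_range, mz_range = mz_range,
                 profile_only = isTRUE(profile_only), filter_regex = filter_regex),
            class = "scan_criteria")
}

#' Select isoMS scans from a run
#'
#' Metadata-driven filter: MS level, isolation width, HCD energy, detection
#' range and profile mode. Order-preserving and idempotent; an empty result
#' is legal. Kept/dropped counts per criterion are attached as attribute
#' `selection_counts`.
#'
#' @param run List of [profile_spectrum()] objects (e.g. from [read_run()]).
#' @param criteria A [scan_criteria()].
#' @return Filtered list with attribute `selection_counts`.
#' @export
select_isoms_scans <- function(run, criteria = scan_criteria()) {
  if (length(run) == 0) {
    return(structure(run, selection_counts = c(total = 0L, kept = 0L)))
  }
  get_num <- function(field) vapply(run, function(s) as.numeric(s[[field]] %||% NA), numeric(1))
  ms <- get_num("ms_level")
  width <- get_num("iso_width")
  hcd <- get_num("hcd")
  cent <- vapply(run, function(s) isTRUE(s$centroided), logical(1))

  ok_ms <- !is.na(ms) & ms == criteria$ms_level
  ok_width <- if (criteria$min_iso_width > 0) !is.na(width) & width >= criteria$min_iso_width else rep(TRUE, length(run))
  ok_hcd <- if (!is.null(criteria$hcd_range)) !is.na(hcd) & hcd >= criteria$hcd_range[1] & hcd <= criteria$hcd_range[2] else rep(TRUE, length(run))
  ok_prof <- if (criteria$profile_only) !cent else rep(TRUE, length(run))
  ok_range <- rep(TRUE, length(run))
  if (!is.null(criteria$mz_range)) {
    ok_range <- vapply(run, function(s) {
      win <- s$scan_window
      if (any(is.na(win))) win <- range(s$mz)
      win[1] <= criteria$mz_range[1] && win[2] >= criteria$mz_range[2]
    }, logical(1))
  }
  ok_filter <- rep(TRUE, length(run))
  if (!is.null(criteria$filter_regex)) {
    ok_filter <- vapply(run, function(s) {
      fs <- attr(s, "filter_string")
      !is.null(fs) && grepl(criteria$filter_regex, fs)
    }, logical(1))
  }
  keep <- ok_ms & ok_width & ok_hcd & ok_prof & ok_range & ok_filter
  counts <- c(total = length(run), kept = sum(keep),
              dropped_ms_level = sum(!ok_ms), dropped_iso_width = sum(!ok_width),
              dropped_hcd = sum(!ok_hcd), dropped_centroid = sum(!ok_prof),
              dropped_mz_range = sum(!ok_range), dropped_filter = sum(!ok_filter))
  structure(run[keep], selection_counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
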