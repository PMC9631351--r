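# Fine-structure component fitting and per-spectrum isotope ratios.

#' Instrument model for peak lookup and fitting
#'
#' @param resolution Nominal resolving power R0 at `ref_mz` (FWHM
#'   definition). The acquisition this package targets uses 60,000 at
#'   m/z 200.
#' @param ref_mz Reference m/z of the resolution setting.
#' @param tol_ppm Mass tolerance for locating the monoisotopic apex.
#' @param kappa Resolvability factor: two components count as resolved when
#'   their spacing is at least `kappa` times the local FWHM.
#' @param peak_shape Peak-shape family; Gaussian only.
#' @return List with class `instrument_model`.
#' @export
instrument_model <- function(resolution = 60000, ref_mz = 200, tol_ppm = 5,
                             kappa = 1, peak_shape = "gaussian") {
  if (resolution <= 0 || tol_ppm <= 0 || kappa <= 0) {
    stop("resolution, tol_ppm and kappa must be positive")
  }
  peak_shape <- match.arg(peak_shape, "gaussian")
  structure(list(resolution = resolution, ref_mz = ref_mz, tol_ppm = tol_ppm,
                 kappa = kappa, peak_shape = peak_shape),
            class = "instrument_model")
}

.FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Resolving power and peak width at a given m/z
#'
#' FT analyzers of the Orbitrap type lose resolving power as sqrt(m/z):
#' R(mz) = R0 * sqrt(ref_mz / mz), so the full width at half maximum is
#' FWHM(mz) = mz / R(mz) = mz^1.5 / (R0 * sqrt(ref_mz)).
#'
#' @param mz m/z value(s), > 0.
#' @param instrument An [instrument_model()].
#' @return List with vectors `resolving_power` and `fwhm` (Da).
#' @export
#' @examples
#' resolution_fwhm(200, instrument_model())$fwhm  # 1/300 Da
resolution_fwhm <- function(mz, instrument = instrument_model()) {
  if (any(mz <= 0)) stop("mz must be positive")
  rp <- instrument$resolution * sqrt(instrument$ref_mz / mz)
  list(resolving_power = rp, fwhm = mz / rp)
}

#' Are two fine-structure lines resolved?
#'
#' @param mz_a,mz_b Line positions (Th).
#' @param instrument An [instrument_model()].
#' @return Logical: spacing at least `kappa * FWHM` at the midpoint.
#' @export
is_resolved <- function(mz_a, mz_b, instrument = instrument_model()) {
  mid <- (mz_a + mz_b) / 2
  abs(mz_b - mz_a) >= instrument$kappa * resolution_fwhm(mid, instrument)$fwhm
}

# quadratic-interpolated apex of a log-Gaussian through three points;
# exact for a noiseless Gaussian profile
.parabolic_apex <- function(x, y) {
  if (any(y <= 0)) return(x[2])
  l <- log(y)
  d21 <- x[2] - x[1]; d32 <- x[3] - x[2]
  num <- (l[1] - l[2]) * d32^2 - (l[3] - l[2]) * d21^2
  den <- (l[1] - l[2]) * d32 + (l[3] - l[2]) * d21
  if (den == 0) return(x[2])
  x[2] + 0.5 * num / den
}

# per-species extraction state reused across the scans of a run
.species_lines <- function(species, abundances, max_shell = NULL) {
  if (is.null(max_shell)) max_shell <- if (.n_atoms(species, "O") > 0) 2L else 1L
  lines <- isotopologue_distribution(species$composition, abundances,
                                     max_shell = max_shell)
  lines[lines$shell > 0, , drop = FALSE]
}

#' Extract fine-structure component areas from one spectrum
#'
#' Locates the species' monoisotopic apex within the lookup tolerance,
#' anchors all expected M+1/M+2 line positions on the *observed* centroid
#' (cancelling any calibration offset common to the multiplet), and
#' estimates component amplitudes by linear least squares of fixed-position,
#' fixed-width Gaussians with non-negative amplitudes (ordinary LS fast
#' path; non-negative LS when it goes negative). Reported areas are
#' amplitude x sigma x sqrt(2*pi); the `amp` column (peak height) is the
#' ion-count-proportional quantity ratios are built from.
#'
#' @param spectrum A profile-mode [profile_spectrum()].
#' @param species An [immonium_species()].
#' @param instrument An [instrument_model()].
#' @param abundances Prior [abundance_set()] (used only to decide which
#'   neighbours are abundant enough to threaten resolution, and which shells
#'   to fit — not to bias amplitudes).
#' @param max_shell 1 or 2; default 2 for oxygen-bearing species, 1
#'   otherwise.
#' @param mz_offset_ppm Run-level calibration offset applied to the lookup
#'   position (see [extract_run()]).
#' @return Tibble of component measurements (`label`, `shell`,
#'   `expected_mz`, `fitted_mz`, `amp`, `area`, `area_se`, `found`,
#'   `below_noise`, `unresolved`) plus the monoisotopic row `"M"`; attribute
#'   `mass_error_ppm` carries the apex mass error. When the monoisotopic
#'   peak is not found an empty tibble is returned with attribute `reason`.
#' @export
extract_fine_components <- function(spectrum, species,
                                    instrument = instrument_model(),
                                    abundances = natural_abundances(),
                                    max_shell = NULL, mz_offset_ppm = 0) {
  if (isTRUE(spectrum$centroided)) {
    stop("spectrum is centroided; fine-structure fitting needs profile mode")
  }
  lines <- .species_lines(species, abundances, max_shell)
  .extract_components_fast(spectrum$mz, spectrum$intensity, species, lines,
                           instrument, mz_offset_ppm)
}

# core fitting routine on bare vectors (hot path)
.extract_components_fast <- function(x, y, species, lines, instrument,
                                     mz_offset_ppm = 0) {
  empty <- function(reason) {
    structure(tibble::tibble(
      species = character(), label = character(), shell = integer(),
      expected_mz = numeric(), fitted_mz = numeric(), amp = numeric(),
      area = numeric(), area_se = numeric(), found = logical(),
      below_noise = logical(), unresolved = logical()
    ), reason = reason, mass_error_ppm = NA_real_)
  }
  mz0 <- species$mz * (1 + mz_offset_ppm * 1e-6)
  fw0 <- resolution_fwhm(mz0, instrument)$fwhm
  tol <- instrument$tol_ppm * 1e-6 * mz0
  i1 <- findInterval(mz0 - tol - fw0, x) + 1L
  i2 <- findInterval(mz0 + tol + fw0, x)
  if (i2 - i1 + 1L < 5L) return(empty("not_found: no profile data at species m/z"))
  seg <- i1:i2
  ia <- seg[which.max(y[seg])]
  if (y[ia] <= 0) return(empty("not_found: no signal at species m/z"))
  apex <- if (ia > 1L && ia < length(x)) {
    .parabolic_apex(x[(ia - 1L):(ia + 1L)], y[(ia - 1L):(ia + 1L)])
  } else x[ia]
  if (abs(apex - mz0) > tol) {
    return(empty(sprintf("not_found: apex %.4f outside %.1f ppm of %.4f",
                         apex, instrument$tol_ppm, mz0)))
  }
  mass_error_ppm <- (apex - species$mz) / species$mz * 1e6

  shells <- split(lines, lines$shell)
  nl <- nrow(lines)
  out_label <- c("M", lines$label)
  out_shell <- c(0L, lines$shell)
  out_expected <- c(species$mz, species$mz + lines$dm)
  out_mu <- c(apex, apex + lines$dm)
  out_amp <- numeric(nl + 1L)
  out_se <- numeric(nl + 1L)
  out_sigma <- numeric(nl + 1L)
  out_found <- logical(nl + 1L)

  fit_window <- function(mus, sigmas) {
    lo <- findInterval(min(mus) - 4.5 * max(sigmas) * 2.3548, x) + 1L
    hi <- findInterval(max(mus) + 4.5 * max(sigmas) * 2.3548, x)
    if (hi - lo + 1L < length(mus) + 2L) return(NULL)
    xs <- x[lo:hi]; ys <- y[lo:hi]
    A <- vapply(seq_along(mus), function(j) {
      exp(-0.5 * ((xs - mus[j]) / sigmas[j])^2)
    }, numeric(length(xs)))
    AtA <- crossprod(A)
    beta <- tryCatch(as.numeric(solve(AtA, crossprod(A, ys))),
                     error = function(e) rep(-1, length(mus)))
    if (any(beta < 0)) {
      beta <- pracma::lsqnonneg(A, ys)$x
    }
    resid <- ys - as.numeric(A %*% beta)
    s2 <- sum(resid^2) / max(1L, length(ys) - length(mus))
    se <- tryCatch(sqrt(pmax(0, diag(solve(AtA))) * s2),
                   error = function(e) rep(NA_real_, length(mus)))
    list(beta = beta, se = se)
  }

  # monoisotopic peak
  sig0 <- fw0 * .FWHM_TO_SIGMA
  fitM <- fit_window(apex, sig0)
  if (is.null(fitM) || fitM$beta[1] <= 0) {
    return(empty("not_found: monoisotopic fit failed"))
  }
  out_amp[1] <- fitM$beta[1]; out_se[1] <- fitM$se[1]
  out_sigma[1] <- sig0; out_found[1] <- TRUE

  for (sh in shells) {
    idx <- match(sh$label, out_label)
    mus <- out_mu[idx]
    sigmas <- resolution_fwhm(mus, instrument)$fwhm * .FWHM_TO_SIGMA
    fit <- fit_window(mus, sigmas)
    if (is.null(fit)) next
    out_amp[idx] <- fit$beta
    out_se[idx] <- fit$se
    out_sigma[idx] <- sigmas
    out_found[idx] <- TRUE
  }

  # resolvability: a component is unresolved when a neighbour expected to
  # contaminate it by at least 1% of its own abundance sits closer than
  # kappa * FWHM (sub-percent neighbours are fit nuisances, not threats)
  prior <- c(1, lines$ratio)
  unresolved <- logical(nl + 1L)
  for (s in unique(out_shell)) {
    idx <- which(out_shell == s)
    if (length(idx) < 2) next
    for (i in idx) {
      others <- setdiff(idx, i)
      sig_nb <- others[prior[others] >= 0.01 * prior[i]]
      if (length(sig_nb) == 0) next
      dmin <- min(abs(out_mu[sig_nb] - out_mu[i]))
      fw <- resolution_fwhm(out_mu[i], instrument)$fwhm
      unresolved[i] <- dmin < instrument$kappa * fw
    }
  }

  area <- out_amp * out_sigma * sqrt(2 * pi)
  structure(tibble::tibble(
    species = species$name, label = out_label, shell = out_shell,
    expected_mz = out_expected, fitted_mz = out_mu, amp = out_amp,
    area = area, area_se = out_se * out_sigma * sqrt(2 * pi),
    found = out_found,
    below_noise = !out_found | out_amp <= 3 * ifelse(is.na(out_se), 0, out_se),
    unresolved = unresolved
  ), mass_error_ppm = mass_error_ppm, reason = NULL)
}

#' Per-spectrum isotope ratios for one species
#'
#' The estimator: each heavy-isotope ratio is the fine-structure component
#' amplitude relative to the monoisotopic amplitude, divided by the number
#' of substitution sites —
#' r_C = A(M+1, 13C) / A(M) / n_C, r_H(raw) = A(M+1, 2H) / A(M) / n_H,
#' r_N = A(M+1, 15N) / A(M) / n_N, and for oxygen-bearing species
#' r_O = A(M+2, 18O) / A(M) / n_O. Components that were not found, fell
#' below the noise floor, or are unresolved from a significant neighbour
#' yield absent (NA) ratios. The raw hydrogen ratio averages over all
#' hydrogens; see [correct_exchangeable_h()] for the solvent correction.
#'
#' @inheritParams extract_fine_components
#' @return One-row tibble (a ratio record): `scan`, `rt`, `tic`, `species`,
#'   `area_M`, `r_C`, `r_H_raw`, `r_N`, `r_O`, `mass_error_ppm`, `qc_pass`,
#'   `flags`; or a zero-row tibble when the species was not found (the
#'   reason is in attribute `reason`).
#' @export
spectrum_ratios <- function(spectrum, species, instrument = instrument_model(),
                            abundances = natural_abundances(),
                            max_shell = NULL, mz_offset_ppm = 0) {
  comp <- extract_fine_components(spectrum, species, instrument, abundances,
                                  max_shell, mz_offset_ppm)
  rec <- .ratios_from_components(comp, species)
  if (is.null(rec)) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(.record_columns)), .record_columns))
    out$species <- character(0); out$qc_pass <- logical(0); out$flags <- character(0)
    return(structure(out, reason = attr(comp, "reason")))
  }
  tibble::as_tibble(c(list(scan = spectrum$scan, rt = spectrum$rt,
                           tic = spectrum$tic), rec))
}

# shared by spectrum_ratios() and the run-level loop; returns a plain list
.ratios_from_components <- function(comp, species) {
  if (nrow(comp) == 0) return(NULL)
  ampM <- comp$amp[comp$label == "M"]
  if (length(ampM) != 1 || ampM <= 0) return(NULL)
  one <- function(label, n) {
    i <- match(label, comp$label)
    if (is.na(i) || n == 0) return(list(r = NA_real_, flag = NA_character_))
    if (!comp$found[i]) return(list(r = NA_real_, flag = paste0(label, ":not_found")))
    if (comp$unresolved[i]) return(list(r = NA_real_, flag = paste0(label, ":unresolved")))
    if (comp$below_noise[i]) return(list(r = NA_real_, flag = paste0(label, ":below_noise")))
    list(r = comp$amp[i] / ampM / n, flag = NA_character_)
  }
  rC <- one("M1_13C", .n_atoms(species, "C"))
  rH <- one("M1_2H", species$h_total)
  rN <- one("M1_15N", .n_atoms(species, "N"))
  rO <- one("M2_18O", .n_atoms(species, "O"))
  flags <- stats::na.omit(c(rC$flag, rH$flag, rN$flag, rO$flag))
  list(species = species$name, area_M = comp$area[comp$label == "M"],
       r_C = rC$r, r_H_raw = rH$r, r_N = rN$r, r_O = rO$r,
       mass_error_ppm = attr(comp, "mass_error_ppm"),
       qc_pass = TRUE,
       flags = if (length(flags)) paste(flags, collapse = ";") else "")
}

#' Extract ratio records from a whole run
#'
#' Applies scan selection, an optional run-level mass recalibration pass
#' (median apex mass error across scans, reapplied as a constant ppm offset
#' to the lookup positions), and per-scan fine-structure extraction for each
#' registry species.
#'
#' @param run List of [profile_spectrum()] (an `ms_run` or `sim_run$spectra`).
#' @param registry Named list of [immonium_species()].
#' @param instrument An [instrument_model()].
#' @param criteria A [scan_criteria()] applied first, or `NULL` to take every
#'   scan.
#' @param recalibrate Logical; run the calibration pass.
#' @param abundances Prior abundance set (see [extract_fine_components()]).
#' @return Tibble of ratio records, one row per (scan, species) in which the
#'   species was found; attribute `skipped` counts not-found (scan, species)
#'   pairs, attribute `mz_offset_ppm` records the calibration offset used.
#' @export
extract_run <- function(run, registry = immonium_registry(),
                        instrument = instrument_model(),
                        criteria = scan_criteria(), recalibrate = TRUE,
                        abundances = natural_abundances()) {
  if (inherits(run, "sim_run")) run <- run$spectra
  if (!is.null(criteria)) run <- select_isoms_scans(run, criteria)
  line_sets <- lapply(registry, .species_lines, abundances = abundances)

  offset <- 0
  if (recalibrate && length(run) > 0) {
    errs <- unlist(lapply(run, function(s) {
      vapply(registry, function(sp) {
        .apex_error_ppm(s$mz, s$intensity, sp$mz, instrument)
      }, numeric(1))
    }))
    errs <- errs[is.finite(errs)]
    if (length(errs) >= 5) offset <- stats::median(errs)
  }

  recs <- vector("list", length(run) * length(registry))
  k <- 0L; skipped <- 0L
  for (s in run) {
    if (isTRUE(s$centroided)) { skipped <- skipped + length(registry); next }
    for (j in seq_along(registry)) {
      comp <- .extract_components_fast(s$mz, s$intensity, registry[[j]],
                                       line_sets[[j]], instrument, offset)
      r <- .ratios_from_components(comp, registry[[j]])
      if (is.null(r)) { skipped <- skipped + 1L; next }
      k <- k + 1L
      recs[[k]] <- c(list(scan = s$scan, rt = s$rt, tic = s$tic), r)
    }
  }
  out <- if (k == 0L) {
    tibble::tibble(scan = integer(), rt = numeric(), tic = numeric(),
                   species = character(), area_M = numeric(), r_C = numeric(),
                   r_H_raw = numeric(), r_N = numeric(), r_O = numeric(),
                   mass_error_ppm = numeric(), qc_pass = logical(),
                   flags = character())
  } else {
    cols <- names(recs[[1]])
    tibble::as_tibble(lapply(stats::setNames(cols, cols), function(cn) {
      unlist(lapply(recs[seq_len(k)], `[[`, cn), use.names = FALSE)
    }))
  }
  structure(out[, .record_columns], skipped = skipped, mz_offset_ppm = offset)
}

# cheap apex lookup for the calibration pass (wider tolerance, no fit)
.apex_error_ppm <- function(x, y, mz0, instrument, tol_ppm = 20) {
  tol <- tol_ppm * 1e-6 * mz0
  i1 <- findInterval(mz0 - tol, x) + 1L
  i2 <- findInterval(mz0 + tol, x)
  if (i2 - i1 + 1L < 3L) return(NA_real_)
  seg <- i1:i2
  ia <- seg[which.max(y[seg])]
  if (y[ia] <= 0 || ia <= 1L || ia >= length(x)) return(NA_real_)
  apex <- .parabolic_apex(x[(ia - 1L):(ia + 1L)], y[(ia - 1L):(ia + 1L)])
  (apex - mz0) / mz0 * 1e6
}
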