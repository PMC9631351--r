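# Forward model: render isoMS profile spectra with exact isotopic fine
# structure, AGC-conditioned shot noise and instrument effects.

#' Simulated-instrument settings
#'
#' Defaults mirror the acquisition the package targets: nominal resolution
#' 60,000 at m/z 200, AGC target 5e4 ions per fill, 20 microscans per
#' reported spectrum, detection over m/z 50-200.
#'
#' @param resolution,ref_mz Resolving power and its reference m/z.
#' @param agc_target Ions per fill (automatic gain control target).
#' @param microscans Microscans (transients) co-added per spectrum.
#' @param mz_range Detected m/z window.
#' @param cal_offset_ppm Constant mass-calibration offset.
#' @param jitter_ppm Per-scan calibration jitter SD.
#' @param baseline_sd Additive Gaussian baseline noise SD, in
#'   ion-equivalent intensity units of the microscan-averaged spectrum
#'   (one ion in one microscan renders with apex height 1).
#' @param grid_factor Profile grid spacing is FWHM / `grid_factor` at the
#'   start of each rendered window (8 gives 8 points per FWHM).
#' @return List with class `sim_instrument`.
#' @export
sim_instrument <- function(resolution = 60000, ref_mz = 200,
                           agc_target = 5e4, microscans = 20,
                           mz_range = c(50, 200), cal_offset_ppm = 1,
                           jitter_ppm = 0.2, baseline_sd = 0.1,
                           grid_factor = 8) {
  stopifnot(resolution > 0, agc_target > 0, microscans >= 1,
            diff(mz_range) > 0, baseline_sd >= 0, grid_factor >= 5)
  structure(list(resolution = resolution, ref_mz = ref_mz,
                 agc_target = agc_target, microscans = as.integer(microscans),
                 mz_range = mz_range, cal_offset_ppm = cal_offset_ppm,
                 jitter_ppm = jitter_ppm, baseline_sd = baseline_sd,
                 grid_factor = grid_factor),
            class = "sim_instrument")
}

#' @rdname sim_instrument
#' @param sim A `sim_instrument`.
#' @param tol_ppm,kappa Passed to [instrument_model()].
#' @export
as_instrument_model <- function(sim, tol_ppm = 5, kappa = 1) {
  instrument_model(resolution = sim$resolution, ref_mz = sim$ref_mz,
                   tol_ppm = tol_ppm, kappa = kappa)
}

#' Species entry of a simulated mixture
#'
#' Hydrogen is modelled as two pools: C-bonded sites at `r_H_cb` and
#' exchangeable sites (N-H, O-H, ionizing proton) pinned to the solvent at
#' `r_H_exch`; both default to the natural 2H/1H of `abundances`.
#'
#' @param species An [immonium_species()] or a registry name.
#' @param abundance Relative molar abundance in the mixture (> 0).
#' @param abundances [abundance_set()] for C, N, O (and default H).
#' @param r_H_cb,r_H_exch 2H/1H of the two hydrogen pools (dimensionless).
#' @return List with class `sim_species`.
#' @export
sim_species <- function(species, abundance = 1,
                        abundances = natural_abundances(),
                        r_H_cb = NULL, r_H_exch = NULL) {
  if (is.character(species)) {
    species <- immonium_registry(species, mz_range = NULL)[[species]]
  }
  if (abundance <= 0) stop("abundance must be > 0")
  structure(list(species = species, abundance = abundance,
                 abundances = abundances,
                 r_H_cb = r_H_cb %||% abundances$H,
                 r_H_exch = r_H_exch %||% abundances$H),
            class = "sim_species")
}

#' Effective hydrogen-pool abundances under a labelling scenario
#'
#' Deuterium incorporation from growth media is linear in the media 2H
#' level: the C-bonded pool sits at
#' `baseline_ppm + incorporation_frac * (media_ppm - control_ppm)` while the
#' exchangeable pool stays pinned to the solvent. Other elements are
#' unchanged.
#'
#' @param spec A [sim_species()].
#' @param media_ppm Growth-media 2H/1H in ppm.
#' @param incorporation_frac Fraction of media deuterium incorporated into
#'   C-bonded positions, in [0, 1].
#' @param baseline_ppm C-bonded 2H/1H at the control media level (ppm).
#' @param control_ppm Control (natural) media level, ppm.
#' @param solvent_ppm Solvent 2H/1H pinning the exchangeable pool, ppm.
#' @return The updated `sim_species`.
#' @export
#' @examples
#' sp <- sim_species("Pro")
#' effective_abundances(sp, media_ppm = 1000, incorporation_frac = 0.04)$r_H_cb * 1e6
effective_abundances <- function(spec, media_ppm, incorporation_frac,
                                 baseline_ppm = 150, control_ppm = 150,
                                 solvent_ppm = 150) {
  if (incorporation_frac < 0 || incorporation_frac > 1) {
    stop("incorporation_frac must be in [0, 1]")
  }
  if (media_ppm < 0) stop("media_ppm must be >= 0")
  cb <- baseline_ppm + incorporation_frac * (media_ppm - control_ppm)
  if (cb <= 0) stop("effective C-bonded 2H/1H is not positive")
  spec$r_H_cb <- cb * 1e-6
  spec$r_H_exch <- solvent_ppm * 1e-6
  spec
}

# line table (shells <= 2, split hydrogen pools) for one mixture entry
.sim_line_table <- function(entry) {
  sp <- entry$species
  h_split <- if (sp$h_total > 0) {
    list(h_cb = sp$h_cb, h_exch = sp$h_exch,
         r_cb = entry$r_H_cb, r_exch = entry$r_H_exch)
  } else NULL
  lines <- isotopologue_distribution(sp$composition, entry$abundances,
                                     max_shell = 2L, h_split = h_split)
  lines$mz <- sp$mz + lines$dm
  lines
}

# rendering grid over merged species windows; returns list(mz, window id)
.sim_grid <- function(mzs, instrument) {
  lo <- pmax(mzs - 0.6, instrument$mz_range[1])
  hi <- pmin(mzs + 2.5, instrument$mz_range[2])
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  # merge overlapping windows
  mlo <- lo[1]; mhi <- hi[1]; outl <- c(); outh <- c()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= mhi) { mhi <- max(mhi, hi[i]) } else {
      outl <- c(outl, mlo); outh <- c(outh, mhi); mlo <- lo[i]; mhi <- hi[i]
    }
  }
  outl <- c(outl, mlo); outh <- c(outh, mhi)
  grids <- lapply(seq_along(outl), function(i) {
    dx <- resolution_fwhm(outl[i], as_instrument_model(instrument))$fwhm /
      instrument$grid_factor
    seq(outl[i], outh[i], by = dx)
  })
  unlist(grids, use.names = FALSE)
}

#' Simulate one isoMS profile spectrum
#'
#' Per reported spectrum the instrument accumulates `agc_target * fill` ions
#' in each of `microscans` fills; the total ion count is allocated
#' multinomially over (species, isotopologue line) cells — probabilities are
#' molar mixture fractions times exact isotopologue probabilities for shells
#' M..M+2, with the beyond-M+2 remainder kept as an unrendered bucket so
#' ledgered counts sum exactly to the drawn total. Each line is rendered as
#' a Gaussian whose FWHM follows the resolution model, centred at the line
#' m/z shifted by the calibration offset plus per-scan jitter, with apex
#' height of one intensity unit per ion per microscan; microscans are
#' averaged and Gaussian baseline noise is added (clamped at zero).
#'
#' @param mix A [sim_species()] or list of them.
#' @param instrument A [sim_instrument()].
#' @param seed Optional integer seed (same seed, same spectrum).
#' @param scan,rt Scan index and retention time metadata.
#' @param fill AGC fill fraction in (0, 1]; models intensity-limited fills.
#' @param line_tables,grid Precomputed isotopologue line tables and render
#'   grid; [simulate_run()] supplies these so they are built once per run.
#' @return List with class `sim_spectrum`: `spectrum`
#'   (a [profile_spectrum()]) and `truth` (tibble of per-line planted ion
#'   counts, including the unrendered remainder per species).
#' @export
simulate_spectrum <- function(mix, instrument = sim_instrument(), seed = NULL,
                              scan = 1L, rt = 0, fill = 1, line_tables = NULL,
                              grid = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(mix, "sim_species")) mix <- list(mix)
  fr <- vapply(mix, `[[`, numeric(1), "abundance")
  fr <- fr / sum(fr)
  mzs <- vapply(mix, function(e) e$species$mz, numeric(1))
  in_range <- mzs >= instrument$mz_range[1] & mzs <= instrument$mz_range[2]
  if (any(!in_range)) {
    warning("species outside simulated m/z range skipped: ",
            paste(vapply(mix[!in_range], function(e) e$species$name, character(1)),
                  collapse = ", "))
  }

  tabs <- line_tables %||% lapply(mix, .sim_line_table)
  cells <- dplyr::bind_rows(lapply(seq_along(mix), function(i) {
    t <- tabs[[i]]
    rem <- max(0, 1 - sum(t$prob))
    tibble::tibble(
      species = mix[[i]]$species$name,
      label = c(t$label, "beyond_M2"),
      mz = c(t$mz, NA_real_),
      prob = fr[i] * c(t$prob, rem),
      rendered = c(rep(in_range[i], nrow(t)), FALSE)
    )
  }))

  n_total <- round(instrument$agc_target * fill) * instrument$microscans
  counts <- as.integer(stats::rmultinom(1, n_total, cells$prob))
  cells$count <- counts

  x <- grid %||% .sim_grid(mzs[in_range], instrument)
  y <- numeric(length(x))
  scale <- 1 + (instrument$cal_offset_ppm +
                  stats::rnorm(1, 0, instrument$jitter_ppm)) * 1e-6
  imod <- as_instrument_model(instrument)
  live <- which(cells$rendered & cells$count > 0L)
  for (i in live) {
    mu <- cells$mz[i] * scale
    sig <- resolution_fwhm(mu, imod)$fwhm * .FWHM_TO_SIGMA
    amp <- cells$count[i] / instrument$microscans
    j1 <- findInterval(mu - 6 * sig, x) + 1L
    j2 <- findInterval(mu + 6 * sig, x)
    if (j2 >= j1) {
      idx <- j1:j2
      y[idx] <- y[idx] + amp * exp(-0.5 * ((x[idx] - mu) / sig)^2)
    }
  }
  if (instrument$baseline_sd > 0) {
    y <- pmax(0, y + stats::rnorm(length(y), 0, instrument$baseline_sd))
  }
  spec <- profile_spectrum(
    mz = x, intensity = y, scan = scan, rt = rt, ms_level = 2L, hcd = 50,
    iso_center = 800, iso_width = 1000, microscans = instrument$microscans,
    tic = sum(cells$count[cells$rendered]),
    resolution = instrument$resolution, scan_window = instrument$mz_range
  )
  cells$scan <- scan
  structure(list(spectrum = spec, truth = cells), class = "sim_spectrum")
}

#' Simulate a run of isoMS scans
#'
#' Direct-infusion mode keeps the mixture constant across scans; LC mode
#' modulates each species' molar abundance with a Gaussian elution profile
#' and scales the AGC fill with the total eluting intensity, so TIC varies
#' along the run. Scan metadata is populated so [select_isoms_scans()]
#' accepts every scan with default criteria.
#'
#' @param mix List of [sim_species()].
#' @param instrument A [sim_instrument()].
#' @param n_spectra Number of scans (>= 1).
#' @param seed Integer seed for the whole run.
#' @param mode `"infusion"` or `"lc"`.
#' @param rt_step Seconds between scans.
#' @param elution_center,elution_width LC mode: per-species Gaussian elution
#'   apex and SD (seconds); recycled to the number of species.
#' @param min_fill LC mode: floor of the AGC fill fraction.
#' @return List with class `sim_run`: `spectra` (list of profile spectra),
#'   `truth` (per scan x species x line planted counts), `planted`
#'   (per-species planted abundance ratios), `instrument`.
#' @export
simulate_run <- function(mix, instrument = sim_instrument(), n_spectra = 10L,
                         seed = NULL, mode = c("infusion", "lc"), rt_step = 1,
                         elution_center = NULL, elution_width = NULL,
                         min_fill = 0.2) {
  mode <- match.arg(mode)
  if (n_spectra < 1) stop("n_spectra must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(mix, "sim_species")) mix <- list(mix)
  ns <- length(mix)
  rts <- (seq_len(n_spectra) - 1) * rt_step
  if (mode == "lc") {
    # immonium signal in a digest comes from all co-eluting peptides, so the
    # default envelopes are broad and overlapping: the species mix is nearly
    # stable while the total current (AGC fill) rises and falls
    elution_center <- rep(elution_center %||% stats::quantile(rts, seq(0.4, 0.6, length.out = max(ns, 2))[seq_len(ns)]), length.out = ns)
    elution_width <- rep(elution_width %||% (diff(range(rts)) / 3 + rt_step), length.out = ns)
  }
  base_ab <- vapply(mix, `[[`, numeric(1), "abundance")
  tabs <- lapply(mix, .sim_line_table)
  mzs <- vapply(mix, function(e) e$species$mz, numeric(1))
  ok <- mzs >= instrument$mz_range[1] & mzs <= instrument$mz_range[2]
  grid <- .sim_grid(mzs[ok], instrument)
  spectra <- vector("list", n_spectra)
  truths <- vector("list", n_spectra)
  for (k in seq_len(n_spectra)) {
    mk <- mix; fill <- 1
    if (mode == "lc") {
      w <- base_ab * exp(-0.5 * ((rts[k] - elution_center) / elution_width)^2)
      if (sum(w) <= 0) w <- rep(1e-6, ns)
      for (i in seq_len(ns)) mk[[i]]$abundance <- max(w[i], 1e-9)
      fill <- max(min_fill, min(1, sum(w) / max(sum(base_ab), 1e-12)))
    }
    ss <- simulate_spectrum(mk, instrument, seed = NULL, scan = k,
                            rt = rts[k], fill = fill, line_tables = tabs,
                            grid = grid)
    spectra[[k]] <- ss$spectrum
    truths[[k]] <- ss$truth
  }
  planted <- tibble::tibble(
    species = vapply(mix, function(e) e$species$name, character(1)),
    abundance = base_ab,
    r_C = vapply(mix, function(e) e$abundances$C, numeric(1)),
    r_N = vapply(mix, function(e) e$abundances$N, numeric(1)),
    r_O = vapply(mix, function(e) e$abundances$O, numeric(1)),
    r_H_cb = vapply(mix, `[[`, numeric(1), "r_H_cb"),
    r_H_exch = vapply(mix, `[[`, numeric(1), "r_H_exch")
  )
  structure(list(spectra = spectra, truth = dplyr::bind_rows(truths),
                 planted = planted, instrument = instrument),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> %d scans, %d species (%s), AGC %g x %d microscans\n",
              length(x$spectra), nrow(x$planted),
              paste(x$planted$species, collapse = ", "),
              x$instrument$agc_target, x$instrument$microscans))
  invisible(x)
}
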