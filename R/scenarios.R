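# Simulation scenarios: named experiment designs built from runs of
# simulate_run(), and the driver that simulates + extracts them.

.scenario <- function(runs, mixes, n_spectra, mode, name) {
  stopifnot(nrow(runs) == length(mixes))
  structure(list(runs = runs, mixes = mixes, n_spectra = n_spectra,
                 mode = mode, name = name),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %s: %d runs x %d scans (%s mode)\n",
              x$name, nrow(x$runs), x$n_spectra, x$mode))
  invisible(x)
}

#' Direct-infusion free-amino-acid scenario
#'
#' Replicated single-species infusion runs (each amino acid injected on its
#' own, as in method validation with pure Pro, Hyp and Val) at natural
#' isotope abundances.
#'
#' @param species Character vector of registry species.
#' @param n_replicates Replicate runs per amino acid.
#' @param n_spectra Scans per run.
#' @param abundances Planted [abundance_set()].
#' @param solvent_ppm Solvent 2H/1H in ppm (pins the exchangeable pool).
#' @return A `sim_scenario`.
#' @export
scenario_direct_infusion <- function(species = c("Pro", "Hyp", "Val"),
                                     n_replicates = 3, n_spectra = 300,
                                     abundances = natural_abundances(),
                                     solvent_ppm = 150) {
  runs <- expand.grid(sample = species, replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  runs <- tibble::as_tibble(runs[order(runs$sample, runs$replicate), ])
  runs$group <- "direct_infusion"
  runs$media_ppm <- NA_real_
  runs$solvent_ppm <- solvent_ppm
  runs$run_id <- sprintf("DI_%s_r%d", gsub("/", "", runs$sample), runs$replicate)
  mixes <- lapply(runs$sample, function(sp) {
    list(sim_species(sp, abundances = abundances,
                     r_H_exch = solvent_ppm * 1e-6))
  })
  .scenario(runs, mixes, n_spectra, "infusion", "direct_infusion")
}

#' Deuterium-titration scenario
#'
#' Cell cultures grown in media spanning a range of deuterium levels
#' incorporate media 2H into C-bonded positions in proportion to the media
#' level; the two most abundant immonium ions of a lysate digest (Leu/Ile
#' and Pro) are simulated with species-specific incorporation fractions.
#'
#' @param media_ppm Media 2H levels in ppm (default 10 levels, 150-1000).
#' @param n_replicates Replicate runs per level.
#' @param n_spectra Scans per run.
#' @param incorporation Named vector of incorporation fractions per species.
#' @param mix_fractions Named relative molar abundances.
#' @param control_ppm,solvent_ppm Control media level and solvent 2H (ppm).
#' @param abundances Baseline [abundance_set()].
#' @return A `sim_scenario`; `runs$media_ppm` carries the level and the
#'   planted per-species slopes are in attribute `planted_incorporation`.
#' @export
scenario_titration <- function(media_ppm = round(seq(150, 1000, length.out = 10)),
                               n_replicates = 3, n_spectra = 300,
                               incorporation = c("Leu/Ile" = 0.04, "Pro" = 0.15),
                               mix_fractions = c("Leu/Ile" = 0.6, "Pro" = 0.4),
                               control_ppm = 150, solvent_ppm = 150,
                               abundances = natural_abundances()) {
  stopifnot(setequal(names(incorporation), names(mix_fractions)))
  runs <- expand.grid(media_ppm = media_ppm, replicate = seq_len(n_replicates))
  runs <- tibble::as_tibble(runs[order(runs$media_ppm, runs$replicate), ])
  runs$sample <- sprintf("media_%dppm", round(runs$media_ppm))
  runs$group <- "titration"
  runs$solvent_ppm <- solvent_ppm
  runs$run_id <- sprintf("TI_%04d_r%d", round(runs$media_ppm), runs$replicate)
  mixes <- lapply(runs$media_ppm, function(m) {
    lapply(names(incorporation), function(sp) {
      effective_abundances(
        sim_species(sp, abundance = mix_fractions[[sp]], abundances = abundances),
        media_ppm = m, incorporation_frac = incorporation[[sp]],
        baseline_ppm = control_ppm, control_ppm = control_ppm,
        solvent_ppm = solvent_ppm)
    })
  })
  structure(.scenario(runs, mixes, n_spectra, "lc", "titration"),
            planted_incorporation = incorporation)
}

#' Isotopically depleted biomass scenario
#'
#' Growth on depleted substrates: carbon at 1/20 and nitrogen at 1/10 of
#' the natural heavy-isotope ratio, C-bonded hydrogen at 80 ppm.
#'
#' @param species Registry species to simulate.
#' @param n_replicates,n_spectra Runs and scans per run.
#' @param depletion_C,depletion_N Division factors for r_C and r_N.
#' @param r_H_cb_ppm C-bonded 2H/1H in ppm.
#' @param solvent_ppm Solvent 2H (the solvent is not depleted).
#' @return A `sim_scenario`.
#' @export
scenario_depletion <- function(species = c("Leu/Ile", "Pro"),
                               n_replicates = 3, n_spectra = 300,
                               depletion_C = 20, depletion_N = 10,
                               r_H_cb_ppm = 80, solvent_ppm = 150) {
  nat <- natural_abundances()
  ab <- abundance_set(r_C = nat$C / depletion_C, r_H = nat$H,
                      r_N = nat$N / depletion_N, r_O = nat$O)
  runs <- tibble::tibble(replicate = seq_len(n_replicates))
  runs$sample <- "depleted_lysate"
  runs$group <- "depletion"
  runs$media_ppm <- NA_real_
  runs$solvent_ppm <- solvent_ppm
  runs$run_id <- sprintf("DE_r%d", runs$replicate)
  mixes <- lapply(seq_len(n_replicates), function(i) {
    lapply(species, function(sp) {
      sim_species(sp, abundances = ab, r_H_cb = r_H_cb_ppm * 1e-6,
                  r_H_exch = solvent_ppm * 1e-6)
    })
  })
  .scenario(runs, mixes, n_spectra, "lc", "depletion")
}

#' Simulate a scenario and extract its ratio records
#'
#' Runs every run of the scenario in sequence (simulate, optionally write
#' mzML, extract, discard the spectra), so memory stays bounded by one run.
#' Per-run seeds are drawn reproducibly from `seed`.
#'
#' @param scenario A `sim_scenario`.
#' @param instrument A [sim_instrument()].
#' @param seed Integer master seed.
#' @param registry Species registry used for extraction (defaults to the
#'   species the scenario simulates).
#' @param write_dir Optional directory: each run is written as
#'   `<run_id>.mzML` and re-read before extraction, exercising the mzML
#'   path end to end.
#' @param tol_ppm,kappa Extraction settings (see [as_instrument_model()]).
#' @return List with class `scenario_result`: `records` (ratio records
#'   annotated with run metadata columns), `planted` (per-run planted
#'   truth), `scenario`, `seed`.
#' @export
run_scenario <- function(scenario, instrument = sim_instrument(), seed = 1,
                         registry = NULL, write_dir = NULL,
                         tol_ppm = 5, kappa = 1) {
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, nrow(scenario$runs))
  imod <- as_instrument_model(instrument, tol_ppm = tol_ppm, kappa = kappa)
  if (is.null(registry)) {
    sp_names <- unique(unlist(lapply(scenario$mixes, function(m) {
      vapply(m, function(e) e$species$name, character(1))
    })))
    registry <- immonium_registry(sp_names, mz_range = instrument$mz_range)
  }
  rec_list <- vector("list", nrow(scenario$runs))
  planted_list <- vector("list", nrow(scenario$runs))
  for (i in seq_len(nrow(scenario$runs))) {
    run <- simulate_run(scenario$mixes[[i]], instrument,
                        n_spectra = scenario$n_spectra, seed = run_seeds[i],
                        mode = scenario$mode)
    if (!is.null(write_dir)) {
      path <- file.path(write_dir, paste0(scenario$runs$run_id[i], ".mzML"))
      write_mzml(run, path)
      spectra <- read_run(path)
    } else {
      spectra <- run$spectra
    }
    rec <- extract_run(spectra, registry, imod)
    meta <- scenario$runs[i, ]
    for (cn in names(meta)) rec[[cn]] <- meta[[cn]]
    rec_list[[i]] <- rec
    pl <- run$planted
    pl$run_id <- scenario$runs$run_id[i]
    planted_list[[i]] <- pl
    rm(run, spectra)
  }
  structure(list(records = dplyr::bind_rows(rec_list),
                 planted = dplyr::bind_rows(planted_list),
                 scenario = scenario, seed = seed),
            class = "scenario_result")
}
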