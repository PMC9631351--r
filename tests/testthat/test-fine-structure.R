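# Resolution model, resolvability, component fitting and ratio recovery
# against the simulator's planted truth.

test_that("resolution model follows R0 * sqrt(ref/mz) scaling", {
  inst <- instrument_model(resolution = 60000)
  expect_equal(resolution_fwhm(200, inst)$fwhm, 200 / 60000)
  r70 <- resolution_fwhm(70.0656, inst)
  expect_equal(r70$resolving_power, 60000 * sqrt(200 / 70.0656))
  expect_equal(r70$fwhm, 70.0656^1.5 / (60000 * sqrt(200)), tolerance = 1e-12)
  expect_equal(r70$fwhm, 6.9118e-4, tolerance = 1e-4)
  expect_equal(resolution_fwhm(86.0606, inst)$fwhm, 9.409e-4, tolerance = 1e-4)
  expect_error(resolution_fwhm(0, inst), "positive")
})

test_that("resolvability criterion separates fine-structure neighbours", {
  inst <- instrument_model(resolution = 60000)
  # 15N vs 13C and 13C vs 2H at m/z ~71 are resolved at R0 = 60k
  expect_true(is_resolved(71.0627, 71.0690, inst))
  expect_true(is_resolved(71.0690, 71.0720, inst))
  expect_false(is_resolved(71.069, 71.069, inst))
  # at R0 = 7,500 the M+1 multiplet merges
  low <- instrument_model(resolution = 7500)
  expect_false(is_resolved(71.0690, 71.0720, low))
})

test_that("noiseless rendered spectra are recovered at oracle precision", {
  reg <- suppressMessages(immonium_registry(c("Pro", "Hyp")))
  inst <- noiseless_instrument()
  imod <- as_instrument_model(inst)
  for (name in names(reg)) {
    ss <- simulate_spectrum(sim_species(name), inst, seed = 42)
    truth <- ss$truth
    comp <- extract_fine_components(ss$spectrum, reg[[name]], imod)
    ampM <- comp$amp[comp$label == "M"]
    for (lab in c("M1_15N", "M1_13C", "M1_2H", "M2_18O")) {
      i <- match(lab, comp$label)
      if (is.na(i)) next
      planted <- truth$count[truth$label == lab] / truth$count[truth$label == "M"]
      got <- comp$amp[i] / ampM
      expect_lt(abs(got / planted - 1), 1e-3)
    }
    rec <- spectrum_ratios(ss$spectrum, reg[[name]], imod)
    expect_equal(nrow(rec), 1)
    expect_equal(rec$flags, "")
  }
})

test_that("planted abundance ratios are recovered within shot-noise bounds", {
  # natural abundances planted; binomial SE oracle at two ion loads
  reg <- suppressMessages(immonium_registry("Pro"))
  ab <- natural_abundances()
  for (N in c(1e5, 1e6)) {
    inst <- sim_instrument(agc_target = N, microscans = 1, cal_offset_ppm = 0,
                           jitter_ppm = 0, baseline_sd = 0)
    set.seed(as.integer(N %% 1e5 + 11))
    rs <- vapply(1:30, function(i) {
      ss <- simulate_spectrum(sim_species("Pro", abundances = ab), inst)
      spectrum_ratios(ss$spectrum, reg$Pro, as_instrument_model(inst))$r_C
    }, numeric(1))
    n_M <- N * 0.9525
    se_pred <- sqrt(1 / (4 * ab$C * n_M))  # relative SE of r_C
    expect_lt(abs(mean(rs) / ab$C - 1), 4 * se_pred / sqrt(30))
    emp_rel_sd <- stats::sd(rs) / mean(rs)
    expect_gt(emp_rel_sd / se_pred, 0.5)
    expect_lt(emp_rel_sd / se_pred, 2)
  }
})

test_that("oxygen handling: r_O present for Hyp, absent for Pro", {
  reg <- suppressMessages(immonium_registry(c("Pro", "Hyp")))
  inst <- noiseless_instrument()
  ss <- simulate_spectrum(sim_species("Hyp"), inst, seed = 4)
  rec <- spectrum_ratios(ss$spectrum, reg$Hyp, as_instrument_model(inst))
  expect_equal(rec$r_O,
               ss$truth$count[ss$truth$label == "M2_18O"] /
                 ss$truth$count[ss$truth$label == "M"],
               tolerance = 1e-3)
  ssp <- simulate_spectrum(sim_species("Pro"), inst, seed = 4)
  recp <- spectrum_ratios(ssp$spectrum, reg$Pro, as_instrument_model(inst))
  expect_true(is.na(recp$r_O))
})

test_that("a blank spectrum yields an empty result with a reason", {
  reg <- suppressMessages(immonium_registry(c("Pro", "Val")))
  inst <- noiseless_instrument(agc = 1e5)
  ss <- simulate_spectrum(sim_species("Val"), inst, seed = 8)
  comp <- extract_fine_components(ss$spectrum, reg$Pro, as_instrument_model(inst))
  expect_equal(nrow(comp), 0)
  expect_match(attr(comp, "reason"), "not_found")
  rec <- spectrum_ratios(ss$spectrum, reg$Pro, as_instrument_model(inst))
  expect_equal(nrow(rec), 0)
  # centroid spectra are refused
  cent <- profile_spectrum(mz = c(70.0656, 71.069), intensity = c(100, 4),
                           centroided = TRUE)
  expect_error(extract_fine_components(cent, reg$Pro), "centroid")
})

test_that("merged fine structure at low resolution is flagged unresolved", {
  # at R0 = 6,000 the FWHM at m/z 71 (7.1e-3 Da) exceeds even the widest
  # M+1 spacing (15N-13C, 6.3e-3 Da): the whole multiplet is merged
  reg <- suppressMessages(immonium_registry("Pro"))
  inst <- noiseless_instrument(agc = 1e6, resolution = 6000)
  ss <- simulate_spectrum(sim_species("Pro"), inst, seed = 12)
  imod <- as_instrument_model(inst)
  comp <- extract_fine_components(ss$spectrum, reg$Pro, imod)
  m1 <- comp[comp$shell == 1, ]
  expect_true(all(m1$unresolved))
  rec <- spectrum_ratios(ss$spectrum, reg$Pro, imod)
  expect_true(is.na(rec$r_C) && is.na(rec$r_N))
  expect_match(rec$flags, "unresolved")
})

test_that("a constant calibration shift cancels through apex anchoring", {
  reg <- suppressMessages(immonium_registry("Pro"))
  base <- noiseless_instrument()
  shifted <- sim_instrument(agc_target = 1e7, microscans = 1,
                            cal_offset_ppm = 5, jitter_ppm = 0, baseline_sd = 0)
  r0 <- spectrum_ratios(simulate_spectrum(sim_species("Pro"), base, seed = 77)$spectrum,
                        reg$Pro, as_instrument_model(base))
  # lookup tolerance widened to reach the shifted apex; anchoring on the
  # observed centroid then cancels the common-mode offset
  r5 <- spectrum_ratios(simulate_spectrum(sim_species("Pro"), shifted, seed = 77)$spectrum,
                        reg$Pro, as_instrument_model(shifted, tol_ppm = 10))
  expect_lt(abs(r5$r_C / r0$r_C - 1), 5e-4)
  expect_lt(abs(r5$r_N / r0$r_N - 1), 5e-4)
  expect_lt(abs(r5$r_H_raw / r0$r_H_raw - 1), 5e-4)
  expect_equal(r5$mass_error_ppm, 5, tolerance = 0.1)
})

test_that("run-level extraction recalibrates and annotates skips", {
  reg <- suppressMessages(immonium_registry("Pro"))
  inst <- sim_instrument(agc_target = 1e4, cal_offset_ppm = 4, jitter_ppm = 0.2)
  run <- simulate_run(sim_species("Pro"), inst, n_spectra = 8, seed = 21)
  rec <- extract_run(run, reg, as_instrument_model(inst))
  expect_equal(nrow(rec), 8)
  expect_equal(attr(rec, "mz_offset_ppm"), 4, tolerance = 0.5)
  # without recalibration a 4 ppm offset still sits inside the 5 ppm gate,
  # but the recorded mass errors must expose it
  expect_equal(mean(rec$mass_error_ppm), 4, tolerance = 0.5)
})
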