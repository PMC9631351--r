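# mzML round-trips, scan selection, CSV schemas.

make_mixed_run <- function() {
  inst <- noiseless_instrument(agc = 1e5)
  iso <- simulate_run(sim_species("Pro"), inst, n_spectra = 5, seed = 3)$spectra
  cid <- lapply(6:10, function(i) {
    profile_spectrum(mz = seq(400, 401, 0.01), intensity = rep(1, 101),
                     scan = i, rt = i, ms_level = 2L, hcd = 35,
                     iso_center = 500, iso_width = 2, scan_window = c(50, 200))
  })
  ms1 <- list(profile_spectrum(mz = seq(400, 401, 0.01), intensity = rep(1, 101),
                               scan = 11L, rt = 11, ms_level = 1L,
                               scan_window = c(50, 250)))
  c(iso, cid, ms1)
}

test_that("mzML write-then-read preserves spectra and metadata", {
  run <- simulate_run(sim_species("Pro"), noiseless_instrument(agc = 1e5),
                      n_spectra = 3, seed = 5)
  tf <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, tf)
  back <- read_run(tf)
  expect_length(back, 3)
  for (i in 1:3) {
    a <- run$spectra[[i]]; b <- back[[i]]
    expect_equal(b$mz, a$mz, tolerance = 1e-12)
    expect_equal(b$intensity, a$intensity, tolerance = 1e-12)
    expect_identical(b$ms_level, a$ms_level)
    expect_equal(b$rt, a$rt)
    expect_equal(b$hcd, a$hcd)
    expect_equal(b$iso_width, a$iso_width)
    expect_equal(b$tic, a$tic, tolerance = 1e-9)
    expect_false(b$centroided)
    # microscan count has no mzML slot: absent, not silently defaulted
    expect_true(is.na(b$microscans))
  }
  # MS levels of a mixed run survive
  tf2 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(make_mixed_run(), tf2)
  lv <- vapply(read_run(tf2), `[[`, integer(1), "ms_level")
  expect_equal(sort(unique(lv)), c(1L, 2L))
})

test_that("empty runs and missing files are handled", {
  tf <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(list(), tf)
  expect_length(read_run(tf), 0)
  expect_error(read_run(file.path(tempdir(), "nope.mzML")), "no such file")
})

test_that("isoMS scan selection is metadata-driven, order-preserving and idempotent", {
  run <- make_mixed_run()
  sel <- select_isoms_scans(run, scan_criteria())
  expect_length(sel, 5)
  expect_equal(vapply(sel, `[[`, numeric(1), "iso_width"), rep(1000, 5))
  counts <- attr(sel, "selection_counts")
  expect_equal(unname(counts["kept"]), 5L)
  # per-criterion counts are not exclusive: the MS1 scan also lacks a wide
  # isolation window
  expect_equal(unname(counts["dropped_iso_width"]), 6L)
  expect_equal(unname(counts["dropped_ms_level"]), 1L)
  # order preserved
  expect_equal(vapply(sel, `[[`, numeric(1), "rt"),
               sort(vapply(sel, `[[`, numeric(1), "rt")))
  # idempotent
  sel2 <- select_isoms_scans(sel, scan_criteria())
  expect_equal(lapply(sel2, `[[`, "scan"), lapply(sel, `[[`, "scan"))
  # open criteria = identity filter on MS2 profile scans
  open <- scan_criteria(min_iso_width = 0, hcd_range = NULL, mz_range = NULL)
  expect_length(select_isoms_scans(run, open), 10)
  # direct-infusion criteria (150 Th isolation) accept the targeted scans
  di <- profile_spectrum(mz = seq(69, 73, 0.001), intensity = rep(1, 4001),
                         ms_level = 2L, hcd = 50, iso_center = 125,
                         iso_width = 150, scan_window = c(50, 200))
  expect_length(select_isoms_scans(list(di), scan_criteria(min_iso_width = 100)), 1)
  # empty input is legal
  expect_length(select_isoms_scans(list(), scan_criteria()), 0)
})

test_that("ratio-record CSVs round-trip losslessly and check their schema", {
  run <- simulate_run(sim_species("Pro"), sim_instrument(agc_target = 1e4),
                      n_spectra = 4, seed = 9)
  rec <- extract_run(run, suppressMessages(immonium_registry("Pro")))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(rec, tf)
  back <- read_records_csv(tf)
  expect_identical(back$r_C, rec$r_C)
  expect_identical(back$r_H_raw, rec$r_H_raw)
  expect_identical(back$area_M, rec$area_M)
  expect_identical(back$species, rec$species)
  # empty set -> header-only file
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(rec[0, ], tf2)
  expect_equal(nrow(read_records_csv(tf2)), 0)
  expect_equal(length(readLines(tf2)), 1)
  # unknown extra columns are preserved opaquely
  rec$extra_note <- "x"
  write_records_csv(rec, tf)
  expect_equal(read_records_csv(tf)$extra_note, rec$extra_note)
  # schema violations are named
  readr::write_csv(rec[, setdiff(names(rec), c("r_C", "tic"))], tf2)
  expect_error(read_records_csv(tf2), "r_C")
  expect_error(write_records_csv(rec[, 1:3], tf2), "missing column")
})

test_that("experiment-design files are validated", {
  tf <- withr::local_tempfile(fileext = ".csv")
  d <- tibble::tibble(file = c("a.csv", "b.csv"), sample = "S",
                      group = "G", replicate = 1:2, solvent_ppm = 150)
  readr::write_csv(d, tf)
  got <- read_design(tf)
  expect_s3_class(got, "experiment_design")
  expect_equal(got$replicate, 1:2)
  readr::write_csv(d[c(1, 1), ], tf)
  expect_error(read_design(tf), "duplicated")
  readr::write_csv(d[, -1], tf)
  expect_error(read_design(tf), "file")
  readr::write_csv(d, tf)
  expect_error(read_design(tf, check_files = TRUE), "missing file")
})
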