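# Corrections, delta values, replicate statistics, diagnostics.

test_that("exchangeable-hydrogen correction follows the mixing identity", {
  expect_equal(correct_exchangeable_h(2e-4, 8, 0), 2e-4)
  expect_equal(correct_exchangeable_h(150e-6, 8, 3, 150e-6), 150e-6)
  # Pro immonium: 8 H total, 1 exchangeable
  expect_equal(correct_exchangeable_h(200e-6, 8, 1, 150e-6) * 1e6,
               (8 * 200 - 150) / 7, tolerance = 1e-10)
  expect_error(correct_exchangeable_h(2e-4, 8, 8), "h_exch")
  # linear in r_raw and exceeds r_raw when r_raw > r_solvent
  r <- seq(150e-6, 400e-6, length.out = 5)
  out <- correct_exchangeable_h(r, 10, 2, 150e-6)
  expect_equal(diff(out) / diff(r), rep(10 / 8, 4))
  expect_true(all(out[-1] > r[-1]))
})

test_that("delta notation round-trips and matches the per-mil scale", {
  std <- standard_ratios()
  expect_equal(delta_value(std$H, std$H), 0)
  expect_equal(delta_value(2 * std$H, std$H), 1000)
  r <- delta_to_ratio(-47.8, std$C)
  expect_equal(r / std$C, 0.9522, tolerance = 1e-4)
  expect_equal(delta_value(r, std$C), -47.8, tolerance = 1e-12)
  set.seed(1)
  x <- runif(20, 1e-5, 1e-2)
  expect_equal(delta_to_ratio(delta_value(x, std$N), std$N), x, tolerance = 1e-14)
})

test_that("aggregation computes moments, applies QC and trims outliers", {
  rec <- gaussian_records(3, replicates = 1, sigma = 1e-12)
  rec$r_C <- 0.011
  s <- aggregate_replicates(rec, registry = suppressMessages(immonium_registry("Pro")))
  sc <- s[s$element == "C", ]
  expect_equal(sc$mean, 0.011)
  expect_equal(sc$median, 0.011)
  expect_equal(sc$sd, 0)
  expect_equal(sc$n, 3L)
  expect_equal(sc$sem, 0)

  # planted Gaussian sample: mean within sampling error
  rec <- gaussian_records(1000, replicates = 1, mu = 0.011, sigma = 1e-4, seed = 5)
  s <- aggregate_replicates(rec, registry = suppressMessages(immonium_registry("Pro")),
                            mad_k = Inf)
  expect_lt(abs(s$mean[s$element == "C"] - 0.011), 4 * 1e-4 / sqrt(1000))
  expect_equal(s$sem[s$element == "C"], s$sd[s$element == "C"] / sqrt(s$n[s$element == "C"]))

  # QC-flagged records are excluded; MAD trim drops spikes
  rec2 <- gaussian_records(50, replicates = 1, sigma = 1e-5, seed = 6)
  rec2$qc_pass[1] <- FALSE
  rec2$r_C[2] <- 0.05  # gross outlier
  s2 <- aggregate_replicates(rec2, registry = suppressMessages(immonium_registry("Pro")))
  expect_equal(s2$n[s2$element == "C"], 48L)
  expect_lt(abs(s2$mean[s2$element == "C"] - 0.011), 1e-5)

  # permutation invariance
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(
    aggregate_replicates(perm, registry = suppressMessages(immonium_registry("Pro")))$mean,
    aggregate_replicates(rec, registry = suppressMessages(immonium_registry("Pro")))$mean)

  # the corrected H element applies the solvent correction per record
  expect_true("H" %in% s$element && "H_raw" %in% s$element)

  # interim-standard calibration: a per-element multiplicative factor
  s3 <- aggregate_replicates(rec, registry = suppressMessages(immonium_registry("Pro")),
                             mad_k = Inf, element_correction = c(C = 1.01))
  expect_equal(s3$mean[s3$element == "C"], 1.01 * s$mean[s$element == "C"])
  expect_equal(s3$mean[s3$element == "N"], s$mean[s$element == "N"])
})

test_that("between-replicate CV matches direct arithmetic and is scale-free", {
  summ <- tibble::tibble(
    sample = "S1", group = "G", species = "Pro", element = "C",
    replicate = 1:3, n = 100,
    mean = c(0.0110, 0.0111, 0.0109), median = c(0.0110, 0.0111, 0.0109))
  cv <- cv_between_replicates(summ)
  expect_equal(cv$cv_mean_pct, sd(summ$mean) / mean(summ$mean) * 100)
  expect_equal(cv$cv_mean_pct, 0.9091, tolerance = 1e-4)
  summ7 <- summ; summ7$mean <- summ7$mean * 7; summ7$median <- summ7$median * 7
  expect_equal(cv_between_replicates(summ7)$cv_mean_pct, cv$cv_mean_pct)
  same <- summ; same$mean <- 0.011; same$median <- 0.011
  expect_equal(cv_between_replicates(same)$cv_mean_pct, 0)
  expect_error(suppressWarnings(cv_between_replicates(summ[1, ])), "replicates")
})

test_that("TIC-trend diagnostic distinguishes null from planted dependence", {
  n <- 500
  null_rec <- gaussian_records(n, replicates = 1, seed = 34)
  null_rec$tic <- 10^runif(n, 5, 6.5)
  tt <- tic_trend(null_rec, "Pro", "C")
  expect_lt(abs(tt$correlation), 0.1)
  expect_gt(tt$p_value, 0.001)

  dep <- null_rec
  dep$r_C <- dep$r_C + 2e-4 * (log10(dep$tic) - 5)
  td <- tic_trend(dep, "Pro", "C")
  expect_gt(td$slope, 0)
  expect_lt(td$p_value, 1e-6)

  const <- null_rec
  const$r_C <- 0.011
  tc <- tic_trend(const, "Pro", "C")
  expect_identical(tc$slope, 0)
  const$tic <- 1e6
  expect_error(tic_trend(const, "Pro", "C"), "degenerate")
})

test_that("subsampling precision follows sampling theory", {
  rec <- gaussian_records(400, replicates = 3, seed = 10)
  reg <- suppressMessages(immonium_registry("Pro"))
  pc <- subsample_precision(rec, ks = c(25, 50, 100, 200), n_draws = 30,
                            seed = 4, registry = reg)
  expect_s3_class(pc, "precision_curve")
  # determinism
  pc2 <- subsample_precision(rec, ks = c(25, 50, 100, 200), n_draws = 30,
                             seed = 4, registry = reg)
  expect_identical(pc$cv_mean_pct, pc2$cv_mean_pct)
  # CV(k) decreases as k^(-1/2): log-log slope -0.5 +/- 0.1
  sl <- unname(coef(lm(log(pc$cv_mean_pct) ~ log(pc$k)))[2])
  expect_lt(abs(sl + 0.5), 0.1)
  # k above availability errors with the offending group named
  expect_error(subsample_precision(rec, ks = c(100, 1000), registry = reg), "1000")
})

test_that("incorporation regression recovers planted slopes", {
  media <- seq(150, 1000, length.out = 10)
  noiseless <- tibble::tibble(media_ppm = media, mean = (150 + 0.15 * (media - 150)) * 1e-6)
  fit <- incorporation_regression(noiseless)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$incorporation_pct, 15)
  expect_equal(fit$intercept_ppm, 150 - 0.15 * 150, tolerance = 1e-9)
  set.seed(2)
  for (slope in c(0.04, 0.15)) {
    noisy <- tibble::tibble(
      media_ppm = rep(media, each = 3),
      mean = (150 + slope * (rep(media, each = 3) - 150) + rnorm(30, 0, 0.5)) * 1e-6)
    f <- incorporation_regression(noisy)
    expect_lt(abs(f$slope - slope), 3 * f$slope_se)
    expect_gt(f$r_squared, 0.98)
  }
  expect_error(incorporation_regression(noiseless[1:2, ]), "3 distinct")
})

test_that("species contributions sum to 100% and score against a reference", {
  rec1 <- gaussian_records(10, replicates = 1)
  expect_equal(species_contributions(rec1)$contribution_pct, 100)
  # planted 2:1:1 mixture by monoisotopic area
  rec3 <- rbind(
    transform(gaussian_records(20, replicates = 1), area_M = 2000),
    transform(gaussian_records(20, replicates = 1, species = "Hyp"), area_M = 1000),
    transform(gaussian_records(20, replicates = 1, species = "Val"), area_M = 1000))
  got <- species_contributions(rec3)
  expect_equal(sort(got$contribution_pct, decreasing = TRUE), c(50, 25, 25))
  # collagen-style composition check: measured vs reference contributions
  meas <- c(Pro = 35, Hyp = 22, "Leu/Ile" = 9, Phe = 5)
  ref <- c(Pro = 18, Hyp = 11, "Leu/Ile" = 7, Phe = 5)
  rec4 <- do.call(rbind, lapply(names(meas), function(sp) {
    transform(gaussian_records(5, replicates = 1, species = sp),
              area_M = meas[[sp]])
  }))
  scored <- species_contributions(rec4, reference = ref)
  expect_equal(scored$contribution_pct[match(names(meas), scored$species)],
               unname(meas) / sum(meas) * 100)
  expect_equal(attr(scored, "r_squared"), cor(meas, ref)^2)
  expect_equal(attr(scored, "r_squared"), 0.98464, tolerance = 1e-4)
  expect_error(species_contributions(rec1[0, ]), "no records")
})
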