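# Elemental bookkeeping: masses, ion m/z conventions, isotopologue
# combinatorics and fine-structure line geometry.

test_that("monoisotopic masses and theoretical m/z reproduce reference values", {
  expect_equal(monoisotopic_mass("C5H9NO2"), 115.06333, tolerance = 1e-7)
  expect_equal(monoisotopic_mass(composition()), 0)
  expect_equal(monoisotopic_mass("C4H8NO"), 86.06059, tolerance = 1e-7)
  expect_error(monoisotopic_mass("C2X5"), "X")

  # MH+ of the free amino acids, H-atom convention
  expect_equal(theoretical_mz("C5H9NO2", extra_h = 1), 116.0712, tolerance = 1e-4 / 116)
  expect_equal(theoretical_mz("C5H9NO3", extra_h = 1), 132.0661, tolerance = 1e-4 / 132)
  expect_equal(theoretical_mz("C5H11NO2", extra_h = 1), 118.0868, tolerance = 1e-4 / 118)
  # immonium ions, written as radical formulas
  expect_lt(abs(theoretical_mz("C4H8N") - 70.0656), 1e-4)
  expect_lt(abs(theoretical_mz("C4H8NO") - 86.0606), 1e-4)
  expect_lt(abs(theoretical_mz("C4H10N") - 72.0813), 1e-4)
  # physical cation differs by exactly one electron mass per charge
  expect_equal(theoretical_mz("C4H8N") - theoretical_mz("C4H8N", "cation_physical"),
               physical_constants()$electron)
  expect_equal(theoretical_mz("C4H8N", "cation_physical"), 70.0651,
               tolerance = 1e-4 / 70)
  expect_error(theoretical_mz("C4H8N", charge = 0), "charge")
})

test_that("isotope table and abundance sets satisfy their invariants", {
  tab <- isotope_table()
  for (el in unique(tab$element)) {
    x <- tab[tab$element == el, ]
    expect_true(all(diff(x$mass) > 0))
    expect_lt(abs(sum(x$abundance) - 1), 1e-9)
  }
  # the bundled TSV mirrors the built-in table
  tsv <- isotope_table(system.file("extdata", "isotopes.tsv", package = "isofine"))
  expect_equal(tsv$mass, tab$mass)
  expect_error(abundance_set(r_C = 1.2, r_H = 1e-4, r_N = 4e-3, r_O = 2e-3), "C")
  expect_error(abundance_set(r_C = 0.01, r_H = 0, r_N = 4e-3, r_O = 2e-3), "H")
  nat <- natural_abundances("iupac")
  expect_equal(nat$C, 0.0107 / 0.9893, tolerance = 1e-12)
})

test_that("isotopologue distribution matches brute-force enumeration", {
  ab <- natural_abundances()
  for (formula in c("C1", "C2H3NO", "C4H8N")) {
    comp <- composition(formula)
    n_atoms <- sum(comp)
    bf <- bf_isotopologues(formula, ab)
    # full enumeration: probabilities over all assignments sum to 1
    expect_lt(abs(sum(bf$prob) - 1), 1e-12)
    got <- isotopologue_distribution(formula, ab, max_shell = n_atoms + 2)
    expect_lt(abs(sum(got$prob) - 1), 1e-12)
    # every line's probability agrees with the brute force, keyed by
    # substitution counts
    for (i in seq_len(nrow(got))) {
      k <- parse_subs(got$subs[i])
      hit <- rep(TRUE, nrow(bf))
      for (el in names(k)) {
        col <- if (el %in% names(bf)) bf[[el]] else rep(0L, nrow(bf))
        hit <- hit & col == k[[el]]
      }
      expect_equal(sum(hit), 1)
      expect_equal(got$prob[i], bf$prob[hit], tolerance = 1e-12)
    }
  }
})

test_that("single- and double-substitution ratios obey the closed forms exactly", {
  ab <- natural_abundances()
  d <- isotopologue_distribution("C4H8N", ab, max_shell = 1)
  expect_identical(d$ratio[d$label == "M1_13C"], 4 * ab$C)
  expect_identical(d$ratio[d$label == "M1_2H"], 8 * ab$H)
  expect_identical(d$ratio[d$label == "M1_15N"], 1 * ab$N)
  d2 <- isotopologue_distribution("C4H8NO", ab, max_shell = 2)
  expect_identical(d2$ratio[d2$label == "M2_18O"], 1 * ab$O)
  expect_identical(d2$ratio[d2$label == "M2_13C2"], choose(4, 2) * ab$C^2)
  # the identity holds for arbitrary compositions and abundance sets
  set.seed(7)
  for (i in 1:10) {
    nC <- sample(1:10, 1); nH <- sample(1:12, 1)
    ab_i <- abundance_set(r_C = runif(1, 1e-4, 0.1), r_H = runif(1, 1e-5, 1e-3),
                          r_N = runif(1, 1e-4, 0.01), r_O = runif(1, 1e-4, 0.01))
    di <- isotopologue_distribution(composition(C = nC, H = nH, N = 1), ab_i, 1)
    expect_identical(di$ratio[di$label == "M1_13C"], nC * ab_i$C)
    expect_identical(di$ratio[di$label == "M1_2H"], nH * ab_i$H)
  }
  expect_error(isotopologue_distribution("C2", ab, max_shell = -1), "max_shell")
})

test_that("fine-structure line positions use exact isotope mass shifts", {
  reg <- suppressMessages(immonium_registry(mz_range = NULL))
  fl <- fine_structure_lines(reg$Pro, shell = 1)
  m1 <- fl[fl$shell == 1, ]
  expect_equal(m1$dm[m1$label == "M1_15N"], 0.9970349, tolerance = 1e-6)
  expect_equal(m1$dm[m1$label == "M1_13C"], 1.0033548, tolerance = 1e-6)
  expect_equal(m1$dm[m1$label == "M1_2H"], 1.0062768, tolerance = 1e-6)
  expect_equal(m1$dm[m1$label == "M1_2H"] - m1$dm[m1$label == "M1_13C"],
               0.0029219, tolerance = 1e-4)
  # M+1 order 15N < 13C < 2H holds for every registry species
  for (sp in reg) {
    lines <- fine_structure_lines(sp, shell = 1)
    m1 <- lines[lines$shell == 1, ]
    present <- intersect(c("M1_15N", "M1_13C", "M1_2H"), m1$label)
    expect_equal(m1$label[order(m1$dm)][m1$label[order(m1$dm)] %in% present], present)
  }
  hyp <- fine_structure_lines(reg$Hyp, shell = 2)
  m2 <- hyp[hyp$shell == 2, ]
  expect_equal(m2$dm[m2$label == "M2_18O"], 2.0042464, tolerance = 2e-6)
  expect_equal(m2$dm[m2$label == "M2_13C2"], 2.0067097, tolerance = 2e-6)
  expect_false(attr(hyp, "o_line_missing"))
  expect_message(flp <- fine_structure_lines(reg$Pro, shell = 2), "no oxygen")
  expect_true(attr(flp, "o_line_missing"))
  expect_true(all(c("M2_13C2", "M2_15N.13C", "M2_13C.2H") %in% flp$label))
})

test_that("immonium registry species are consistent", {
  reg <- suppressMessages(immonium_registry(mz_range = NULL))
  for (sp in reg) {
    expect_equal(sp$h_exch + sp$h_cb, sp$h_total)
    expect_equal(sp$mz - sp$mz_cation, physical_constants()$electron)
  }
  expect_message(inr <- immonium_registry(), "Gly, Ala")
  expect_false(any(c("Gly", "Ala") %in% names(inr)))
  expect_error(immonium_registry("Trp"), "unknown species")
  # registry round-trips through its editable TSV form
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_species_registry(reg, tf)
  reg2 <- immonium_registry(mz_range = NULL, path = tf)
  expect_equal(registry_table(reg2), registry_table(reg))
})
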