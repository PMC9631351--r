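Package: isofine
Title: Amino Acid-Resolved Stable Isotope Ratios from Immonium-Ion
    Isotopic Fine Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts element-wise stable isotope ratios (13C/12C, 2H/1H,
    15N/14N, 18O/16O) at amino-acid resolution from the isotopic fine
    structure of immonium ions recorded in ultrahigh-resolution profile-mode
    MS/MS spectra of peptide digests. Provides elemental and isotopologue
    bookkeeping, mzML input/output, constrained Gaussian fitting of M+1/M+2
    fine-structure components, exchangeable-hydrogen solvent correction,
    delta-notation reporting against VSMOW/VPDB/AIR standards, replicate
    statistics and diagnostics (between-replicate CVs, TIC-independence,
    datapoint-subsampling precision curves, deuterium-incorporation
    regression), and a forward simulator that renders broad-isolation
    high-energy HCD scans with exact fine structure and shot noise so the
    whole pipeline is testable without instrument data. A command-line
    interface and a static HTML report generator mirror the
    simulate/extract/report workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    mzR,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
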