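# isofine

Element-wise stable isotope ratios (¹³C/¹²C, ²H/¹H, ¹⁵N/¹⁴N, ¹⁸O/¹⁶O) at
amino-acid resolution, extracted from the isotopic fine structure of
immonium ions in ultrahigh-resolution profile-mode MS/MS spectra.

## Why

Conventional isotope-ratio MS needs ~1 mg of purified material per isotope
and has no amino-acid resolution. A proteomics-type experiment can do
better: fragmenting peptides with high-energy HCD in a very wide isolation
window ("isoMS" scans) produces immonium ions — one fragment per residue —
and at a resolving power of 60,000 @ m/z 200 the M+1 isotope peak of each
immonium ion splits into resolved components, one per substitution
(¹⁵N < ¹³C < ²H in m/z; ¹⁸O separates from ¹³C₂ in M+2). Because
substitution sites are independent, the abundance of a single-substitution
component relative to the monoisotopic peak is exactly `n_X · r_X`, so

    r̂_X = A(M+1, X) / A(M) / n_X

estimates the heavy/light ratio of element X from sub-microgram digests,
per residue, with per-mil-range precision. Raw ²H/¹H is corrected for
exchangeable hydrogens equilibrated with the solvent (~150 ppm ²H), and
results are reported as δ-values against VSMOW/VPDB/AIR.

The package implements the whole pipeline — isotopologue combinatorics,
mzML I/O, constrained Gaussian fitting of fine-structure components,
solvent correction, replicate statistics and diagnostics — plus a forward
simulator of isoMS acquisitions (AGC-conditioned multinomial ion
statistics, resolution-scaled Gaussian peaks, calibration jitter, baseline
noise) that serves as the ground-truth oracle for every recovery test.

## Worked example

Simulate a three-level deuterium titration, extract ratio records, and
regress the corrected ²H/¹H on the media level:

```r
library(isofine)
library(dplyr)

sc  <- scenario_titration(media_ppm = c(150, 500, 1000),
                          n_replicates = 2, n_spectra = 60)
res <- run_scenario(sc, sim_instrument(), seed = 1)

summ <- aggregate_replicates(res$records,
                             registry = immonium_registry(c("Leu/Ile", "Pro")))
hs <- filter(summ, element == "H")
for (sp in c("Leu/Ile", "Pro")) {
  f <- incorporation_regression(filter(hs, species == sp))
  cat(sprintf("%-8s incorporation %.1f%%  (R^2 = %.4f)\n",
              sp, f$incorporation_pct, f$r_squared))
}
```

```
Leu/Ile  incorporation 4.1%  (R^2 = 0.9979)
Pro      incorporation 15.0%  (R^2 = 0.9991)
```

The planted incorporation fractions are 0.04 and 0.15: the slope of the
measured C-bonded ²H/¹H (ppm) against the media ²H (ppm) recovers them,
and R² close to 1 reflects the linearity of the response. `summ` also
carries per-replicate means/medians/SDs and δ-values; `tic_trend()`,
`cv_between_replicates()`, `subsample_precision()` and
`species_contributions()` reproduce the standard QC diagnostics, and
`build_report()` renders everything into a single static HTML report.

A thin command-line front end covers the same workflow
(`inst/cli/isofine simulate | extract | report`).

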