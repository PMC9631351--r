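---
title: "Isotope ratios from immonium-ion fine structure: models and methods"
author: "isofine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope ratios from immonium-ion fine structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofine)
```

## The measurement

High-energy HCD fragmentation of peptides produces immonium ions
(H~2~N^+^=CHR), one characteristic fragment per amino-acid residue. In an
"isoMS" acquisition the quadrupole isolates a very wide m/z window (1000 Th
for digests, 150 Th for infused free amino acids), fragments everything at
HCD 50%, and detects the products in profile mode over m/z 50--200 at a
nominal resolving power of 60,000 at m/z 200, co-adding 20 microscans per
reported spectrum. At that resolving power the nominal M+1 isotope peak of
an immonium ion splits into resolved fine-structure components, one per
heavy-isotope substitution, ordered in m/z as ^15^N < ^13^C < ^2^H
(mass shifts 0.99703, 1.00335, 1.00628 Da). For oxygen-bearing ions the
M+2 shell separates ^18^O (+2.00425 Da) from ^13^C~2~ (+2.00671 Da).

Because substitution sites are independent and heavy-isotope abundances
small, the abundance of a single-substitution component relative to the
monoisotopic peak is exactly $n_X r_X$, where $n_X$ is the atom count of
element $X$ in the ion and $r_X$ the heavy/light ratio
(e.g. $r_C = [^{13}\mathrm{C}]/[^{12}\mathrm{C}]$). The estimator is the
inverse:

$$\hat r_X \;=\; \frac{A(\mathrm{M{+}1},X)}{A(\mathrm{M})}\cdot\frac{1}{n_X},
\qquad
\hat r_O \;=\; \frac{A(\mathrm{M{+}2},{}^{18}\mathrm{O})}{A(\mathrm{M})}\cdot\frac{1}{n_O}.$$

Double substitutions (ratio $\binom{n_X}{2} r_X^2$ and cross terms) sit in
the M+2 shell and are fit as nuisance components so they cannot inflate the
^18^O amplitude. `isotopologue_distribution()` implements the exact
combinatorics; the closed forms are verified in the test suite against
brute-force enumeration over all per-atom isotope assignments.

Results are reported as per-mil deviations from the international
standards, $\delta = (r/r_\mathrm{std} - 1)\cdot 1000$, with default
standard ratios VSMOW (^2^H/^1^H = 1.5576e-4; ^18^O/^16^O = 2.0052e-3),
VPDB (^13^C/^12^C = 1.11802e-2) and atmospheric N~2~
(^15^N/^14^N = 3.6765e-3). These are literature consensus values and are
overridable via `standard_ratios()`.

## Mass conventions

Immonium ions are conventionally written as neutral-radical formulas that
already include the ionizing proton (Pro = C4H8N). Under hydrogen-*atom*
arithmetic this reproduces the m/z values commonly printed for these ions
(70.0657 for Pro, 86.0606 for Hyp, 72.0813 for Val; MH^+^ of free Pro/Hyp/Val
at 116.0712/132.0661/118.0868). The physically exact cation m/z is one
electron mass lower (70.0651 for Pro). Both are computed
(`theoretical_mz()`, conventions `"h_atom"` and `"cation_physical"`); the
package defaults to `"h_atom"` for peak lookup because it matches the
printed values, and because the lookup is followed by anchoring on the
*observed* monoisotopic centroid, a constant offset of either convention
(or of the instrument calibration) cancels out of all ratios. The
resolvability and fitting mathematics are unaffected by the choice.

## Peak fitting

For each species and spectrum:

1. The monoisotopic apex is located within a mass tolerance (default 5 ppm
   after a run-level recalibration pass that applies the median apex mass
   error of the whole run). The centroid is refined by parabolic
   interpolation of the log-intensities around the apex, which is exact for
   a Gaussian profile.
2. All expected M+1/M+2 line positions are placed relative to the observed
   centroid using exact isotope mass differences, cancelling common-mode
   calibration error.
3. Component amplitudes are estimated by linear least squares of
   fixed-position, fixed-width Gaussians over each shell's window, with a
   non-negativity constraint (ordinary least squares as the fast path,
   non-negative least squares via `pracma::lsqnonneg` when any amplitude
   goes negative). Widths come from the resolution model
   $R(m/z) = R_0\sqrt{200/(m/z)}$, FWHM $= (m/z)/R$, the scaling of FT
   analyzers with fixed transient length.
4. A component is flagged *unresolved* when a neighbour expected (from
   natural abundances) to contribute at least 1% of the component's own
   abundance lies closer than $\kappa$ FWHM ($\kappa$ default 1.0);
   sub-percent neighbours are retained as fit nuisances but are not
   treated as threats. Components are flagged *below noise* when their
   amplitude does not exceed three times its standard error estimated from
   the fit residuals. Flagged components yield absent ratios and are
   excluded from downstream statistics.

Ratios are formed from the fitted *amplitudes* (peak heights), which are
the ion-count-proportional quantity: under the resolution model the peak
width grows as $(m/z)^{3/2}$, so a raw area ratio between the M and M+1
shells would carry a systematic $(1+1/m)^{3/2}$ factor (about +2% at
m/z 70). Amplitude ratios are identical to area ratios within a
fine-structure multiplet (equal widths) and free of that factor across
shells. Integrated areas (amplitude x width) are still reported per
component for diagnostics.

Open choices resolved here: whether the original instrument-side tooling
uses apex intensity, integrated area or fitted area is not published; this
package defines the fitted-amplitude estimator above and documents it.
Similarly the noise floor in full-profile mode ("no noise reduction") is
estimated from fit residuals per window rather than a global model.

## Hydrogen pools and the solvent correction

The ionizing proton and hydrogens bonded to heteroatoms exchange with the
solvent (natural deuterium content about 140--150 ppm) and carry no sample
information. With $h$ total hydrogens of which $h_e$ are exchangeable,

$$r_\mathrm{C\text{-}bonded} =
  \frac{h\, r_\mathrm{raw} - h_e\, r_\mathrm{solvent}}{h - h_e}.$$

Exchangeable counts come from the H~2~N^+^=CHR structure: 1 for Pro (ring
N--H), 2 for Val/Leu/Ile/Phe (two N--H), 2 for Hyp (N--H + O--H). They are
stored in the editable species registry because they are structural
assignments, not measured quantities. The default solvent level is 150 ppm,
configurable per design file.

## The simulator

`simulate_spectrum()` is a forward model of one isoMS acquisition:

- **Ion statistics.** Automatic gain control accumulates a fixed target of
  ions per fill (default 5e4) in each of 20 microscans; the total ion count
  is allocated multinomially over (species x isotopologue line) cells with
  probabilities equal to molar mixture fractions times exact isotopologue
  probabilities for shells M..M+2. The beyond-M+2 remainder is kept as an
  unrendered bucket so ledgered counts always sum exactly to
  AGC x microscans. Conditioning on the AGC target is what makes measured
  ratios independent of ion current, and the `tic_trend()` diagnostic
  checks exactly that.
- **Hydrogen pools.** C-bonded and exchangeable hydrogens are separate
  site classes with independent ^2^H levels, so labelling scenarios plant
  different deuterium levels in the two pools and the solvent correction
  can be validated against ground truth.
- **Rendering.** Each line is a Gaussian with FWHM from the resolution
  model, centred at the line m/z scaled by a calibration offset (default
  1 ppm) plus per-scan jitter (SD 0.2 ppm, typical of lock-mass-stabilised
  Orbitrap acquisitions); one ion contributes an apex height of one
  intensity unit per microscan and microscans are averaged. Profile grids
  span each species' M-0.6 to M+2.5 Da window at FWHM/8 spacing (8 points
  per FWHM), and additive Gaussian baseline noise (SD 0.1 ion-equivalents,
  clamped at zero) models detection noise.
- **Run modes.** Direct infusion keeps the mixture constant. LC mode
  modulates species abundances with broad, overlapping Gaussian elution
  envelopes and scales the AGC fill with the total eluting current
  (floor 20%): immonium ions in a digest derive from all co-eluting
  peptides, so the species mix is nearly stable while TIC rises and falls
  by almost an order of magnitude across the run.

What the simulator does **not** emulate: space-charge coalescence,
resolution-dependent systematic biases, Lorentzian peak tails, chemical
background and co-isolated cluster ions (the phenomenon that defeats
internal-standard designs on real instruments), retention-dependent
suppression, and ^17^O (natural abundance 0.04%, a further factor ~5 below
the 2H component and resolved from it at the default resolution). Passing
recovery tests on simulated data therefore demonstrates correctness of the
estimator and its statistics under shot-noise-limited acquisition, not
robustness to every instrument artefact of real data.

## Scenario presets and study conditions

Three presets mirror the validation designs the method is used in:

- `scenario_direct_infusion()`: Pro, Hyp, Val infused one by one,
  3 replicates x 300 scans, natural abundances.
- `scenario_titration()`: 10 media deuterium levels from 150 ppm (control)
  to 1000 ppm, 3 replicate LC runs per level, 300 scans each, two species
  with planted C-bonded incorporation fractions 0.04 (Leu/Ile) and
  0.15 (Pro); the media-to-residue line is
  $r_\mathrm{cb} = 150\,\mathrm{ppm} + f\,( \mathrm{media} - 150)$.
  The Leu/Ile:Pro molar mix defaults to 0.6:0.4, the approximate abundance
  ratio of these residues in a mammalian proteome digest.
- `scenario_depletion()`: biomass grown on depleted substrates, planted at
  $r_C/20$, $r_N/10$ and 80 ppm C-bonded ^2^H against a normal solvent.

These defaults are the study conditions of the package's validation suite;
the reproduction script (`scripts/acceptance.R`) runs them unchanged. Replicate precision follows
binomial counting statistics: with $N_M$ monoisotopic ions per spectrum the
relative SD of $\hat r_X$ per scan is $1/\sqrt{n_X r_X N_M}$, and CVs of
replicate means shrink as (datapoints)^-1/2^ — the `subsample_precision()`
curve verifies the -0.5 log-log slope. One *datapoint* is one per-scan,
per-species record.

## Numerical choices and edge cases

- Subsampling draws records without replacement per (replicate, species)
  group. For iid records with $k$ well below the group size $n$ the CV of
  the subsampled replicate means follows $k^{-1/2}$; as $k$ approaches $n$
  the draws overlap, the without-replacement correction $(1-k/n)$ bites,
  and the apparent log-log slope steepens below -1/2. Power-law checks are
  therefore fit on $k \le n/4$.
- Outlier policy before aggregation: drop records outside median +/- 5 MAD
  per (group, species, element); full-profile mode retains noise spikes
  and a heavy-tailed record occasionally survives QC. Configurable;
  `mad_k = Inf` disables.
- Aggregation reports means as the headline statistic with medians always
  alongside; CVs are computed on both.
- Degenerate inputs: empty runs and blank spectra return empty results
  with reasons, not errors; centroid spectra are refused by the fitter;
  TIC regressions require non-degenerate TIC spread; CV computations
  require at least two replicates and say so.
- Problem sizes: the validation suite and the reproduction script run the
  scenarios at their stated sizes (30 + 9 + 3 runs of 300-600 scans);
  property tests use reduced sizes (tens of scans) chosen so each check
  still has the statistical power to fail if the code is wrong.

## Limitations

- Leu and Ile are isomeric at the immonium level and reported as one
  species; Gly and Ala immonium ions (m/z 30 and 44) fall below the m/z 50
  cutoff of the targeted acquisition and are excluded by default.
- Absolute accuracy on real instruments requires calibration against a
  standard of known isotopic composition; the package supports a
  user-supplied multiplicative correction per element
  (`aggregate_replicates(element_correction = ...)`) but ships none.
- The mzML standard has no slot for the microscan count; it is carried
  in-memory and recorded as absent after a file round-trip.
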