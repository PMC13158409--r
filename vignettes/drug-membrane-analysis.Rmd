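---
title: "Modelling drug-membrane interactions on supported bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug-membrane interactions on supported bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slbtools)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the choices made where the design
was genuinely open, and what its synthetic-data tests do and do not
demonstrate about real measurements.

## The physical problem

Amphiphilic cationic drugs such as chlorpromazine partition into lipid
bilayers, change their thickness, hydration and mechanics, and at high
concentration nucleate drug-lipid aggregates above the membrane. The
package's core is the structural assay for this process: specular neutron
reflectometry of a silicon-supported bilayer measured in several isotopic
solvent contrasts (H2O, silicon-matched water at 38% D2O, four-matched water
at 66% D2O, and D2O), analysed by co-refining one slab model against all
contrasts simultaneously. Around it sit four companion assays of the same
interaction - fluorescence partitioning, Laurdan order sensing, spin-label
EPR, and AFM force spectroscopy - each implemented as an independent module.

## Scattering-length bookkeeping

A species' scattering length density is SLD = sum(b_c)/v_m: the summed
coherent scattering lengths of its atoms over its molecular volume. The
scattering lengths are the standard tabulated (Sears) values; they are not
fitted. Molecular volumes come from mass densities (waters: 0.997 and
1.1044 g/cm3 at 25 C; amorphous oxide: 2.20 g/cm3), from crystallography
(silicon: diamond-cubic cell, a = 5.431 A, 8 atoms), or from reported
fragment volumes (PC headgroup: 319 A3). These reproduce the printed
anchor values (-0.56, 6.35, 2.07, 3.47, 1.88, all 1e-6 A^-2) to about one
unit in the last printed digit; the small residuals reflect rounding in the
source values, not a model choice. Solvent contrasts are linear volume
mixes of the two pure waters. All SLDs are real-valued: every material here
has negligible neutron absorption at cold wavelengths. The drug SLD
(1.30e-6 A^-2) is stored as a fixed constant because its underlying
molecular volume is not independently recoverable; it is never recomputed.

## The forward model

Reflectivity of a stack of homogeneous slabs between semi-infinite silicon
and solvent is evaluated by the Parratt recursion, with interfacial
roughness as Nevot-Croce attenuation factors. That approximation is
standard slab-model practice and valid while roughness is small against
thickness; for rough interfaces (roughness beyond about half the layer
thickness) a micro-slicing evaluation through the error-function SLD
profile (1 A slices) is provided as `method = "microslice"`. The recursion
is verified in the test suite against an independently written
characteristic-matrix (transfer-matrix) implementation to |dR|/R < 1e-10 on
random stacks, and against the Fresnel and critical-edge closed forms.

Instrument resolution is a constant dq/q of 7%. The measurement convention
states only "7%"; the package interprets it as the full width at half
maximum of a Gaussian kernel - the usual time-of-flight instrument
convention - truncated at +/-3.5 sigma with at least 21 kernel points. If a
user's instrument quotes sigma instead, the numeric value should be scaled
by 2.355; this convention choice is a flagged assumption, not ground truth.
Fitting always happens on unscaled R; R*q^4 scaling is presentation only.

## The membrane model hierarchy

The bilayer is five layers on top of the silicon: native oxide, inner
headgroups, inner tails, outer tails, outer headgroups, each with
thickness, SLD, roughness and a solvent fraction; component volume
fractions in every layer sum to one. Head and tail thicknesses are
leaflet-symmetric while the inventories (drug share, hydration) may differ
between leaflets. The model hierarchy follows increasing complexity: the
pristine bilayer; drug intercalated in the fatty-acid region; drug plus
one, two, or three adsorbed layers above the membrane, optionally separated
by a pure-solvent gap. Design choices made here:

- One shared roughness for all membrane interfaces plus one substrate
  roughness, since the analysis fits conformal slab models and no
  per-interface roughness is identifiable.
- Coverage is not a separate parameter: incomplete coverage is carried by
  the tail-layer solvent fractions (coverage = 1 - tail solvent fraction).
- Adsorbed layers carry a fitted SLD directly rather than a component
  decomposition, because their composition is a result (their SLD) rather
  than an input.
- Drug uptake redistributes dry volume (lipid fraction = 1 - drug
  fraction): the model treats the fatty-acid region's dry volume as
  conserved, which is an interpretation - displacement versus compression
  of the lipid tails is not distinguishable at this resolution.
- Headgroup drug occupancy is off by default (`allow_headgroup_cpz`)
  because the headgroup SLD (1.88) and the drug SLD (1.30) are barely
  distinguishable; enabling it is the documented extension used to test
  whether headgroup pools are supported by the data.

The volume-fraction profile writer places z = 0 at the silicon/oxide
boundary, uses half-open layer intervals, and smooths boxcars with error
functions of the interface roughness; the solvent channel is the complement
of all material channels so the profile sums to one identically.

## Co-refinement, uncertainty, and model choice

All contrasts share every structural parameter; only the solvent SLD
differs. The objective is the plain weighted sum of squares
chi2 = sum((R_model - R_data)^2 / dR^2) over all contrasts and points, with
model curves smeared at each dataset's resolution. Whether residuals should
be taken in linear or log space is not prescribed by the source analysis;
linear-space dR-weighted residuals are the default and the deliberate
choice here, not a silent substitution. Zero uncertainties are refused with
advice (floor or exclude); internally dR is floored at 1e-12 of the
curve's maximum to keep weights finite.

Global optimization is differential evolution (rand/1/bin, population 10
per free dimension, reflection at the bounds) - written in-package because
no pre-installed package provides it - with two stopping rules: collapse of
the population cost spread, or collapse of the population in parameter
space below `ptol` of each bound width. Posterior sampling is an
affine-invariant stretch-move ensemble with log-likelihood -chi2/2 and
uniform priors on the bounds; the protocol mirrors the study: burn-in 200
sweeps, production 200 sweeps, thinning 10. Walker count defaults to
max(2 n_free + 2, 32), a standard ensemble-size heuristic the source does
not state. "Steps" are interpreted as ensemble sweeps (every walker
advances once per step). Model variants are ranked by reduced chi2 =
chi2/(N - n_free), with ties within 1% relative broken toward fewer free
parameters; no multiplicity correction is applied, matching the original
selection procedure.

## Partitioning, Laurdan, EPR, AFM

**Partitioning.** The titration model is
I/I_w = (1 + K_P g_L [L] I_L/I_W)/(1 + K_P g_L [L]) with the lipid molar
volume g_L fixed at 0.763 1/M (the POPC value). K_P and I_L/I_W are fitted
jointly by Levenberg-Marquardt least squares (unweighted by default, since
no weighting is prescribed; per-point sigmas are accepted). Starting values
are read from the data: the plateau for I_L/I_W, the half-saturation lipid
concentration for K_P. The fitter warns when the design cannot identify
K_P (fewer than four points, a flat series, or a lipid range that never
reaches half-saturation).

**Laurdan.** GP = (I440 - I490)/(I440 + I490), with band intensities read
by linear interpolation on the 2-nm acquisition grid. The dose series
tabulates GP mean and sd per drug:lipid ratio in ratio order.

**EPR.** At room temperature the mobility ratio h0/h- is the peak-to-peak
amplitude of the mid-field line over the high-field line; peak-to-peak
rather than peak-height normalization is an explicit convention choice (the
source does not state which it used) and is invariant to amplitude
inversion. At 77 K the hyperfine coupling is read as half the distance
between the first and last line, each line's position refined by a local
Gaussian fit within +/-1 mT of the detected extremum (window configurable);
the uncertainty combines the two center standard errors in quadrature.
"First and last line" means the low-field maximum and the high-field
minimum - the conventional 2A_zz reading, documented as such.

**AFM.** Breakthroughs are sudden force drops exceeding a threshold
(default five baseline noise sd) within a five-point window during
approach. The hard-contact zero comes from a linear fit to the steep
constant-compliance region, and rupture distances e_b are referenced to
that substrate zero. Detection runs on a lightly Savitzky-Golay-smoothed
curve, while force readouts use raw values. Event lists preserve occurrence
order, so the two-step signature (F_b1 < F_b2, e_b1 > e_b2) is directly
assertable.

## The synthetic-data generator

The generator defines the study conditions under which the package is
exercised, and its defaults are fixed once:

- Canonical blank bilayer: 8 A headgroups, 17.5 A tails, 50% headgroup
  hydration, 5% tail solvent, 3 A roughness, 12 A oxide with 10% hydration
  - inside the experimentally reported ranges (7-9 A heads, 17-18 A tails,
  45-55% headgroup hydration, >90% coverage).
- Drug condition: 20% tail occupancy per leaflet (inside the reported
  15-25% band) with one adsorbed layer, 119 A thick, SLD 2.3, 96% solvent.
- Reflectivity noise follows counting statistics: incident counts decay as
  q^-2 scaled by `counts_scale`, detected counts are Poisson with mean
  (incident x R) - drawn exactly below 20 expected counts and as a
  matching-variance Gaussian above - and dR = R/sqrt(expected counts).
  `counts_scale = 1e6` gives a median relative uncertainty of about 1% over
  the measured q range and is the "1% noise" condition referred to by the
  recovery studies; `1e5` is visibly noisy, `1e4` sparse.
- Emission spectra are two Gaussian bands (440/490 nm, sigmas 20/25 nm)
  with a per-dose amplitude ratio; EPR lines are derivative Gaussians,
  except the outer lines of cryo spectra which are modelled as signed
  Gaussian bumps so that the extraction convention (outermost extrema) and
  the generating truth (outer-center distance) coincide exactly.
- Force curves are piecewise ramps with configured drops and a 10 nN/nm
  hard wall at zero separation.

Every generator runs all randomness through one seeded call and serializes
its generating parameters; recovery tests read truth only from that record.
What the generator does not emulate - instrument backgrounds, detector
artifacts, sample misalignment, footprint effects, multiple scattering,
slow-motion EPR lineshapes, cantilever calibration errors - bounds what
passing tests show: they demonstrate the estimators are correct and
calibrated under the assumed noise model, not that the assumed noise model
exhausts real instruments.

## Problem sizes and numerical choices

The shipped studies use 4 contrasts x 50-60 log-spaced q points over
0.008-0.3 1/A, differential evolution with populations of 16-42 and up to
60 generations, and MCMC runs of 100-200 sweeps with 16-32 walkers; these
sizes make each analysis script and the full test suite run in minutes on a
single core while leaving the estimators' behaviour unchanged at larger
sizes. The blank-bilayer recovery study frees the three structurally
informative parameters (head thickness, tail thickness, shared headgroup
hydration); the drug recovery study frees the shared tail occupancy, tail
thickness and adsorbed-layer solvation while pinning the substrate - the
same fix-the-substrate strategy the co-refinement workflow itself uses
between conditions. Model curves below the critical edge are clamped to
R <= 1; complex square roots take the principal branch so evanescent waves
decay; degenerate parameter bounds (lower = upper) pin a parameter exactly
and propagate a zero-width posterior.

## Known limitations

- Névot-Croce roughness degrades for roughness comparable to layer
  thickness; the micro-slicing fallback exists but is slower and is not
  used inside fits by default.
- The resolution kernel's FWHM-vs-sigma convention is an assumption
  (see above).
- Reduced-chi2 selection has no Occam penalty beyond the 1% parsimony
  tie-break; nested-sampling evidence comparison is out of scope.
- The partition fit treats I_L/I_W as jointly free; if a measured plateau
  is available, pinning it will tighten K_P.
- Leaflet-asymmetric thickness, curvature/vesicle form factors, and
  explicit micelle form factors for the adsorbed structures are out of
  scope: adsorbed material is a slab, as in the original analysis.
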