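---
title: "Quantifying tight-junction integrity and perivascular cellularity in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tight-junction integrity and perivascular cellularity in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vesselquant)
```

## The measurement problem

During neuroinflammation — most prominently in experimental autoimmune
encephalomyelitis (EAE), the standard mouse model of multiple sclerosis —
CNS venules lose blood–brain-barrier integrity. Two features of the
inflamed vessel can be read out from multichannel confocal z-stacks:

1. **Tight-junction integrity.** Claudin-5 (CLN-5) is the dominant
   tight-junction protein of CNS endothelium. In healthy vessels its
   junctional staining is continuous; in inflamed vessels it fragments.
   A robust scalar summary is the *staining density*: total CLN-5
   intensity inside the vessel surface divided by the microvascular
   surface area (intensity per µm²).
2. **Leukocyte position.** During inflammation the basement membrane
   (BM) splits into an endothelial and a parenchymal layer. A nucleus
   (DRAQ5⁺) can sit in the lumen, in the perivascular space between the
   two BMs, or in the parenchyma beyond — three compartments with very
   different biological meaning (stalled in the bloodstream, recently
   extravasated, fully infiltrated).

Historically both quantities are produced interactively (manual contour
tracing and spot counting in a commercial 3D package). `vesselquant`
re-implements the workflow as deterministic, scriptable code, and pairs
it with a synthetic vessel-phantom generator so that every stage can be
validated against known ground truth.

## Pipeline model and assumptions

### Coordinates and containers

A stack is a 4-axis array ordered (channel, z, y, x) with voxel spacing
(dz, dy, dx) in µm. All physical coordinates are (z, y, x) µm measured
from the corner of voxel (0, 0, 0); voxel centers sit at
`(i + 0.5) * spacing`. Fixing this convention once avoids half-voxel
drift between stages. Indexing is 0-based in all exchange formats.

### Surfaces from slice contours

The vessel surface is built the way an operator would build it: one
closed contour per z-slice, merged into a 3D surface.

- **Automated tracing** (`extract_slice_contours`): each slice is
  smoothed in-plane (default σ = 0.4 µm), thresholded (Otsu over the
  whole channel by default), reduced to one connected component chosen
  by area rank, hole-filled, and traced as a sub-pixel iso-contour.
  The area-rank argument is what lets a single Laminin-1 channel supply
  both surfaces: the filled parenchymal tube is the largest component in
  every slice, the endothelial tube the second largest. Slices without a
  usable component are skipped and the longest consecutive run is kept.
  User-supplied contours (JSON) bypass extraction entirely.
- **Lofting** (`loft_surface`): every polygon is resampled to M
  vertices by arc length (default M = 64), consecutive rings are aligned
  by the cyclic offset minimising total vertex displacement, adjacent
  rings are joined by 2M triangles, and both end rings are capped with
  centroid fans. The result is watertight with outward normals (checked
  by edge-pairing and by the sign of the enclosed volume).

**End caps are included in the surface area.** Whether the interactive
contour surface includes its end caps is not documented anywhere we
could verify, so the closed-surface convention is fixed here and stated;
it contributes `2πr²` out of `2πrL + 2πr²` (≈ 5% for a typical r = 10 µm,
L = 60 µm venule) and cancels exactly in density *ratios*, which is how
densities are compared.

### The density statistic

`cln5_density` sums the CLN-5 intensity of voxels whose **centers** lie
inside the endothelial surface and whose intensity is at or above a
threshold, then divides by the surface area. Choices worth knowing:

- "Isosurface rendering" is operationalised as thresholded-voxel
  summation: the quantity used downstream is the total intensity, and
  rendering is only visualisation.
- The default threshold is Otsu computed over inside-mesh voxels only,
  because the interactive workflow's threshold is not recorded anywhere;
  a fixed intensity value can be supplied for full reproducibility.
- Membership is by voxel center with no partial-voxel weighting — a
  simple, testable rule consistent with the `point_inside` primitive
  (ray-parity with a 10⁻⁹ µm surface tie-break counting as inside).

### Nuclei as spot objects

`detect_nuclei` smooths the DRAQ5 channel with an isotropic 0.5 µm
Gaussian, thresholds, labels 26-connected components, and summarises
each component as a spot: intensity-weighted centroid, voxel count,
total intensity, and the volume-equivalent sphere diameter
`(6V/π)^(1/3)`. The conventional "> 3 µm" filter is read literally: the
inequality is strict, and a spot of exactly 3 µm is excluded. The
equivalent-sphere diameter (rather than a Feret diameter) is a
documented substitute for the interactive tool's unspecified spot-size
parameter. Splitting of touching nuclei is off by default — the manual
workflow specifies no splitting rule, and determinism wins; a
nearest-seed split around well-separated intensity maxima can be
enabled.

Spots are classified by centroid only: inside the endothelial mesh →
luminal; else inside the parenchymal mesh → perivascular; else
parenchymal. Parenchymal spots are reported but excluded from
vessel-associated counts. `spread_profile` then gives, per compartment
and axis, the median position and the maximum/minimum spread from the
median — the numbers a box-and-whisker "vantage" plot displays.

## The phantom generator

`generate_phantom` renders a straight venule along z: two concentric BM
tubes (Laminin-1), a junctional CLN-5 lattice on the endothelial tube,
and spherical nuclei in the three compartments, followed by Gaussian
blur, constant background, optional Gaussian/Poisson noise, and
quantisation to integer detector counts. Defaults emulate the imaging
regime the analysis is designed for: 60 z-slices at 1 µm with
sub-micron (0.3 µm) xy sampling.

Key modelling decisions:

- **Lattice with whole-segment gaps.** The CLN-5 signal is a lattice of
  circumferential rings (6 µm apart, snapped onto voxel-center planes)
  and 12 longitudinal lines, split into segments at their crossings.
  Junctional loss removes whole segments by seeded uniform sampling of
  a `1 - coverage` fraction, so gaps are contiguous stretches like real
  focal fragmentation, not salt-and-pepper voxel dropout. Each lattice
  voxel is owned by exactly one segment, which makes the retained voxel
  fraction track the requested coverage closely (within a few percent;
  the realised value is recorded in the ground truth).
- **Nucleus placement margins.** Nuclei are spheres (ellipsoids in
  index space) placed by rejection sampling with ≥ 1 µm clearance from
  both BM surfaces and ≥ 2.5 µm surface-to-surface separation between
  nuclei. The surface margin makes compartment ground truth
  unambiguous; the pairwise gap keeps blurred nuclei from merging into
  one component, so detection counts are attributable. Both margins are
  generator properties: real infiltrates can touch, and the package's
  detector would then need `split_touching`.
- **Grid width.** The default grid is 60×160×160 voxels at
  (1.0, 0.3, 0.3) µm — wider in xy than the minimal 128 px, so that
  parenchymal nuclei have room outside an inflamed-calibre parenchymal
  BM (18 µm radius) while respecting all margins.
- **Image formation.** Blur before noise; Poisson noise applied to
  signal + background; counts quantised to integers like a detector.
  The Gaussian blur is an idealisation of a confocal PSF — no Airy
  structure, no depth dependence, no photobleaching.
- **Free intensity parameters.** No channel intensity statistics are
  available to match, so channel gains (140–220), background (4) and
  noise defaults are free parameters chosen to give realistic
  contrast-to-noise; every validation that depends on them is a ratio
  or an ordering, not an absolute intensity.

**Presets.** Five named regimes differ only in junctional coverage and
nucleus counts: `naive` (coverage 1.0, no vessel-associated cells),
`wt_d9` (0.40), `wt_d16` (0.20, dense perivascular cuff),
`astro_ko_d16` (0.40, dense cuff but little parenchymal entry), and
`endo_ko_d16` (0.35, cells stalled in the lumen, sparse cuff). The
wild-type values encode the canonical ≈60% (early) and ≈80% (peak)
density losses; the astrocyte-knockout value encodes a ≈60% loss at
peak. The endothelial-knockout value is derived as a further ≈19% drop
from an assumed early-disease level of ≈0.43, keeping the qualitative
ranking (astrocyte-KO most intact at peak disease, wild type least,
endothelial-KO intermediate). These are scenario encodings for
validation, not measurements.

### What passing phantom tests does and does not show

The phantom shares the *statistical and geometric structure* the
analysis assumes — nested tubes, a fragmented junctional lattice,
compartmentalised nuclei, blur and shot noise — but not the
complexities of real tissue: curved and branching vessels, BM
fragmentation, anisotropic PSFs, autofluorescence, touching nuclei,
intensity inhomogeneity. Passing tests therefore demonstrate that the
*implementation* recovers known ground truth under the stated model;
they do not certify accuracy on arbitrary real images, where contour
quality and threshold choice still require inspection.

## Clinical-course analytics

Scores live on the integer 0–5 scale (5 = death, absorbing; half-point
scores are rejected at ingestion). The implemented definitions:

- onset = first day of two consecutive days with score ≥ 1; mice
  without onset enter the mean as `T + 1`;
- mean maximum score = mean of per-mouse maxima;
- disease index = 100 × (sum over days of the daily cohort-mean score)
  / mean day of onset — note it is *not* invariant to appending extra
  observation days, a documented sensitivity of the definition itself;
- ascending slope = OLS slope of the daily mean score from
  `ceiling(mean onset)` through the first day the series attains its
  maximum; a degenerate window is widened to two days so a flat
  post-onset course yields slope 0, and a window that does not fit
  returns `NA`.

Group tests follow the conventional battery: χ² on incidence (Fisher's
exact test when any expected count is below 5), Mann–Whitney on
severity, ANOVA with Bonferroni-adjusted pairwise t tests on onset.
Because "severity" is not pinned down anywhere, the Mann–Whitney is run
on per-mouse maximum scores; with ≤ 8 mice per group the two-sided p
value is computed exactly by enumerating all group assignments (base
R's `wilcox.test` cannot be exact under ties), otherwise the
tie-corrected normal approximation is used.

`simulate_cohort` encodes three disease profiles (onset mean/SD, ramp
rate, plateau) that reproduce the qualitative phenotypes: delayed onset
with otherwise normal course (endothelial knockout), reduced severity
and slower ramp (astrocyte knockout). Induction is modelled as fully
penetrant: active-immunisation EAE incidence is near-complete, and
leaving non-responders out keeps the onset-window metrics undistorted
by the `T + 1` substitution; incidence testing is exercised with
explicit contingency tables instead. When comparing ramp slopes,
"similar" (wild type vs endothelial knockout) is asserted as agreement
within 25% — a choice fixed before running the simulations.

## CFSE proliferation indices

With observed generation counts `N_i` and precursor back-calculation
`P_i = N_i / 2^i`, the five standard metrics are: % divided
(`ΣP_{i≥1}/ΣP`), division index (`Σ i·P_i / ΣP`), proliferation index
(`Σ i·P_i / ΣP_{i≥1}`), expansion index (`ΣN/ΣP`), replication index
(`ΣN_{i≥1}/ΣP_{i≥1}`). The last two ratios are undefined when nothing
divided and are returned as `NA`, never 0 — "no responders" and "no
proliferation" are different findings. Inputs are resolved per-generation
counts as a gating tool exports them; CFSE histogram peak
deconvolution is out of scope. The simulator draws division counts from
a zero-truncated Poisson, so precursor conservation
(`ΣP_i = n_precursors`) is exact by construction.

## Numerical choices and problem sizes

- Otsu thresholds come from a 256-level histogram over the observed
  range (via EBImage); degenerate (constant) samples return their value.
- Ray-parity inside tests use a fixed, minutely tilted ray so voxel
  centers never hit mesh edges exactly; triangles are bucketed by z so
  a lofted tube costs O(ring size) per query.
- Ring alignment is exhaustive over all M cyclic offsets — exact, and
  cheap at M ≤ 128.
- Meshes are validated watertight (every edge shared by exactly two
  consistently oriented triangles); a non-watertight mesh warns but
  still reports an area.
- Validation sizes were chosen to keep the full suite comfortable on a
  single CPU: 20 phantoms for classification recovery, 12 vessels per
  regime for the preset ordering, 200 mice per simulated cohort,
  10,000 points for the membership oracle. All are package choices and
  easily increased.

## Known limitations

- Straight, unbranched tubes only; no open-surface handling.
- The density statistic inherits the threshold's bias: absolute values
  are threshold-dependent, which is why the package reports and tests
  ratios and orderings.
- Compartment classification is centroid-based; a nucleus straddling a
  BM surface is assigned wholly to one side.
- The clinical simulator is a scenario generator for validating
  analytics, not a fitted disease model.
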