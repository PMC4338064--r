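---
title: "Quantifying cells and EPS in biofilm lambda-Z-stacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cells and EPS in biofilm lambda-Z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter and their
defaults, what the synthetic generators do and do not emulate, and the
design choices made where the methodology left genuine latitude. It
states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The measurement problem

Drinking-water biofilms are thin, patchy films of cells embedded in an
EPS matrix of carbohydrates and proteins, grown on rough plastic pipe
walls. Quantifying the three components concurrently requires a
triple-stain confocal acquisition in lambda mode: every pixel of every
focal slice carries a binned emission spectrum (here 12-bit intensities
over equally spaced wavelength bins), because the stains' emission
spectra overlap each other and the autofluorescence of the plastic and
biomass. The separation is therefore computational — linear spectral
unmixing — and everything downstream (thresholding, coverage, volume,
stratification) operates on the unmixed per-component images.

## 2. Emission fingerprints and unmixing

**Fingerprints.** A component's fingerprint is its characteristic
emission spectrum over the acquisition's lambda bins. Fingerprints are
measured from control acquisitions (`extract_spectrum()` averages a
voxel region per bin) and replicate spectra are reduced to one
representative by `medoid_spectrum()`. The selection of a "median"
spectrum from replicates is not fully specified by a graphical
procedure, so the package makes it concrete: spectra are unit-sum
normalised (shape, not brightness, is what matters) and the **medoid** —
the member minimising summed Euclidean distance to all others — is
returned. A pointwise median per bin is available behind
`method = "pointwise"`, but it can fabricate a spectrum no replicate
ever exhibited, which is why it is not the default. Ties break by input
order, making the operation deterministic and permutation-invariant up
to that rule.

**Unmixing.** Each pixel solves observed ≈ Σ_c a_c·S_c with a_c ≥ 0.
Non-negativity is imposed by default because abundances are physical
concentrations; whether the original instrument software constrained
its solution is unknowable, so `nonneg = FALSE` gives the unconstrained
comparison. The NNLS solve is exact, not iterative: with k ≤ 5
endmembers the optimum of this convex problem lies on one of the 2^k
coefficient-support sets, and all of them are evaluated in closed form,
vectorised across every pixel of a slice simultaneously. The test suite
checks this solver pixel-by-pixel against an independent active-set
implementation. Autofluorescence, when supplied, is always an endmember;
its coefficient is reported but never counted as biofilm. The full
recorded lambda range enters the fit — no band selection.

## 3. From abundances to structure metrics

**Median filter.** A 3×3 per-slice median precedes all quantification
(far-red channels are shot-noise heavy). Edges replicate the nearest
pixel; the implementation is a vectorised 19-exchange median network,
tested against a brute-force sort-of-nine oracle.

**Threshold selection.** Stain-positivity needs an intensity threshold
on the 1–4095 scale. The automated procedure: (i) compute each field of
view's total coverage at every threshold (one cumulative histogram per
slice — not 4095 thresholding passes); (ii) normalise each curve by its
own maximum; (iii) find the widest contiguous threshold window in which
a Kruskal–Wallis test across thresholds (observations = per-FOV
normalised coverages) fails to reject — the plateau where the answer
does not depend on the threshold; (iv) return the plateau's median
threshold. The methodology being re-implemented states only that a
Kruskal–Wallis test located "the range of thresholds between which there
was no difference"; the windowed search with `alpha = 0.05`,
`min_window = 10` evaluated thresholds and a subsampling `step = 8` is
this package's concrete realisation, and all three are configuration
keys. Thresholds whose normalised coverage is saturated or zero in every
FOV are excluded as candidates, which reproduces the expected behaviour
on degenerate (identical-replicate) ensembles. Unmixed float abundances
are min-max rescaled to integers 0–4095 first, so the threshold domain
applies verbatim; offset and scale land in the provenance log.

**Volume.** volume = Δz · ImageArea · Σ AC_i over the stack's slices,
with AC_i the per-slice stain-positive fraction. The printed form of
this equation in the source methodology is internally inconsistent (an
optical slice of 4.7 µm with a "420 µm²" image area cannot produce the
reported 10⁵–10⁶ µm³ volumes in 10–20 slices). The package resolves it
as: ImageArea is the full 420 µm × 420 µm field (176,400 µm²), and Δz
is the 2.35 µm *acquisition interval* — half the 4.7 µm optical section,
the Nyquist spacing at which adjacent optical sections overlap by half,
so counting Δz per slice avoids double-counting. Both factors are
explicit arguments (`depth_step_um`, `image_area_um2`), so the literal
reading is one setting away. Volumes are *relative* to the detection
threshold, as in any threshold-based biovolume.

**Alignment and peak location.** Stack sizes differ between FOVs, so
profiles are aligned by labelling the slice of maximum cell coverage
slice 0 (cells anchor the alignment because they produce the EPS);
negative indices run toward the bulk water, positive toward the
substratum. Peak ties break toward the substratum — attached cells seed
growth at the wall. The plotting axis multiplies aligned indices by
4.7 µm per slice by default (`plot_depth_step_um`), matching the
convention of area-distribution plots even though volumes use 2.35 µm;
both are configurable, and alignment is idempotent.

**Spread.** spread = volume / (peak coverage · ImageArea). For a uniform
profile over k slices this is Δz·k *independent of the coverage level*,
which is exactly why it is robust to uneven substrata: relief moves
coverage between slices but leaves the ratio intact. The acceptance
suite verifies this identity over randomised coverage levels, and the
end-to-end test exercises it over a randomised 30 µm-relief substratum.

**Ratios and statistics.** EPS (= carbohydrates + proteins) and total
volumes are summed per FOV *before* any averaging; ratios are formed per
FOV and summarised by median and range (these metrics are routinely
non-normal — a Shapiro-Wilk screen is included). Two groups are compared
with the Wilcoxon rank-sum test (W and p reported), more with
Kruskal–Wallis. A zero-denominator ratio is flagged undefined and
excluded from summaries with an exclusion count, never silently zeroed.

## 4. The community-fingerprint chain

Peaks below 50 fluorescence units are noise-filtered (strictly greater
survives), sizes outside the marker window (50–500 nt for terminal
restriction fragments, 94–827 nt for ARISA) are dropped. Alignment uses
a 0.5 nt confidence interval in two passes: within-sample merge (areas
summed), then consensus bins grown in ascending size order with a
running-mean consensus — deterministic, since the original web tool's
tie behaviour is unknowable. Relative abundances use peak *area*
(heights are carried but unused); fragments contributing < 0.5% are
excluded and rows are then re-normalised — the source text says
"normalised to exclude", which this package reads as
exclusion-then-renormalisation, with `renormalise = FALSE` available.
Entries at exactly 0.5% are retained (the rule is strictly less than).

Similarities are Bray–Curtis on square-root transformed abundances,
reported in percent. ANOSIM follows Clarke's rank form
R = (r̄_between − r̄_within)/(n(n−1)/4), with the label permutations
enumerated exhaustively whenever n! ≤ `n_perm` — p-values at small n are
exact, not sampled. SIMPER decomposes the average between-group
dissimilarity into per-bin terms that sum to it exactly (asserted to
1e-9), and reports within-group average similarity ("similarity between
replicates"). SIMPROF tests each dendrogram node (group-average
clustering) top-down: the π statistic is the departure of the node's
ordered similarities from their mean under independent within-bin
permutation; 20,000 permutations by default as in the original
workflow, 1,000 for the expected profile; nodes failing to reject are
flagged homogeneous, as are all nodes below them. ANOSIM's default
9,999 permutations is this package's choice (the source does not state
one); every permutation test takes a seed. Diversity indices are
richness, Shannon H′ (natural log) and Pielou J′ = H′/ln S, undefined
(flagged NA) at S = 1; index comparisons use Welch's t — hence
fractional degrees of freedom.

One calibration caveat the test design reflects: SIMPROF's null permutes
bins independently, so data carrying built-in row constraints (e.g.
compositions renormalised to 1) violate that null by construction and
inflate rejection slightly. Type-I calibration is therefore asserted on
exchangeable raw-abundance matrices; on real relative-abundance data
SIMPROF should be read as mildly liberal.

Local Southern sizing fits the reciprocal mobility model
L = c/(m − m₀) + L₀ exactly through each of the two overlapping
standard triplets flanking a query and averages the two fitted sizes;
queries must be bracketed by two standards on each side.

## 5. What the synthetic generators emulate

`generate_biofilm_stack()` reproduces the acquisition conditions of the
real protocol: a 420 µm square field at 832×832 pixels (0.505 µm/px),
2.35 µm slice interval, 4.7 µm optical sections, 12-bit intensities,
10.7 nm spectral bins spanning 500.9–704.2 nm (19 bins), a rough
substratum (30 µm relief by default, within the 20–80 µm range reported
for these plastics), EPS peaking above the cells (carbohydrate +1 slice,
protein +3 toward the water), and carbohydrate-dominant composition
(lateral presence fractions 0.92/0.65/0.18 for
carbohydrate/cells/protein). Endmember spectra are synthetic Gaussians
at the adopted triple-stain emission maxima — 673 nm (far-red nucleic
acid stain, cells), 580 nm (rhodamine lectin, carbohydrates), 520 nm
(FITC, proteins) — plus a broad autofluorescence; synthetic rather than
digitised real curves keeps the spectral overlap controllable and the
package self-contained. Noise is Poisson shot noise plus Gaussian read
noise (sd 6), applied after the truth masks are recorded.

The biofilm body is columnar: each pixel column is filled from the
substratum surface up to a nearly level canopy (biofilms smooth the
topography they colonise), pinned at the 0.85 quantile of the
substratum height distribution so it always intersects the relief, and
snapped midway between slice heights so the truth peak slice is never
split across a slice boundary by aliasing. Component layers are pure
columnar shifts of the cell layer with independent lateral masks, which
makes the configured peak offsets exact in the noise-free coverage
curves rather than approximate. Truth volumes are exact voxel counts
times voxel volume — every acceptance comparison is against these,
never against re-measured values.

What the generator does **not** emulate: internal biofilm porosity and
density gradients, partial-volume blur between overlapping optical
sections, stain cross-reactivity or photobleaching, lateral drift, and
mushroom/streamer morphologies. Passing the recovery tests therefore
demonstrates that the analysis chain is unbiased under the stated image
formation model, not that any real biofilm obeys that model. The default
scene is also thinner (spread ≈ 6–7 µm) than a mature 28-day biofilm;
the stratification and composition ordering, not absolute thickness, are
the emulated features.

`generate_fingerprint_dataset()` produces per-group fragment size sets
at least 2 nt apart (unambiguous binning), lognormal areas, Gaussian
size jitter (sd 0.1 nt, warned above 0.25 nt where bins may merge), and
sub-threshold baseline peaks. `reynolds_number()` is the facility
hydraulics helper, Re = 4Q/(πDν), with water's kinematic viscosity at
16 °C defaulting to 1.11×10⁻⁶ m²/s from standard tables. The wall shear
stress quoted alongside the facility's flow condition is *not*
reproducible from smooth-pipe (Blasius) arithmetic at these parameters
and is deliberately not used as an oracle.

## 6. Numerical choices and degenerate inputs

- Exact NNLS support enumeration is capped at 12 endmembers; singular
  sub-libraries (reciprocal condition < 1e-12) are skipped.
- `coverage_vs_threshold` demands integer 0–4095 input and rescales
  (with a message) otherwise; coverage is exactly non-increasing in the
  threshold by construction.
- Kruskal–Wallis windows in which every observation ties (exact
  plateaus) are treated as failing to reject (p = 1), which is what the
  degenerate identical-FOV ensemble requires.
- All-zero profiles: peak location is NA with a warning; an all-zero
  *cell* profile is an error (nothing to align to); zero peak coverage
  makes spread an error, zero denominators make ratios NA-flagged.
- Permutation p-values use (exceedances + 1)/(n_perm + 1) except under
  exhaustive enumeration, where the count is exact and includes the
  identity.
- Stack geometry is never inferred from content: the z-orientation
  (which end faces the water) must be declared, and missing geometry on
  read raises instead of defaulting. CLI defaults (2.35/4.7 µm, 420 µm
  field) are logged with provenance whenever they are applied.

## 7. Problem sizes used in validation

The test suite and acceptance script run the full-geometry default scene
(832×832×~20 slices×19 bins, ≈ 2.6×10⁸ voxel-bins) once and cache its
summary; unit tests use 48–256 px scenes. Permutation calibration uses
200 null datasets at 1,000 permutations; SIMPROF's default 20,000
permutations is retained for analysis use but reduced in calibration
loops. These sizes are the package's validation choices: large enough
that subset noise in coverage curves (≈ 0.007 at the default lateral
texture) sits well below the engineered peak margins, small enough to
re-run routinely.

## 8. Known limitations

- The threshold plateau search is one defensible reading of a partially
  specified procedure; different window rules can select different (but
  plateau-interior) thresholds.
- Volume calibration (2.35 vs 4.7 µm per slice) is a declared
  convention, not recoverable from the source text; comparisons between
  datasets must hold it fixed.
- SIMPROF on compositional data is mildly anti-conservative (see §4).
- The CLI reads plain TIFF plus YAML sidecar or OME-XML descriptions;
  exotic OME layouts (interleaved dimensions, multi-series files) are
  out of scope.
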