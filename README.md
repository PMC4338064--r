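# biofilmq

Quantification of cells and extracellular polymeric substances (EPS) in
drinking-water biofilms from confocal lambda-Z-stacks, plus the matching
microbial community-fingerprint statistics.

Biofilms in drinking-water distribution pipes are a matrix of cells
embedded in EPS — mostly carbohydrates and proteins. Quantifying all
three components *concurrently*, through the depth of the biofilm, takes
a triple-stain confocal acquisition in lambda mode: at every pixel of
every focal slice a full binned emission spectrum is recorded, so the
overlapping fluorophores (and the substratum/biomass autofluorescence)
can be separated computationally rather than optically. `biofilmq`
implements that analysis chain for R users working with such data, plus
seeded synthetic generators so the whole pipeline can be validated
end-to-end with exact ground truth and no instrument.

## The method

**Physical structure.** Each lambda-Z-stack (12-bit intensities, 0–4095)
is unmixed per pixel by non-negative least squares against a library of
emission fingerprints S_c:

&nbsp;&nbsp;&nbsp;&nbsp; observed(λ) ≈ Σ_c a_c · S_c(λ),&nbsp; a_c ≥ 0,

with autofluorescence always an explicit endmember whose coefficient is
excluded from biofilm metrics. Unmixed component images are 3×3 median
filtered, rescaled to the 1–4095 threshold domain, and thresholded at a
value selected automatically: each field of view's total
coverage-versus-threshold curve is normalised by its own maximum, a
Kruskal–Wallis test across thresholds locates the widest plateau where
coverage is threshold-insensitive, and the plateau's median threshold is
used. From the per-slice area coverage fraction AC_i (stain-positive
pixels / total pixels) the package computes

- **volume** (µm³) = Δz · ImageArea · Σ_i AC_i (relative biovolume;
  Δz = 2.35 µm acquisition interval by default, ImageArea = 176,400 µm²
  for a 420 µm square field),
- **peak location** — slices are aligned so the slice of maximum *cell*
  coverage is slice 0 (negative indices toward the bulk water), and each
  component's peak slice is reported on that axis,
- **spread** (µm) = volume / (peak coverage · ImageArea), a thickness
  proxy that equals Δz·k for any uniform k-slice profile regardless of
  coverage level — hence robust to uneven plastic substrata,
- EPS (= carbohydrate + protein) and total volumes, composition ratios
  per field of view, summarised by median and range, and Wilcoxon /
  Kruskal–Wallis group comparisons.

**Community fingerprints.** T-RFLP/ARISA peak tables are filtered
(heights > 50 fluorescence units, marker size windows 50–500 nt /
94–827 nt), aligned into consensus bins with a 0.5 nt confidence
interval, converted to relative abundances with fragments contributing
< 0.5% excluded, square-root transformed, and compared by Bray–Curtis
similarity (in %). On top of that: richness / Shannon H′ / Pielou J′,
ANOSIM (with exact exhaustive p-values at small n), SIMPER
decomposition, SIMPROF-flagged group-average clustering (Newick export),
Welch t-tests on the indices, and Local Southern fragment sizing.

## Worked example

```r
library(biofilmq)

# a full-geometry synthetic acquisition (420 um field, 832x832 px,
# 19 lambda bins, Poisson + read noise) with exact voxel ground truth
sc  <- generate_biofilm_stack(seed = 1)
cfg <- resolve_config(quiet = TRUE)
res <- run_quantify(list(sc$stack), sc$library, cfg)

res$metrics
#>       component volume_um3 spread_um peak_location area_coverage_peak fov
#> 1         cells   542885.4  6.430683             0          0.4785777   1
#> 2 carbohydrates   772207.6  6.512940            -1          0.6721379   1
#> 3      proteins   146502.7  6.501794            -3          0.1277361   1

sc$truth$volumes_um3
#>         cells carbohydrates      proteins
#>      545406.0      772138.7      150477.8
```

Reading the output: carbohydrates dominate the biofilm by volume,
proteins are the sparsest component, and the carbohydrate and protein
coverage peaks sit 1 and 3 slices above the cell peak (toward the bulk
water) — exactly the stratification the generator was asked for
(`sc$truth$peak_offsets`). Recovered volumes land within a few percent
of the voxel-count ground truth.

For fingerprints:

```r
ds  <- generate_fingerprint_dataset(n_groups = 2, seed = 1)
res <- run_fingerprint(ds$profiles, ds$groups,
                       resolve_config(quiet = TRUE))
res$anosim$R        # 1: the two groups share no fragments
res$indices         # richness, Shannon, Pielou per sample
```

A thin command-line wrapper over the same functions ships at
`inst/exec/biofilmq` (`quantify`, `fingerprint`, `simulate`, `report`).

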