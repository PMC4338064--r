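# Shared fixtures.  The full-acquisition-geometry scene (420 um field at
# 832 x 832 px) is expensive, so its pipeline is run once and only the
# small summary numbers are cached for the tests that need them.

.fixture_env <- new.env(parent = emptyenv())

# evaluate expr under a private seed, restoring the RNG state afterwards
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# A small lambda stack with known content for I/O and spectrum tests.
small_stack <- function(nz = 3L, nl = 5L, ny = 8L, nx = 8L, seed = 101) {
  set.seed(seed)
  arr <- array(sample(0:4095, nz * nl * ny * nx, replace = TRUE),
               dim = c(nz, nl, ny, nx))
  bins <- lambda_bins(c(650.7, 704.2), nl)
  lambda_zstack(arr,
                slice_interval_um = 2.35, optical_slice_um = 4.7,
                lambda_bin_centres_nm = bins,
                lambda_bin_width_nm = attr(bins, "bin_width_nm"),
                pixel_size_um = 0.505, water_side = "first")
}

# geometry list usable as `source` for component_zstack()
fake_geometry <- function(pixel_size_um = 0.505) {
  list(slice_interval_um = 2.35, optical_slice_um = 4.7,
       pixel_size_um = pixel_size_um, water_side = "first")
}

# Two-level component stack: background `lo` everywhere, `hi` on the top
# half of every slice; the coverage plateau under thresholding is exactly
# (lo+1)..hi at coverage 0.5.
two_level_stack <- function(nz = 3L, n = 32L, lo = 100L, hi = 3000L) {
  a <- array(lo, dim = c(nz, n, n))
  a[, seq_len(n / 2L), ] <- hi
  component_zstack(a, "cells", fake_geometry())
}

# Small synthetic scene (desk scale) shared by several unit tests.
small_scene <- function() {
  if (is.null(.fixture_env$small_scene))
    .fixture_env$small_scene <- generate_biofilm_stack(
      list(nx = 128L, ny = 128L, field_um = 64.6), seed = 7)
  .fixture_env$small_scene
}

# Full default scene, pipeline run once; only summary numbers kept.
default_scene_summary <- function(seed = 1) {
  if (!is.null(.fixture_env$default_summary))
    return(.fixture_env$default_summary)
  sc <- generate_biofilm_stack(seed = seed)
  um <- unmix_stack(sc$stack, sc$library)
  truth_cells <- sc$truth$masks$cells * sc$truth$params$amplitude[["cells"]]
  noisy_cor <- stats::cor(as.vector(um$components$cells$abundances),
                          as.vector(truth_cells))
  rm(truth_cells)
  comps <- lapply(um$components[c("cells", "carbohydrates", "proteins")],
                  function(x) rescale_to_12bit(median_filter_stack(x)))
  rm(um); gc(FALSE)
  thresholds <- vapply(comps, function(cc)
    as.integer(suppressWarnings(
      select_threshold(list(coverage_vs_threshold(cc)), step = 8L))),
    integer(1L))
  masks <- Map(apply_threshold, comps, thresholds)
  rm(comps); gc(FALSE)
  profiles <- align_to_cell_peak(lapply(masks, area_profile))
  rm(masks); gc(FALSE)
  metrics <- structure_metrics(profiles)
  out <- list(
    metrics = metrics,
    thresholds = thresholds,
    truth_volumes = sc$truth$volumes_um3,
    truth_offsets = sc$truth$peak_offsets,
    noisy_unmixing_cor = noisy_cor,
    n_voxels = prod(dim(sc$stack$intensities)[c(1, 3, 4)])
  )
  .fixture_env$default_summary <- out
  out
}
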