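# Seeded generators: lambda-Z-stacks of a stratified biofilm over a rough
# substratum with exact voxel ground truth, fragment-peak tables with known
# group structure, and a pipe-hydraulics helper.  All generators are pure
# functions of (parameters, seed).

#' Default synthetic emission fingerprints
#'
#' Gaussian emission profiles for the adopted triple-stain combination —
#' cells (far-red nucleic acid stain, maximum 673 nm), proteins (FITC-like,
#' 520 nm), carbohydrates (rhodamine lectin-like, 580 nm) — plus a broad
#' autofluorescence endmember, evaluated on the given bin centres and
#' unit-max scaled.  Synthetic rather than digitised real curves: the
#' overlap structure stays controllable and the package self-contained.
#'
#' @param lambda_nm bin centres (nm).
#' @param peaks_nm named numeric of emission maxima.
#' @param sigma_nm Gaussian width of the stain spectra (default 25 nm).
#' @param auto_centre_nm,auto_sigma_nm autofluorescence centre/width.
#' @return A [fingerprint_library()].
#' @export
default_spectra <- function(lambda_nm,
                            peaks_nm = c(cells = 673, carbohydrates = 580,
                                         proteins = 520),
                            sigma_nm = 25,
                            auto_centre_nm = 560, auto_sigma_nm = 90) {
  gauss <- function(mu, sd) {
    v <- exp(-((lambda_nm - mu)^2) / (2 * sd^2))
    v / max(v)
  }
  spectra <- c(
    lapply(names(peaks_nm), function(id)
      emission_spectrum(id, gauss(peaks_nm[[id]], sigma_nm),
                        normalisation = "unit-max")),
    list(emission_spectrum("autofluorescence",
                           gauss(auto_centre_nm, auto_sigma_nm),
                           normalisation = "unit-max")))
  fingerprint_library(spectra)
}

# Gaussian blur by circular (FFT) convolution: band-limits white noise
# with stationary variance everywhere (no edge artifacts, which matter
# because the result is min-max rescaled)
blur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  ny <- nrow(m); nx <- ncol(m)
  gy <- stats::dnorm(pmin(0:(ny - 1L), ny - 0:(ny - 1L)), sd = sigma_px)
  gx <- stats::dnorm(pmin(0:(nx - 1L), nx - 0:(nx - 1L)), sd = sigma_px)
  k <- outer(gy, gx)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (ny * nx)
}

#' Generate a rough substratum height map
#'
#' Smooth band-limited random relief emulating the machined plastic
#' surface biofilms grow on (HDPE roughness is commonly modelled at 20 um;
#' up to 80 um relief has been measured under mature biofilms).  The map
#' is rescaled so its peak-to-trough amplitude is exactly
#' `amplitude_um`; heights are >= 0 (0 = deepest trough).
#'
#' @param nx,ny map size in pixels.
#' @param amplitude_um peak-to-trough relief (0--80 um sensible range).
#' @param correlation_px lateral smoothing scale (default 40 px).
#' @param seed RNG seed.
#' @return ny x nx numeric matrix of heights (um).
#' @export
generate_substratum <- function(nx, ny, amplitude_um = 20,
                                correlation_px = 40, seed = 1) {
  if (amplitude_um < 0 || amplitude_um > 80)
    warning("relief amplitude outside the 0-80 um range measured in pipes")
  with_rng(seed, function() {
    if (amplitude_um == 0) return(matrix(0, ny, nx))
    z <- matrix(stats::rnorm(nx * ny), ny, nx)
    z <- blur2d(z, correlation_px / 3)
    rng <- range(z)
    (z - rng[1L]) / (rng[2L] - rng[1L]) * amplitude_um
  })
}

#' Default parameters of the synthetic biofilm scene
#'
#' The acquisition geometry mirrors the real protocol: 420 um square field
#' at 832 x 832 pixels (0.505 um/px), 2.35 um slice interval, 4.7 um
#' optical sections, 12-bit intensities, 10.7 nm spectral bins spanning
#' 500.9--704.2 nm (19 bins).  The biofilm fills the troughs of a rough
#' substratum (30 um relief) up to a nearly level canopy pinned inside the
#' relief range, and is stratified: the carbohydrate coverage peak sits 1
#' slice above the cells and the protein peak 3 slices above (toward the
#' bulk water); carbohydrates are the dominant component by volume, then
#' cells, then patchy sparse proteins.
#'
#' @return named list of generator parameters.
#' @export
default_scene_params <- function() {
  list(
    nx = 832L, ny = 832L,
    field_um = 420,
    slice_interval_um = 2.35,
    optical_slice_um = 4.7,
    lambda_range_nm = c(500.9, 704.2),
    n_lambda = 19L,
    relief_um = 30,
    relief_correlation_px = 40,
    # the biofilm fills from the rough substratum up to a nearly level
    # canopy (biofilms smooth the topography they grow on); the canopy is
    # pinned to a quantile of the substratum height distribution so it
    # always intersects the relief, giving the coverage curve one sharply
    # defined peak; bumps standing above the canopy keep a thin cap
    canopy_quantile = 0.85,
    canopy_above_um = 0,       # extra canopy height above that quantile
    canopy_um = NULL,          # absolute canopy height overrides both
    canopy_sd_um = 0.5,
    min_thickness_um = 2,
    texture_px = 12,
    # lateral presence fractions (area coverage at the component's peak)
    lateral_cover = c(cells = 0.65, carbohydrates = 0.92, proteins = 0.18),
    # slice offsets of the coverage peak relative to cells
    # (negative = toward bulk water); layers are pure columnar shifts of
    # the cell layer so these offsets are exact in the coverage curves,
    # and volume ranking (carbohydrates > cells > proteins) follows from
    # the lateral presence fractions alone
    peak_offset = c(carbohydrates = -1L, proteins = -3L),
    # endmember amplitudes on the 12-bit scale
    amplitude = c(cells = 2200, carbohydrates = 2500, proteins = 1600),
    autofluorescence_level = 60,
    noise = "poisson",          # "poisson", "none"
    read_noise_sd = 6
  )
}

#' Generate a synthetic biofilm lambda-Z-stack with ground truth
#'
#' Builds per-component occupancy masks over a rough substratum (see
#' [default_scene_params()] for the scene layout), mixes them through the
#' endmember spectra into a 12-bit lambda-Z-stack, and adds Poisson shot
#' noise plus Gaussian read noise.  Truth (exact voxel masks, volumes,
#' peak offsets, the substratum map and all parameters) is recorded
#' before noise.
#'
#' Component occupancy is columnar: in each pixel column the cell layer
#' fills the slices from the substratum surface up to a smoothly varying
#' local thickness; carbohydrate and protein layers are the same column
#' occupancy shifted toward the bulk water by the configured peak offsets
#' (and masked laterally), so the true coverage-peak offsets are exact by
#' construction.
#'
#' @param params list as from [default_scene_params()]; entries override
#'   the defaults.
#' @param seed RNG seed.
#' @return list with `stack` (a `lambda_zstack`), `truth` (masks (z,y,x)
#'   per component, `volumes_um3`, `peak_offsets`, `substratum_um`,
#'   `params`, `seed`) and `library` (the generating
#'   `fingerprint_library`).
#' @export
generate_biofilm_stack <- function(params = list(), seed = 1) {
  p <- utils::modifyList(default_scene_params(), params)
  nx <- p$nx; ny <- p$ny
  pixel_um <- p$field_um / nx
  lambda <- lambda_bins(p$lambda_range_nm, p$n_lambda)
  lib <- default_spectra(as.numeric(lambda))

  with_rng(seed, function() {
    sub_um <- generate_substratum(nx, ny, p$relief_um,
                                  p$relief_correlation_px,
                                  seed = NULL)  # inherits this RNG stream
    canopy_level <- if (is.null(p$canopy_um))
      stats::quantile(sub_um, p$canopy_quantile) + p$canopy_above_um
    else p$canopy_um
    # snap the canopy midway between slice heights: a canopy sitting on a
    # slice boundary would split the peak slice's coverage between two
    # slices and leave the truth peak location ill-defined
    canopy_level <- (floor(canopy_level / p$slice_interval_um) + 0.5) *
      p$slice_interval_um
    cfield <- blur2d(matrix(stats::rnorm(nx * ny), ny, nx), p$texture_px / 3)
    canopy <- canopy_level +
      (cfield - mean(cfield)) / stats::sd(cfield) * p$canopy_sd_um
    lateral <- lapply(c(cells = "cells", carbohydrates = "carbohydrates",
                        proteins = "proteins"), function(id) {
      z <- blur2d(matrix(stats::rnorm(nx * ny), ny, nx), p$texture_px / 3)
      z <= stats::quantile(z, p$lateral_cover[[id]])
    })

    surf <- sub_um                              # top of plastic
    top_cells <- pmax(canopy, surf + p$min_thickness_um)

    # z grid: slice 1 = bulk water side; heights measured from the stack
    # bottom.  Depth covers the canopy, the upward-shifted EPS layers and
    # two slices of headroom.
    max_shift <- max(0L, -min(p$peak_offset))
    depth_um <- max(top_cells) + (max_shift + 2) * p$slice_interval_um
    nz <- as.integer(ceiling(depth_um / p$slice_interval_um)) + 1L
    slice_height <- (nz - seq_len(nz)) * p$slice_interval_um
    occupies <- function(shift_slices, lat_mask) {
      # occupied where slice height in (surf, top] after shifting the
      # whole column up by shift_slices * interval (negative = toward
      # bulk water); a pure shift keeps the coverage-peak offset exact
      shift_um <- -shift_slices * p$slice_interval_um
      lo <- surf + shift_um
      hi <- top_cells + shift_um
      arr <- array(FALSE, dim = c(nz, ny, nx))
      for (z in seq_len(nz)) {
        h <- slice_height[z]
        arr[z, , ] <- (h > lo) & (h <= hi) & lat_mask
      }
      arr
    }
    masks <- list(
      cells = occupies(0L, lateral$cells),
      carbohydrates = occupies(p$peak_offset[["carbohydrates"]],
                               lateral$carbohydrates),
      proteins = occupies(p$peak_offset[["proteins"]], lateral$proteins))

    voxel_um3 <- pixel_um^2 * p$slice_interval_um
    volumes <- vapply(masks, function(m) sum(m) * voxel_um3, numeric(1L))

    S <- lib$matrix   # bins x 4 (cells, carbohydrates, proteins, auto)
    amp <- p$amplitude
    arr <- array(0L, dim = c(nz, p$n_lambda, ny, nx))
    for (z in seq_len(nz)) {
      A <- rbind(cells = as.numeric(masks$cells[z, , ]) * amp[["cells"]],
                 carbohydrates = as.numeric(masks$carbohydrates[z, , ]) *
                   amp[["carbohydrates"]],
                 proteins = as.numeric(masks$proteins[z, , ]) *
                   amp[["proteins"]],
                 autofluorescence = p$autofluorescence_level)
      M <- S %*% A                       # bins x pixels, noise-free
      if (identical(p$noise, "poisson")) {
        M[] <- stats::rpois(length(M), M)
        if (p$read_noise_sd > 0)
          M[] <- M + stats::rnorm(length(M), 0, p$read_noise_sd)
      }
      M <- round(pmin(pmax(M, 0), MAX_INTENSITY))
      arr[z, , , ] <- as.integer(M)
    }
    stack <- lambda_zstack(arr,
                           slice_interval_um = p$slice_interval_um,
                           optical_slice_um = p$optical_slice_um,
                           lambda_bin_centres_nm = as.numeric(lambda),
                           lambda_bin_width_nm = attr(lambda, "bin_width_nm"),
                           pixel_size_um = pixel_um,
                           water_side = "first")
    truth <- list(masks = masks, volumes_um3 = volumes,
                  peak_offsets = p$peak_offset,
                  substratum_um = sub_um, params = p, seed = seed)
    list(stack = stack, truth = truth, library = lib)
  })
}

#' Generate a synthetic fingerprint dataset with known group structure
#'
#' Emulates T-RFLP/ARISA peak tables: each group has its own set of true
#' fragment sizes (minimum 2 nt apart so alignment bins are unambiguous),
#' per-sample abundances are lognormal around fragment-specific means,
#' measured sizes carry Gaussian jitter, and sub-threshold baseline noise
#' peaks (height below the 50-unit cutoff) are sprinkled in.
#'
#' @param n_groups number of groups (default 2).
#' @param samples_per_group samples per group (default 5).
#' @param fragments_per_group true fragments per group (default 15).
#' @param shared_fragments fragments common to all groups (default 0).
#' @param marker "TRF" or "ARISA".
#' @param jitter_sd size jitter sd in nt (default 0.1; warned about at
#'   >= half the 0.5 nt alignment interval).
#' @param abundance_sdlog lognormal within-fragment variability.
#' @param n_noise_peaks sub-threshold noise peaks per sample.
#' @param equal_abundance all true fragments equally abundant (for
#'   evenness checks).
#' @param seed RNG seed.
#' @return list: `profiles` (list of `fingerprint_profile`), `groups`
#'   (factor), `truth` (true sizes per group, expected richness per
#'   sample).
#' @export
generate_fingerprint_dataset <- function(n_groups = 2L,
                                         samples_per_group = 5L,
                                         fragments_per_group = 15L,
                                         shared_fragments = 0L,
                                         marker = "TRF",
                                         jitter_sd = 0.1,
                                         abundance_sdlog = 0.4,
                                         n_noise_peaks = 10L,
                                         equal_abundance = FALSE,
                                         seed = 1) {
  if (jitter_sd >= 0.25)
    warning("size jitter sd >= half the 0.5 nt alignment interval; ",
            "bins may merge")
  window <- marker_size_window(marker)
  with_rng(seed, function() {
    # candidate sizes on a 2 nt lattice keeps bins >= 2 nt apart
    lattice <- seq(window[1L] + 1, window[2L] - 1, by = 2)
    n_need <- shared_fragments + n_groups * fragments_per_group
    if (n_need > length(lattice)) stop("too many fragments for the window")
    sizes_all <- sort(sample(lattice, n_need))
    shared <- if (shared_fragments > 0L) sizes_all[seq_len(shared_fragments)]
              else numeric(0)
    rest <- setdiff(sizes_all, shared)
    group_sizes <- split(rest, rep(seq_len(n_groups),
                                   each = fragments_per_group))
    group_sizes <- lapply(group_sizes, function(s) sort(c(shared, s)))

    groups <- factor(rep(seq_len(n_groups), each = samples_per_group))
    profiles <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      g <- as.integer(groups[i])
      true_sizes <- group_sizes[[g]]
      meanlog <- if (equal_abundance) rep(log(5000), length(true_sizes))
                 else log(5000) + stats::rnorm(length(true_sizes), 0, 0.8)
      area <- stats::rlnorm(length(true_sizes), meanlog,
                            if (equal_abundance) 0 else abundance_sdlog)
      height <- pmax(area / 8, 51)    # real signal is always above cutoff
      size <- true_sizes + stats::rnorm(length(true_sizes), 0, jitter_sd)
      peaks <- data.frame(size_nt = size, height = height, area = area)
      if (n_noise_peaks > 0L) {
        noise <- data.frame(
          size_nt = stats::runif(n_noise_peaks, window[1L], window[2L]),
          height = stats::runif(n_noise_peaks, 5, 49),
          area = stats::runif(n_noise_peaks, 10, 200))
        peaks <- rbind(peaks, noise)
      }
      profiles[[i]] <- fingerprint_profile(sprintf("g%d_s%d", g,
                                                   i - (g - 1L) *
                                                     samples_per_group),
                                           peaks, marker = marker)
    }
    truth <- list(group_sizes = group_sizes,
                  richness = vapply(as.integer(groups), function(g)
                    length(group_sizes[[g]]), integer(1L)))
    list(profiles = profiles, groups = groups, truth = truth)
  })
}

#' Reynolds number of pipe flow
#'
#' Re = 4 Q / (pi D nu) for volumetric flow Q in a circular pipe of
#' internal diameter D with kinematic viscosity nu.  Defaults describe
#' the test-facility condition: 0.4 l/s in a 79.3 mm pipe at 16 degC
#' (nu = 1.11e-6 m^2/s from standard water tables), giving Re of about
#' 5800 (turbulent).
#'
#' @param flow_l_s volumetric flow rate (litres per second).
#' @param diameter_mm internal pipe diameter (mm).
#' @param temperature_c water temperature (metadata only; viscosity is
#'   not derived from it).
#' @param kinematic_viscosity_m2_s kinematic viscosity (m^2/s).
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(flow_l_s = 0.4, diameter_mm = 79.3,
                            temperature_c = 16,
                            kinematic_viscosity_m2_s = 1.11e-6) {
  if (flow_l_s <= 0 || diameter_mm <= 0 || kinematic_viscosity_m2_s <= 0)
    stop("flow, diameter and viscosity must be strictly positive")
  Q <- flow_l_s / 1000            # m^3/s
  D <- diameter_mm / 1000         # m
  4 * Q / (pi * D * kinematic_viscosity_m2_s)
}
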