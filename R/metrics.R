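# Digital image analysis of unmixed biofilm stacks: median filtering,
# automated threshold selection over the 12-bit range, per-slice area
# coverage, relative biovolume, cell-peak alignment, peak location, the
# "spread" thickness proxy, composition ratios and group statistics.

# --- median filtering ------------------------------------------------------

# exchange network: after swap_sort(i, j), p[[i]] <= p[[j]] elementwise
median9 <- function(p) {
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  # Paeth's 19-exchange median-of-9 network
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  p[[5]]
}

shift_replicate <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  ri <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
  ci <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
  m[ri, ci, drop = FALSE]
}

#' 3x3 median filter of one image
#'
#' Far-red confocal channels carry appreciable shot noise; a 3x3 median
#' preserves fine structure while removing isolated noise pixels.  Edges
#' are handled by nearest-value replication.
#'
#' @param m numeric matrix.
#' @return filtered matrix of the same shape.
#' @export
median_filter_slice <- function(m) {
  p <- vector("list", 9L)
  k <- 1L
  for (dy in -1:1) for (dx in -1:1) {
    p[[k]] <- shift_replicate(m, dy, dx)
    k <- k + 1L
  }
  out <- median9(p)
  dim(out) <- dim(m)
  out
}

#' 3x3 median filter of a component stack
#'
#' Each z-slice is filtered independently (the filter is two-dimensional,
#' applied to every image of the unmixed series before thresholding,
#' quantification or visualisation).
#'
#' @param component a `component_zstack`.
#' @return the filtered `component_zstack`.
#' @export
median_filter_stack <- function(component) {
  a <- component$abundances
  for (z in seq_len(dim(a)[1L])) a[z, , ] <- median_filter_slice(a[z, , ])
  component$abundances <- a
  component
}

# --- thresholding and coverage --------------------------------------------

#' Rescale float abundances to the 12-bit threshold domain
#'
#' Unmixing yields real-valued abundances; thresholds are defined on the
#' integer 1..4095 scale, so abundances are min-max rescaled to 0..4095 and
#' rounded.  The applied offset/scale is recorded in the provenance for
#' reproducibility.
#'
#' @param component a `component_zstack`.
#' @return the component with integer-valued abundances in 0..4095 and
#'   provenance entries `rescale_offset`, `rescale_scale`.
#' @export
rescale_to_12bit <- function(component) {
  a <- component$abundances
  lo <- min(a); hi <- max(a)
  scale <- if (hi > lo) MAX_INTENSITY / (hi - lo) else 0
  a <- round((a - lo) * scale)
  component$abundances <- a
  component$provenance$rescale_offset <- lo
  component$provenance$rescale_scale <- scale
  component
}

#' Area coverage fraction of one binary slice
#'
#' Stain-positive pixels divided by the total pixel count of the image —
#' the principal quantified parameter, prerequisite to all further
#' analysis.
#'
#' @param mask logical/0-1 matrix.
#' @return fraction in \[0, 1\].
#' @export
area_coverage <- function(mask) sum(mask != 0) / length(mask)

#' Exact area coverage for every threshold 1..4095
#'
#' For each z-slice, the coverage fraction that applying each of the 4095
#' possible thresholds would produce, computed from one cumulative
#' histogram per slice rather than 4095 thresholding passes.
#'
#' @param component a `component_zstack` whose abundances are integers in
#'   0..4095 (see [rescale_to_12bit()]); float input is rescaled with a
#'   message.
#' @return 4095 x n_slices matrix of coverage fractions; row t corresponds
#'   to threshold t (mask = abundance >= t).
#' @export
coverage_vs_threshold <- function(component) {
  a <- component$abundances
  if (any(a != round(a)) || max(a) > MAX_INTENSITY || min(a) < 0) {
    message("coverage_vs_threshold: rescaling float abundances to 0..4095")
    component <- rescale_to_12bit(component)
    a <- component$abundances
  }
  nz <- dim(a)[1L]
  npix <- prod(dim(a)[2:3])
  out <- matrix(0, nrow = MAX_INTENSITY, ncol = nz)
  for (z in seq_len(nz)) {
    counts <- tabulate(a[z, , ] + 1L, nbins = MAX_INTENSITY + 1L)
    # n_ge[t] = number of pixels with value >= t, t = 1..4095
    n_ge <- rev(cumsum(rev(counts)))[-1L]
    out[, z] <- n_ge / npix
  }
  rownames(out) <- NULL
  out
}

#' Automated threshold selection from replicate fields of view
#'
#' Implements plateau-based selection: each FOV's total coverage-versus-
#' threshold curve is normalised by its own maximum; a Kruskal-Wallis test
#' (groups = thresholds, observations = per-FOV normalised coverages) then
#' locates the widest contiguous threshold window within which coverage is
#' threshold-insensitive (the test fails to reject at `alpha`); the median
#' threshold of that window is returned.  Selecting the threshold this way
#' removes investigator bias and individual-FOV influence.
#'
#' Thresholds whose normalised coverage is saturated (equal to the curve
#' maximum) or zero in every FOV are not plateau candidates.
#'
#' @param ensemble list of coverage tables from [coverage_vs_threshold()],
#'   one per FOV (or a list of `component_zstack`s, converted internally).
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param min_window minimum plateau width in evaluated thresholds
#'   (default 10).
#' @param step threshold subsampling step for the window search (default
#'   8); the returned median is on the full 1..4095 scale.
#' @return integer threshold, with attributes `window` (length-2 plateau
#'   bounds) and `p_value` (KW p over the plateau).
#' @export
select_threshold <- function(ensemble, alpha = 0.05, min_window = 10L,
                             step = 8L) {
  if (inherits(ensemble[[1L]], "component_zstack"))
    ensemble <- lapply(ensemble, coverage_vs_threshold)
  if (length(ensemble) < 2L)
    warning("threshold selection from fewer than 2 FOVs is unreliable")
  # total coverage per threshold, normalised by each FOV's own maximum
  curves <- vapply(ensemble, function(tab) {
    tot <- rowSums(tab)
    mx <- max(tot)
    if (mx == 0) stop("constant-zero coverage; nothing to threshold")
    tot / mx
  }, numeric(nrow(ensemble[[1L]])))
  thresholds <- seq(1L, nrow(curves), by = as.integer(step))
  M <- curves[thresholds, , drop = FALSE]  # evaluated thresholds x FOVs
  # plateau candidates: strictly between zero coverage and the curve
  # maximum (normalised 1) in every FOV
  candidate <- apply(M, 1L, min) > 0 & apply(M, 1L, max) < 1
  kw_fail <- function(lo, hi) {
    vals <- as.vector(M[lo:hi, , drop = FALSE])
    grp <- factor(rep(thresholds[lo:hi], times = ncol(M)))
    if (max(vals) - min(vals) < 1e-12) return(TRUE)  # exact plateau
    p <- tryCatch(stats::kruskal.test(vals, grp)$p.value,
                  error = function(e) NaN)
    if (is.nan(p)) TRUE else p >= alpha
  }
  runs <- rle(candidate)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL
  for (r in which(runs$values)) {
    s0 <- starts[r]; e0 <- ends[r]
    i <- s0
    while (i <= e0) {
      j <- i
      while (j < e0 && kw_fail(i, j + 1L)) j <- j + 1L
      if (!kw_fail(i, j)) { i <- i + 1L; next }
      if (is.null(best) || (j - i) > (best[2L] - best[1L])) best <- c(i, j)
      i <- j + 1L
    }
  }
  if (is.null(best) || (best[2L] - best[1L] + 1L) < min_window)
    stop("no threshold plateau of width >= ", min_window,
         " found; review coverage curves manually")
  window <- c(thresholds[best[1L]], thresholds[best[2L]])
  t_sel <- as.integer(round(stats::median(window[1L]:window[2L])))
  structure(t_sel, window = window,
            p_value = {
              vals <- as.vector(M[best[1L]:best[2L], , drop = FALSE])
              grp <- factor(rep(thresholds[best[1L]:best[2L]],
                                times = ncol(M)))
              if (max(vals) - min(vals) < 1e-12) 1
              else stats::kruskal.test(vals, grp)$p.value
            })
}

#' Apply an intensity threshold
#'
#' A voxel is stain-positive iff its (rescaled integer) abundance is at
#' least the threshold: threshold 1 labels every pixel associated with the
#' fluorophore positive, 4095 labels (almost) none.
#'
#' @param component a `component_zstack` on the 0..4095 integer scale.
#' @param threshold integer in 1..4095.
#' @return A `binary_zstack`: list with logical `mask` (z, y, x),
#'   `threshold_value`, `component_id` and the source geometry.
#' @export
apply_threshold <- function(component, threshold) {
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > MAX_INTENSITY)
    stop("threshold must be in 1..4095")
  structure(list(
    mask              = component$abundances >= threshold,
    threshold_value   = threshold,
    component_id      = component$component_id,
    slice_interval_um = component$slice_interval_um,
    optical_slice_um  = component$optical_slice_um,
    pixel_size_um     = component$pixel_size_um,
    water_side        = component$water_side
  ), class = "binary_zstack")
}

# --- area profiles, volume, alignment, spread -----------------------------

#' Per-slice area-coverage profile of a binary stack
#'
#' Raw slice indices are numbered 0..(n-1) from the bulk-water side of the
#' stack (using the stack's declared orientation), so that alignment
#' conventions are orientation-independent.
#'
#' @param binary a `binary_zstack`.
#' @return An `area_profile`: data.frame with `raw_index` (0-based, 0 =
#'   bulk-water end) and `coverage`, plus attributes `component_id` and
#'   geometry.
#' @export
area_profile <- function(binary) {
  nz <- dim(binary$mask)[1L]
  cov <- vapply(seq_len(nz), function(z) area_coverage(binary$mask[z, , ]),
                numeric(1L))
  if (identical(binary$water_side, "last")) cov <- rev(cov)
  out <- data.frame(raw_index = seq_len(nz) - 1L, coverage = cov)
  structure(out, class = c("area_profile", "data.frame"),
            component_id = binary$component_id,
            slice_interval_um = binary$slice_interval_um,
            optical_slice_um = binary$optical_slice_um,
            pixel_size_um = binary$pixel_size_um)
}

profile_peak_raw <- function(profile) {
  cov <- profile$coverage
  if (all(cov == 0)) return(NA_integer_)
  # ties broken toward the substratum, i.e. the larger index
  idx <- which(cov == max(cov))
  profile$raw_index[max(idx)]
}

#' Align component profiles to the cell coverage peak
#'
#' Stack sizes differ between fields of view, so profiles are put on a
#' common axis by labelling the slice with maximum cell coverage as slice
#' 0 and numbering consecutively: negative indices run toward the
#' bulk-water interface, positive toward the substratum (plastic).  Cells
#' are the anchor because they produce the EPS.  A `normalised_depth_um`
#' column (aligned index x `depth_step_um`) is added for plotting.
#'
#' @param profiles named list of `area_profile`s including one named
#'   `cells` (or with `component_id == "cells"`).
#' @param depth_step_um depth per slice used for the normalised-depth axis
#'   (default 4.7 um, the optical slice depth conventionally used for
#'   area-distribution plots).
#' @return the list of profiles, each gaining `aligned_index` and
#'   `normalised_depth_um` columns.  Idempotent.
#' @export
align_to_cell_peak <- function(profiles, depth_step_um = 4.7) {
  ids <- vapply(profiles, function(p) attr(p, "component_id") %||% "",
                character(1L))
  ci <- which(ids == "cells")
  if (length(ci) == 0L) ci <- which(names(profiles) == "cells")
  if (length(ci) == 0L) stop("no 'cells' profile to align to")
  peak <- profile_peak_raw(profiles[[ci[1L]]])
  if (is.na(peak)) stop("cell profile is all zero; cannot align")
  lapply(profiles, function(p) {
    p$aligned_index <- p$raw_index - peak
    p$normalised_depth_um <- p$aligned_index * depth_step_um
    p
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak location of an aligned profile
#'
#' The aligned slice index at which coverage is maximal; always 0 for the
#' cells (by construction), possibly any slice for carbohydrates and
#' proteins.  Negative values lie toward the bulk water.  Ties are broken
#' toward the substratum (larger index).
#'
#' @param profile an aligned `area_profile`.
#' @return integer aligned index, or `NA` (with a warning) if the profile
#'   is all zero.
#' @export
peak_location <- function(profile) {
  if (is.null(profile$aligned_index))
    stop("profile is not aligned; call align_to_cell_peak() first")
  if (all(profile$coverage == 0)) {
    warning("all-zero profile: peak location undefined")
    return(NA_integer_)
  }
  idx <- which(profile$coverage == max(profile$coverage))
  as.integer(profile$aligned_index[max(idx)])
}

#' Relative biovolume of a component
#'
#' Volume (um^3) = depth step x total image area x the sum of per-slice
#' area-coverage fractions over the stack.  The result is relative to the
#' detection threshold applied beforehand.  The default depth step is the
#' 2.35 um acquisition interval (half the 4.7 um optical section: adjacent
#' optical sections overlap by half, so Nyquist spacing avoids double
#' counting); the literal optical-slice reading is one argument away.
#'
#' @param profile an `area_profile`.
#' @param depth_step_um depth accounted to each slice (default 2.35).
#' @param image_area_um2 total image area (default 176,400 um^2, a 420 um
#'   square field).
#' @return volume in um^3.
#' @export
compute_volume <- function(profile, depth_step_um = 2.35,
                           image_area_um2 = 176400) {
  if (depth_step_um <= 0 || image_area_um2 <= 0)
    stop("geometry values must be positive")
  depth_step_um * image_area_um2 * sum(profile$coverage)
}

#' Spread: a thickness proxy robust to uneven substrata
#'
#' Spread (um) = volume / (peak area coverage x image area).  Unlike
#' full-stack thickness it does not assume the biofilm spans the whole
#' Z-stack, and for a uniform profile over k slices it equals depth step
#' x k regardless of the coverage level — which is what makes it
#' insensitive to substratum relief.
#'
#' @param volume_um3 component volume from [compute_volume()].
#' @param area_coverage_peak the maximum per-slice coverage fraction (> 0).
#' @param image_area_um2 total image area (um^2).
#' @return spread in um.
#' @export
compute_spread <- function(volume_um3, area_coverage_peak,
                           image_area_um2 = 176400) {
  if (area_coverage_peak <= 0) stop("peak area coverage must be > 0")
  volume_um3 / (area_coverage_peak * image_area_um2)
}

#' Per-component structure metrics for one field of view
#'
#' Convenience wrapper: volume, spread, peak location and peak coverage
#' for each aligned component profile.
#'
#' @param profiles aligned profiles (see [align_to_cell_peak()]).
#' @param depth_step_um depth accounted to each slice for volume/spread.
#' @param image_area_um2 total image area (um^2).
#' @return data.frame, one row per component: `component`, `volume_um3`,
#'   `spread_um`, `peak_location`, `area_coverage_peak`.
#' @export
structure_metrics <- function(profiles, depth_step_um = 2.35,
                              image_area_um2 = 176400) {
  rows <- lapply(profiles, function(p) {
    vol <- compute_volume(p, depth_step_um, image_area_um2)
    pk <- max(p$coverage)
    data.frame(
      component = attr(p, "component_id"),
      volume_um3 = vol,
      spread_um = if (pk > 0) compute_spread(vol, pk, image_area_um2)
                  else NA_real_,
      peak_location = if (pk > 0) peak_location(p) else NA_integer_,
      area_coverage_peak = pk
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Biofilm composition ratios per field of view
#'
#' EPS (= carbohydrates + proteins) and total biofilm (= EPS + cells)
#' volumes are summed per FOV before any averaging; ratios (first
#' component divided by the second) are likewise formed per FOV and only
#' then summarised by median and range, matching non-parametric reporting.
#' Ratios with a zero denominator are flagged undefined (NA) and excluded
#' from the summaries, with the exclusion count reported.
#'
#' @param volumes data.frame with columns `fov`, `component`, `volume_um3`
#'   (components "cells", "carbohydrates", "proteins").
#' @return list with `per_fov` (fov, component volumes, eps, total, the
#'   four ratios) and `summary` (ratio, median, min, max, n, n_undefined).
#' @export
composition_ratios <- function(volumes) {
  wide <- stats::reshape(volumes[c("fov", "component", "volume_um3")],
                         idvar = "fov", timevar = "component",
                         direction = "wide")
  names(wide) <- sub("^volume_um3\\.", "", names(wide))
  for (c in c("cells", "carbohydrates", "proteins"))
    if (is.null(wide[[c]])) stop("missing component volumes: ", c)
  wide$eps <- wide$carbohydrates + wide$proteins
  wide$total <- wide$eps + wide$cells
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  wide$eps_to_cells <- safe_ratio(wide$eps, wide$cells)
  wide$carbohydrates_to_cells <- safe_ratio(wide$carbohydrates, wide$cells)
  wide$proteins_to_cells <- safe_ratio(wide$proteins, wide$cells)
  wide$carbohydrates_to_proteins <- safe_ratio(wide$carbohydrates,
                                               wide$proteins)
  ratio_cols <- c("eps_to_cells", "carbohydrates_to_cells",
                  "proteins_to_cells", "carbohydrates_to_proteins")
  summ <- do.call(rbind, lapply(ratio_cols, function(rc) {
    v <- wide[[rc]]
    ok <- !is.na(v)
    data.frame(ratio = rc,
               median = if (any(ok)) stats::median(v[ok]) else NA_real_,
               min = if (any(ok)) min(v[ok]) else NA_real_,
               max = if (any(ok)) max(v[ok]) else NA_real_,
               n = sum(ok), n_undefined = sum(!ok))
  }))
  rownames(summ) <- NULL
  list(per_fov = wide, summary = summ)
}

#' Non-parametric comparison of a per-FOV metric between groups
#'
#' Volume, spread and peak-location data are typically non-normal
#' (screened here with Shapiro-Wilk), so groups are compared with the
#' Wilcoxon rank-sum test (two groups; W and p reported) or Kruskal-Wallis
#' (more), and summarised by median and range.
#'
#' @param values numeric per-FOV metric.
#' @param labels group factor (>= 2 observations per group).
#' @return list with `test` ("wilcoxon" or "kruskal-wallis"), `statistic`
#'   (W or chi-squared), `p_value`, `shapiro_p` per group, and a `groups`
#'   summary table (n, median, min, max).
#' @export
compare_groups <- function(values, labels) {
  labels <- factor(labels)
  n_by <- table(labels)
  if (any(n_by < 2L)) stop("every group needs >= 2 observations")
  shapiro_p <- vapply(levels(labels), function(l) {
    v <- values[labels == l]
    if (length(v) >= 3L && length(unique(v)) > 1L)
      stats::shapiro.test(v)$p.value else NA_real_
  }, numeric(1L))
  if (nlevels(labels) == 2L) {
    ht <- suppressWarnings(stats::wilcox.test(values ~ labels))
    test <- "wilcoxon"
  } else {
    ht <- stats::kruskal.test(values, labels)
    test <- "kruskal-wallis"
  }
  groups <- do.call(rbind, lapply(levels(labels), function(l) {
    v <- values[labels == l]
    data.frame(group = l, n = length(v), median = stats::median(v),
               min = min(v), max = max(v))
  }))
  rownames(groups) <- NULL
  list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
       shapiro_p = shapiro_p, groups = groups)
}

# --- 3-D export ------------------------------------------------------------

#' Export thresholded components as a VTK voxel volume plus slice overlays
#'
#' Writes a legacy-ASCII VTK structured-points file with one 0/1 scalar
#' field per component on the shared voxel grid (spacing = pixel size,
#' pixel size, slice interval), annotated with each component's display
#' colour at 50% opacity so co-localised voxels remain visible, and one
#' RGB overlay PNG per slice (components additively blended at half
#' intensity).
#'
#' @param masks named list of `binary_zstack` sharing geometry.
#' @param path output `.vtk` path; PNGs go to `<path>_slices/`.
#' @param colours named vector of hex colours per component (defaults:
#'   cells red, carbohydrates green, proteins blue).
#' @param write_png write the per-slice overlay PNGs (default TRUE).
#' @return `path`, invisibly.
#' @export
export_overlay <- function(masks, path,
                           colours = c(cells = "#FF0000",
                                       carbohydrates = "#00FF00",
                                       proteins = "#0000FF"),
                           write_png = TRUE) {
  dims <- lapply(masks, function(m) dim(m$mask))
  if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    stop("masks do not share geometry")
  g <- masks[[1L]]
  d <- dim(g$mask)  # (z, y, x)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  con <- file(path, "w")
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("biofilm component overlay; colours at 50% opacity: ",
                      paste(sprintf("%s=%s", names(masks),
                                    colours[names(masks)]),
                            collapse = " ")),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.6g %.6g %.6g", g$pixel_size_um,
                       g$pixel_size_um, g$slice_interval_um),
               sprintf("POINT_DATA %d", nx * ny * nz)), con)
  for (nm in names(masks)) {
    writeLines(c(sprintf("SCALARS %s unsigned_char 1", nm),
                 "LOOKUP_TABLE default"), con)
    # VTK expects x fastest, then y, then z
    v <- aperm(masks[[nm]]$mask * 1L, c(3L, 2L, 1L))
    writeLines(paste(as.integer(v), collapse = " "), con)
  }
  close(con)
  if (write_png) {
    slice_dir <- paste0(sub("\\.vtk$", "", path), "_slices")
    dir.create(slice_dir, showWarnings = FALSE, recursive = TRUE)
    rgb_of <- t(grDevices::col2rgb(colours[names(masks)]) / 255)
    for (z in seq_len(nz)) {
      img <- array(0, dim = c(ny, nx, 3L))
      for (i in seq_along(masks)) {
        m <- masks[[i]]$mask[z, , ]
        for (ch in 1:3) img[, , ch] <- img[, , ch] + 0.5 * rgb_of[i, ch] * m
      }
      img[img > 1] <- 1
      png::writePNG(img, file.path(slice_dir, sprintf("slice_%03d.png", z)))
    }
  }
  invisible(path)
}

# Reads back a VTK file written by export_overlay (round-trip checks).
read_overlay_vtk <- function(path) {
  lines <- readLines(path)
  dim_line <- strsplit(lines[grep("^DIMENSIONS", lines)], "\\s+")[[1L]]
  nx <- as.integer(dim_line[2L]); ny <- as.integer(dim_line[3L])
  nz <- as.integer(dim_line[4L])
  starts <- grep("^SCALARS", lines)
  out <- list()
  for (s in starts) {
    nm <- strsplit(lines[s], "\\s+")[[1L]][2L]
    vals <- as.integer(strsplit(lines[s + 2L], " ")[[1L]])
    arr <- array(vals, dim = c(nx, ny, nz))
    out[[nm]] <- aperm(arr, c(3L, 2L, 1L))  # back to (z, y, x)
  }
  out
}
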