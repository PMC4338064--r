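# Run configuration and end-to-end pipeline drivers.  Every numeric
# default that encodes an acquisition or analysis constant is resolved
# through one table so its value and provenance are logged whenever a
# run falls back to it.

config_defaults <- function() {
  list(
    geometry = list(
      slice_interval_um = 2.35,   # acquisition step between focal slices
      optical_slice_um  = 4.7,    # optical section depth dZ
      depth_step_um     = 2.35,   # depth accounted per slice in volumes
      plot_depth_step_um = 4.7,   # per-slice depth on area-distribution axes
      image_area_um2    = 176400, # 420 um x 420 um field
      water_side        = "first"
    ),
    threshold = list(
      alpha = 0.05,
      min_window = 10L,
      step = 8L
    ),
    unmixing = list(
      nonneg = TRUE
    ),
    fingerprint = list(
      min_height = 50,            # electropherogram noise cutoff (units)
      align_tol_nt = 0.5,         # alignment confidence interval
      min_fraction = 0.005,       # <0.5% contribution exclusion
      renormalise = TRUE,
      marker = "TRF",
      anosim_perm = 9999L,
      simprof_perm = 20000L,
      seed = 1L
    )
  )
}

#' Resolve a run configuration
#'
#' Merges, in increasing precedence: documented defaults, a YAML config
#' file, and direct overrides.  Every field that falls back to a default
#' is reported through `message()` so no constant is applied silently.
#'
#' @param config_file optional YAML file with any of the blocks
#'   `geometry`, `threshold`, `unmixing`, `fingerprint`.
#' @param overrides nested named list with the same structure.
#' @param quiet suppress the default-provenance log.
#' @return nested list of resolved settings with attribute `provenance`
#'   (source of every leaf: "default", "config", or "override").
#' @export
resolve_config <- function(config_file = NULL, overrides = list(),
                           quiet = FALSE) {
  base <- config_defaults()
  from_file <- if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ",
                                        config_file)
    yaml::read_yaml(config_file)
  } else list()
  out <- base
  prov <- list()
  for (blk in names(base)) {
    for (key in names(base[[blk]])) {
      src <- "default"
      if (!is.null(from_file[[blk]][[key]])) {
        out[[blk]][[key]] <- from_file[[blk]][[key]]; src <- "config"
      }
      if (!is.null(overrides[[blk]][[key]])) {
        out[[blk]][[key]] <- overrides[[blk]][[key]]; src <- "override"
      }
      prov[[paste(blk, key, sep = ".")]] <- src
      if (src == "default" && !quiet)
        message(sprintf("config: %s.%s = %s (default)", blk, key,
                        paste(out[[blk]][[key]], collapse = ",")))
    }
  }
  structure(out, provenance = prov)
}

#' Quantify biofilm structure from lambda-Z-stacks
#'
#' The full physical-structure pipeline over one or more fields of view:
#' read (or accept in-memory) stacks, unmix against the fingerprint
#' library, 3x3-median filter each component, rescale to the 12-bit
#' threshold domain, select one threshold per component across the FOV
#' ensemble, mask, build cell-peak-aligned area profiles, and compute
#' volume, spread, peak location and composition ratios per FOV.
#'
#' @param stacks list of `lambda_zstack` (or character paths readable by
#'   [read_lambda_stack()]).
#' @param library a `fingerprint_library`.
#' @param config resolved configuration from [resolve_config()].
#' @param out_dir optional output directory; when given, writes
#'   `metrics.tsv`, `area_profiles.tsv`, `ratios.tsv`, `thresholds.tsv`,
#'   VTK/PNG overlays per FOV and an area-distribution plot.
#' @return list: `metrics` (per FOV x component), `ratios`, `thresholds`
#'   (per component), `profiles` (aligned, per FOV), `group_tests`
#'   (NULL; add labels downstream via [compare_groups()]).
#' @export
run_quantify <- function(stacks, library, config = resolve_config(quiet = TRUE),
                         out_dir = NULL) {
  if (length(stacks) == 0L) stop("no input stacks supplied")
  stacks <- lapply(stacks, function(s)
    if (is.character(s)) read_lambda_stack(s) else s)
  geom <- config$geometry
  biofilm_ids <- setdiff(library$component_ids,
                         library$autofluorescence_id)

  filtered <- lapply(stacks, function(st) {
    um <- unmix_stack(st, library, nonneg = config$unmixing$nonneg)
    comps <- um$components[biofilm_ids]
    lapply(comps, function(cc) rescale_to_12bit(median_filter_stack(cc)))
  })

  thresholds <- vapply(biofilm_ids, function(id) {
    ens <- lapply(filtered, `[[`, id)
    as.integer(select_threshold(ens, alpha = config$threshold$alpha,
                                min_window = config$threshold$min_window,
                                step = config$threshold$step))
  }, integer(1L))

  all_metrics <- list(); all_profiles <- list()
  masks_by_fov <- list()
  for (f in seq_along(filtered)) {
    masks <- lapply(biofilm_ids, function(id)
      apply_threshold(filtered[[f]][[id]], thresholds[[id]]))
    names(masks) <- biofilm_ids
    masks_by_fov[[f]] <- masks
    profiles <- lapply(masks, area_profile)
    profiles <- align_to_cell_peak(profiles,
                                   depth_step_um = geom$plot_depth_step_um)
    m <- structure_metrics(profiles, depth_step_um = geom$depth_step_um,
                           image_area_um2 = geom$image_area_um2)
    m$fov <- f
    all_metrics[[f]] <- m
    all_profiles[[f]] <- profiles
  }
  metrics <- do.call(rbind, all_metrics)
  ratios <- composition_ratios(metrics)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(ratios$per_fov, file.path(out_dir, "ratios.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(component = names(thresholds), threshold = thresholds),
      file.path(out_dir, "thresholds.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    prof_tab <- do.call(rbind, lapply(seq_along(all_profiles), function(f)
      do.call(rbind, lapply(all_profiles[[f]], function(p) {
        data.frame(fov = f, component = attr(p, "component_id"),
                   raw_index = p$raw_index, aligned_index = p$aligned_index,
                   normalised_depth_um = p$normalised_depth_um,
                   coverage = p$coverage)
      }))))
    utils::write.table(prof_tab, file.path(out_dir, "area_profiles.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (f in seq_along(masks_by_fov))
      export_overlay(masks_by_fov[[f]],
                     file.path(out_dir, sprintf("overlay_fov%02d.vtk", f)),
                     write_png = FALSE)
    plot_area_distributions(all_profiles,
                            file.path(out_dir, "area_distribution.pdf"))
  }
  list(metrics = metrics, ratios = ratios, thresholds = thresholds,
       profiles = all_profiles, masks = masks_by_fov)
}

#' Area-distribution plot (aligned depth vs coverage, per component)
#'
#' One panel per component: per-FOV coverage curves against the
#' cell-peak-aligned normalised depth, positive depths toward the
#' substratum at the bottom of the axis.
#'
#' @param profiles_by_fov list (per FOV) of aligned profile lists.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
plot_area_distributions <- function(profiles_by_fov, path) {
  comps <- names(profiles_by_fov[[1L]])
  grDevices::pdf(path, width = 3 * length(comps), height = 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(comps)), mar = c(4, 4, 2, 1))
  for (cid in comps) {
    xs <- unlist(lapply(profiles_by_fov, function(pp) pp[[cid]]$coverage))
    ys <- unlist(lapply(profiles_by_fov,
                        function(pp) pp[[cid]]$normalised_depth_um))
    graphics::plot(NA, xlim = c(0, max(xs, 1e-3)), ylim = rev(range(ys)),
                   xlab = "area coverage fraction",
                   ylab = "normalised depth (um)", main = cid)
    graphics::abline(h = 0, lty = 2, col = "blue")
    for (pp in profiles_by_fov)
      graphics::lines(pp[[cid]]$coverage, pp[[cid]]$normalised_depth_um)
  }
  invisible(path)
}

#' Run the community-fingerprint analysis chain
#'
#' filter -> align -> normalise -> square-root Bray-Curtis -> diversity
#' indices, plus ANOSIM/SIMPER between groups and SIMPROF-flagged
#' clustering when group labels and enough samples are available.  A
#' single sample yields indices only (similarity stages are skipped with
#' a notice).
#'
#' @param profiles list of `fingerprint_profile`s.
#' @param groups optional group factor (one level per sample).
#' @param config resolved configuration from [resolve_config()].
#' @param out_dir optional output directory for delimited tables and the
#'   Newick dendrogram.
#' @return list: `community` (normalised matrix), `similarity` (percent),
#'   `indices`, `anosim`, `simper`, `simprof`, `index_tests`.
#' @export
run_fingerprint <- function(profiles, groups = NULL,
                            config = resolve_config(quiet = TRUE),
                            out_dir = NULL) {
  fp <- config$fingerprint
  filtered <- lapply(profiles, filter_peaks, min_height = fp$min_height)
  if (length(filtered) == 1L) {
    message("single sample: computing indices only, similarity skipped")
    pk <- filtered[[1L]]$peaks
    mat <- matrix(pk$area, nrow = 1L,
                  dimnames = list(filtered[[1L]]$sample_id,
                                  sprintf("%.3f", pk$size_nt)))
    cm <- structure(mat, class = c("community_matrix", "matrix"),
                    consensus_sizes = pk$size_nt, normalised = FALSE)
    norm <- normalise_community(cm, fp$min_fraction, fp$renormalise)
    return(list(community = norm, similarity = NULL,
                indices = diversity_indices(norm), anosim = NULL,
                simper = NULL, simprof = NULL, index_tests = NULL))
  }
  aligned <- align_fragments(filtered, tol = fp$align_tol_nt)
  norm <- normalise_community(aligned, fp$min_fraction, fp$renormalise)
  sim <- bray_curtis(norm, transform = "sqrt")
  indices <- diversity_indices(norm)
  res <- list(community = norm, similarity = sim, indices = indices,
              anosim = NULL, simper = NULL, simprof = NULL,
              index_tests = NULL)
  if (!is.null(groups)) {
    groups <- factor(groups)
    res$anosim <- anosim(sim, groups, n_perm = fp$anosim_perm,
                         seed = fp$seed)
    if (nlevels(groups) == 2L) {
      res$simper <- simper(norm, groups)
      res$index_tests <- compare_indices(indices, groups)
    }
  }
  if (nrow(norm) >= 3L)
    res$simprof <- simprof_cluster(norm, n_perm = fp$simprof_perm,
                                   seed = fp$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(unclass(norm)),
                       file.path(out_dir, "community_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    if (!is.null(res$similarity))
      utils::write.table(as.data.frame(res$similarity),
                         file.path(out_dir, "similarity.tsv"),
                         sep = "\t", quote = FALSE)
    utils::write.table(indices, file.path(out_dir, "indices.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$simprof))
      writeLines(res$simprof$newick, file.path(out_dir, "dendrogram.nwk"))
  }
  res
}
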