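MAX_INTENSITY <- 4095L

#' Construct a lambda-Z-stack
#'
#' A lambda-Z-stack is a confocal acquisition in which a full binned emission
#' spectrum is recorded at every pixel of every focal slice.  Intensities are
#' 12-bit (0--4095).  The first array margin is the focal slice (z), the
#' second the emission wavelength bin, then image row and column.
#'
#' @param intensities integer array indexed (z, lambda bin, y, x), values in
#'   0..4095.
#' @param slice_interval_um acquisition step between adjacent focal slices
#'   (micrometres).
#' @param optical_slice_um optical section depth dZ (micrometres).
#' @param lambda_bin_centres_nm ascending, equally spaced bin centres (nm).
#' @param lambda_bin_width_nm spectral bin width (nm); must equal the centre
#'   spacing.
#' @param pixel_size_um lateral pixel size (micrometres).
#' @param water_side which end of the z axis faces the bulk water:
#'   `"first"` (slice 1) or `"last"`.
#'
#' @return An object of class `lambda_zstack`.
#' @export
lambda_zstack <- function(intensities,
                          slice_interval_um,
                          optical_slice_um,
                          lambda_bin_centres_nm,
                          lambda_bin_width_nm,
                          pixel_size_um,
                          water_side = c("first", "last")) {
  water_side <- match.arg(water_side)
  if (length(dim(intensities)) != 4L)
    stop("intensities must be a 4-D array (z, lambda, y, x)")
  storage.mode(intensities) <- "integer"
  d <- dim(intensities)
  obj <- structure(list(
    intensities          = intensities,
    n_slices             = d[1L],
    slice_interval_um    = slice_interval_um,
    optical_slice_um     = optical_slice_um,
    lambda_bin_centres_nm = as.numeric(lambda_bin_centres_nm),
    lambda_bin_width_nm  = lambda_bin_width_nm,
    pixel_size_um        = pixel_size_um,
    field_width_um       = pixel_size_um * d[4L],
    field_height_um      = pixel_size_um * d[3L],
    water_side           = water_side
  ), class = "lambda_zstack")
  validate_lambda_zstack(obj)
}

validate_lambda_zstack <- function(x) {
  d <- dim(x$intensities)
  if (d[1L] < 1L) stop("n_slices must be >= 1")
  if (length(x$lambda_bin_centres_nm) != d[2L])
    stop("lambda_bin_centres_nm length does not match the lambda dimension")
  rng <- range(x$intensities)
  if (rng[1L] < 0L || rng[2L] > MAX_INTENSITY)
    stop("intensities outside the 12-bit range 0..4095")
  if (d[2L] > 1L) {
    spacing <- diff(x$lambda_bin_centres_nm)
    if (any(spacing <= 0)) stop("lambda_bin_centres_nm must be ascending")
    if (any(abs(spacing - x$lambda_bin_width_nm) > 1e-6))
      stop("lambda bin centres are not spaced by lambda_bin_width_nm")
  }
  if (abs(x$field_width_um - x$pixel_size_um * d[4L]) > 1e-6)
    stop("field_width_um inconsistent with pixel_size_um * n_cols")
  invisible(x)
}

#' @export
print.lambda_zstack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "lambda_zstack: %d slices x %d lambda bins x %d x %d px\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  lambda %.1f-%.1f nm (bin width %.2f nm)\n",
              min(x$lambda_bin_centres_nm), max(x$lambda_bin_centres_nm),
              x$lambda_bin_width_nm))
  cat(sprintf("  slice interval %.2f um, optical slice %.2f um, pixel %.3f um\n",
              x$slice_interval_um, x$optical_slice_um, x$pixel_size_um))
  cat(sprintf("  field %.1f x %.1f um, bulk water at %s slice\n",
              x$field_width_um, x$field_height_um, x$water_side))
  invisible(x)
}

#' Evenly spaced lambda bin centres for a detection range
#'
#' Divides a detection range into `n_bins` equal spectral bins and returns
#' the bin centres; e.g. the 650.7--704.2 nm far-red detection range in five
#' bins gives a 10.7 nm bin width.
#'
#' @param range_nm length-2 numeric, detection range edges (nm).
#' @param n_bins number of bins.
#' @return numeric vector of bin centres with attribute `bin_width_nm`.
#' @export
lambda_bins <- function(range_nm, n_bins) {
  stopifnot(length(range_nm) == 2L, n_bins >= 1L, range_nm[2L] > range_nm[1L])
  width <- (range_nm[2L] - range_nm[1L]) / n_bins
  centres <- range_nm[1L] + width * (seq_len(n_bins) - 0.5)
  attr(centres, "bin_width_nm") <- width
  centres
}

geometry_fields <- c("slice_interval_um", "optical_slice_um",
                     "lambda_bin_centres_nm", "lambda_bin_width_nm",
                     "pixel_size_um", "water_side")

#' Write a lambda-Z-stack as multi-page 16-bit TIFF
#'
#' Pages are ordered z-major, lambda-minor.  Geometry is written to a YAML
#' sidecar (`<path>.yml`) because baseline TIFF carries no acquisition
#' metadata; the sidecar is read back automatically by [read_lambda_stack()].
#'
#' @param stack a `lambda_zstack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_lambda_stack <- function(stack, path) {
  d <- dim(stack$intensities)
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (z in seq_len(d[1L])) {
    for (l in seq_len(d[2L])) {
      pages[[k]] <- stack$intensities[z, l, , ] / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  geom <- stack[geometry_fields]
  geom$n_slices <- d[1L]
  geom$n_lambda <- d[2L]
  yaml::write_yaml(geom, paste0(path, ".yml"))
  invisible(path)
}

# Minimal OME-XML geometry extraction from a TIFF ImageDescription.
parse_ome_geometry <- function(description) {
  if (is.null(description) || !grepl("<OME", description, fixed = TRUE))
    return(NULL)
  doc <- xml2::read_xml(description)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  att <- function(name) {
    v <- xml2::xml_attr(px, name)
    if (is.na(v)) NULL else as.numeric(v)
  }
  out <- list()
  out$n_slices <- att("SizeZ")
  out$n_lambda <- att("SizeC")
  out$pixel_size_um <- att("PhysicalSizeX")
  out$slice_interval_um <- att("PhysicalSizeZ")
  out[!vapply(out, is.null, logical(1))]
}

#' Read a lambda-Z-stack from TIFF/OME-TIFF
#'
#' Page ordering must encode (z, lambda) z-major.  Geometry is resolved, in
#' increasing precedence: OME-XML in the TIFF description (if present), a
#' YAML sidecar `<path>.yml` (written by [write_lambda_stack()]), then the
#' `geometry` overrides.  Any geometry field still missing raises an error;
#' nothing is silently defaulted.
#'
#' @param path TIFF file.
#' @param geometry named list of overrides for any of: `n_slices`,
#'   `n_lambda`, `slice_interval_um`, `optical_slice_um`,
#'   `lambda_bin_centres_nm`, `lambda_bin_width_nm`, `pixel_size_um`,
#'   `water_side`.
#' @return A validated `lambda_zstack`.
#' @export
read_lambda_stack <- function(path, geometry = list()) {
  if (!file.exists(path)) stop("cannot read stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)

  meta <- list()
  descr <- attr(pages[[1L]], "description")
  ome <- parse_ome_geometry(descr)
  if (!is.null(ome)) meta[names(ome)] <- ome
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) {
    sc <- yaml::read_yaml(sidecar)
    meta[names(sc)] <- sc
  }
  meta[names(geometry)] <- geometry

  need <- c("n_slices", "n_lambda", geometry_fields)
  missing_fields <- setdiff(need, names(meta))
  if (length(missing_fields) > 0L)
    stop("missing geometry fields (supply via metadata or overrides): ",
         paste(missing_fields, collapse = ", "))

  nz <- as.integer(meta$n_slices)
  nl <- as.integer(meta$n_lambda)
  if (nz * nl != length(pages))
    stop(sprintf("page count %d does not match declared z=%d x lambda=%d",
                 length(pages), nz, nl))

  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0L, dim = c(nz, nl, ny, nx))
  k <- 1L
  for (z in seq_len(nz)) {
    for (l in seq_len(nl)) {
      arr[z, l, , ] <- as.integer(round(pages[[k]] * 65535))
      k <- k + 1L
    }
  }
  lambda_zstack(arr,
                slice_interval_um     = meta$slice_interval_um,
                optical_slice_um      = meta$optical_slice_um,
                lambda_bin_centres_nm = unlist(meta$lambda_bin_centres_nm),
                lambda_bin_width_nm   = meta$lambda_bin_width_nm,
                pixel_size_um         = meta$pixel_size_um,
                water_side            = meta$water_side)
}

#' Construct an emission spectrum (fingerprint)
#'
#' @param component_id e.g. "cells", "carbohydrates", "proteins",
#'   "autofluorescence".
#' @param intensities non-negative intensity per lambda bin.
#' @param excitation_nm excitation wavelength (metadata only).
#' @param normalisation one of "raw", "unit-sum", "unit-max".
#' @return An `emission_spectrum` object.
#' @export
emission_spectrum <- function(component_id, intensities, excitation_nm = NA_real_,
                              normalisation = c("raw", "unit-sum", "unit-max")) {
  normalisation <- match.arg(normalisation)
  intensities <- as.numeric(intensities)
  if (any(intensities < 0)) stop("spectrum intensities must be non-negative")
  if (!any(intensities > 0)) stop("spectrum must have at least one positive value")
  structure(list(component_id = component_id,
                 intensities = intensities,
                 excitation_nm = excitation_nm,
                 normalisation = normalisation),
            class = "emission_spectrum")
}

#' Renormalise an emission spectrum
#' @param spectrum an `emission_spectrum`.
#' @param mode "unit-sum" (divides by the total) or "unit-max".
#' @return The renormalised spectrum.
#' @export
normalise_spectrum <- function(spectrum, mode = c("unit-sum", "unit-max")) {
  mode <- match.arg(mode)
  s <- spectrum$intensities
  spectrum$intensities <- if (mode == "unit-sum") s / sum(s) else s / max(s)
  spectrum$normalisation <- mode
  spectrum
}

#' Extract the mean emission spectrum over a voxel region
#'
#' Used to pull emission fingerprints out of control acquisitions (unstained
#' inserts/biofilms, single-stained biofilms): the per-bin mean intensity
#' over a region of interest.
#'
#' @param stack a `lambda_zstack`.
#' @param region matrix or data.frame with columns `z`, `y`, `x` (1-based
#'   voxel coordinates).
#' @param component_id label for the resulting spectrum.
#' @return An `emission_spectrum` tagged `raw`.
#' @export
extract_spectrum <- function(stack, region, component_id = "region") {
  region <- as.matrix(as.data.frame(region)[, c("z", "y", "x")])
  if (nrow(region) == 0L) stop("region is empty")
  d <- dim(stack$intensities)
  if (any(region < 1L) || any(region[, "z"] > d[1L]) ||
      any(region[, "y"] > d[3L]) || any(region[, "x"] > d[4L]))
    stop("region exceeds stack bounds")
  nl <- d[2L]
  means <- vapply(seq_len(nl), function(l) {
    idx <- cbind(region[, "z"], l, region[, "y"], region[, "x"])
    mean(stack$intensities[idx])
  }, numeric(1L))
  emission_spectrum(component_id, means, normalisation = "raw")
}

#' Select the representative spectrum from replicates
#'
#' Replicate fingerprints (e.g. 21 spectra: 7 fields of view for each of 3
#' samples) are reduced to one characteristic fingerprint.  Spectra are
#' unit-sum normalised for comparison and the medoid — the member spectrum
#' minimising the summed Euclidean distance to all others — is returned
#' (the original member, untouched).  A pointwise-median mode is available
#' but can produce a spectrum no replicate ever exhibited.
#'
#' @param spectra list of `emission_spectrum` of equal length.
#' @param method "medoid" (default) or "pointwise" median per bin.
#' @return An `emission_spectrum`; for "medoid", a member of `spectra`
#'   (ties broken by input order).
#' @export
medoid_spectrum <- function(spectra, method = c("medoid", "pointwise")) {
  method <- match.arg(method)
  stopifnot(length(spectra) >= 1L)
  lens <- vapply(spectra, function(s) length(s$intensities), integer(1L))
  if (length(unique(lens)) != 1L) stop("spectra have mixed lengths")
  norm <- t(vapply(spectra, function(s) {
    v <- s$intensities; v / sum(v)
  }, numeric(lens[1L])))
  if (method == "pointwise") {
    med <- apply(norm, 2L, stats::median)
    return(emission_spectrum(spectra[[1L]]$component_id, med,
                             excitation_nm = spectra[[1L]]$excitation_nm))
  }
  dmat <- as.matrix(stats::dist(norm))
  total <- rowSums(dmat)
  spectra[[which.min(total)]]  # which.min takes the first on ties
}

#' Build a fingerprint library for unmixing
#'
#' An ordered set of endmember spectra covering every component to be
#' unmixed, optionally with exactly one autofluorescence spectrum (its
#' coefficient is estimated but never counted as biofilm signal).
#'
#' @param spectra list of `emission_spectrum` with unique `component_id`s.
#' @param autofluorescence_id the `component_id` holding the
#'   autofluorescence endmember, or `NULL` if none supplied.
#' @return A `fingerprint_library`.
#' @export
fingerprint_library <- function(spectra, autofluorescence_id = "autofluorescence") {
  ids <- vapply(spectra, `[[`, character(1L), "component_id")
  if (anyDuplicated(ids)) stop("component_ids must be unique")
  lens <- vapply(spectra, function(s) length(s$intensities), integer(1L))
  if (length(unique(lens)) != 1L) stop("spectra have mixed lengths")
  S <- vapply(spectra, `[[`, numeric(lens[1L]), "intensities")
  S <- matrix(S, nrow = lens[1L], dimnames = list(NULL, ids))
  # pairwise cosine similarity; identical directions make unmixing singular
  U <- sweep(S, 2L, sqrt(colSums(S^2)), "/")
  cs <- crossprod(U)
  diag(cs) <- 0
  if (any(cs >= 1 - 1e-9))
    stop("two fingerprints are (numerically) identical; library is singular")
  if (!is.null(autofluorescence_id) && !autofluorescence_id %in% ids)
    autofluorescence_id <- NULL
  structure(list(spectra = spectra, matrix = S, component_ids = ids,
                 autofluorescence_id = autofluorescence_id),
            class = "fingerprint_library")
}

#' Write emission spectra as delimited text
#'
#' Two columns (wavelength-bin centre in nm, intensity) with a header line
#' naming the component; multiple spectra are concatenated with blank-line
#' separators.
#'
#' @param spectra list of `emission_spectrum`.
#' @param lambda_nm bin centres shared by all spectra.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, lambda_nm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(length(s$intensities) == length(lambda_nm))
    writeLines(sprintf("# component: %s excitation_nm: %s", s$component_id,
                       s$excitation_nm), con)
    writeLines("wavelength_nm\tintensity", con)
    writeLines(sprintf("%.6g\t%.10g", lambda_nm, s$intensities), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read emission spectra written by [write_spectra()]
#' @param path input file.
#' @return list of `emission_spectrum` with attribute `lambda_nm`.
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  starts <- grep("^# component:", lines)
  if (length(starts) == 0L) stop("no '# component:' headers found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lambda <- NULL
  spectra <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    hdr <- block[1L]
    id <- sub("^# component:\\s*(\\S+).*$", "\\1", hdr)
    exc <- suppressWarnings(as.numeric(
      sub("^.*excitation_nm:\\s*(\\S+)\\s*$", "\\1", hdr)))
    rows <- block[grepl("^[0-9.+-eE]+\t", block)]
    vals <- utils::read.table(text = rows, sep = "\t",
                              col.names = c("wavelength_nm", "intensity"))
    lambda <<- vals$wavelength_nm
    emission_spectrum(id, vals$intensity, excitation_nm = exc)
  })
  attr(spectra, "lambda_nm") <- lambda
  spectra
}
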