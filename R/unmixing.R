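# Linear spectral unmixing: each pixel's binned emission spectrum is
# decomposed into a non-negative combination of endmember fingerprints
# (stains + autofluorescence).  The NNLS solve is exact: for a small
# endmember library the optimum over all support sets is found by
# enumerating them, which vectorises over every pixel of a slice at once.

# Batched exact NNLS.  S: bins x k endmember matrix; Y: bins x n observed
# spectra.  Returns list(coefficients = k x n, rss = length-n residual
# sum of squares).  NNLS is a convex QP, so the global optimum is attained
# on one of the 2^k support sets; we try them all (k is 3-5 in practice).
nnls_batch <- function(S, Y) {
  k <- ncol(S); n <- ncol(Y)
  if (k > 12L) stop("endmember enumeration supports at most 12 components")
  AtA <- crossprod(S)                # k x k
  AtY <- crossprod(S, Y)             # k x n
  yty <- colSums(Y^2)
  best_rss <- yty                    # empty support: all coefficients 0
  best_coef <- matrix(0, k, n)
  for (mask in seq_len(2^k - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    A_ss <- AtA[sel, sel, drop = FALSE]
    # skip numerically singular supports (collinear sub-libraries)
    if (rcond_sym(A_ss) < 1e-12) next
    C <- solve(A_ss, AtY[sel, , drop = FALSE])        # |sel| x n
    feas <- colSums(C < -1e-10) == 0L
    if (!any(feas)) next
    # rss = yty - 2 c.b + c' A c ; at the LS optimum c'Ac = c.b, so
    # rss = yty - c.b
    cb <- colSums(C * AtY[sel, , drop = FALSE])
    rss <- yty - cb
    improve <- feas & (rss < best_rss - 1e-12)
    if (any(improve)) {
      best_rss[improve] <- rss[improve]
      best_coef[, improve] <- 0
      best_coef[sel, improve] <- C[, improve, drop = FALSE]
    }
  }
  best_coef[best_coef < 0] <- 0      # clip -1e-10..0 numerical dust
  # the cancellation form yty - c.b is fine for picking the best support
  # but loses precision near zero; report the residual computed directly
  rss <- colSums((Y - S %*% best_coef)^2)
  list(coefficients = best_coef, rss = rss)
}

rcond_sym <- function(A) {
  ev <- tryCatch(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Unmix a single pixel spectrum
#'
#' Least-squares decomposition of one observed binned emission spectrum
#' into the library endmembers.  By default coefficients are constrained
#' non-negative (abundances are physical concentrations); an unconstrained
#' mode is available for comparison.  The autofluorescence coefficient is
#' estimated alongside the stains but reported separately.
#'
#' @param observed numeric vector, one intensity per lambda bin.
#' @param library a [fingerprint_library()].
#' @param nonneg constrain abundances to be non-negative (default TRUE).
#' @return named numeric vector of abundances, one per library component,
#'   with attribute `rms_residual`.
#' @export
unmix_pixel <- function(observed, library, nonneg = TRUE) {
  S <- library$matrix
  if (length(observed) != nrow(S))
    stop("observed spectrum length does not match library bin count")
  Y <- matrix(as.numeric(observed), ncol = 1L)
  if (nonneg) {
    fit <- nnls_batch(S, Y)
    coefs <- fit$coefficients[, 1L]
    rss <- fit$rss[1L]
  } else {
    coefs <- qr.coef(qr(S), Y)[, 1L]
    rss <- sum((Y - S %*% coefs)^2)
  }
  names(coefs) <- library$component_ids
  attr(coefs, "rms_residual") <- sqrt(rss / nrow(S))
  coefs
}

#' Unmix a whole lambda-Z-stack
#'
#' Applies [unmix_pixel()] to every voxel (vectorised slice by slice) and
#' returns one abundance stack per library component together with a
#' per-voxel RMS spectral-fit residual map.  Deterministic.
#'
#' @param stack a `lambda_zstack`.
#' @param library a `fingerprint_library`; every lambda bin of `stack` must
#'   be covered.
#' @param nonneg non-negative least squares (default) or unconstrained.
#' @return list with `components` (named list of `component_zstack`) and
#'   `residual` (z, y, x array of RMS residuals).
#' @export
unmix_stack <- function(stack, library, nonneg = TRUE) {
  d <- dim(stack$intensities)
  nz <- d[1L]; nl <- d[2L]; ny <- d[3L]; nx <- d[4L]
  S <- library$matrix
  if (nrow(S) != nl)
    stop("library spectra length does not match stack lambda bins")
  k <- ncol(S)
  out <- lapply(seq_len(k), function(i) array(0, dim = c(nz, ny, nx)))
  names(out) <- library$component_ids
  residual <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) {
    # bins x pixels matrix for this slice
    Y <- matrix(aperm(stack$intensities[z, , , , drop = FALSE],
                      c(2L, 3L, 4L, 1L)), nrow = nl)
    if (nonneg) {
      fit <- nnls_batch(S, Y)
      coefs <- fit$coefficients
      rms <- sqrt(fit$rss / nl)
    } else {
      coefs <- qr.coef(qr(S), Y)
      rss <- colSums((Y - S %*% coefs)^2)
      rms <- sqrt(pmax(rss, 0) / nl)
    }
    for (i in seq_len(k)) out[[i]][z, , ] <- coefs[i, ]
    residual[z, , ] <- rms
  }
  provenance <- list(library_hash = library_hash(library),
                     solver = if (nonneg) "nnls-exhaustive" else "ols")
  components <- lapply(library$component_ids, function(id)
    component_zstack(out[[id]], id, stack, provenance))
  names(components) <- library$component_ids
  list(components = components, residual = residual)
}

library_hash <- function(library) {
  v <- c(as.numeric(library$matrix), utf8ToInt(paste(library$component_ids,
                                                     collapse = "|")))
  # order-sensitive checksum; enough to tag provenance without digest pkgs
  sprintf("%.0f", sum(v * seq_along(v)) %% 2^31)
}

#' Construct a per-component abundance stack
#'
#' @param abundances non-negative (z, y, x) array for one component.
#' @param component_id component label.
#' @param source a `lambda_zstack` providing the geometry, or a list with
#'   the same geometry fields.
#' @param provenance free-form list (library hash, solver settings).
#' @return A `component_zstack`.
#' @export
component_zstack <- function(abundances, component_id, source,
                             provenance = list()) {
  if (length(dim(abundances)) != 3L)
    stop("abundances must be a 3-D (z, y, x) array")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  structure(list(
    abundances        = abundances,
    component_id      = component_id,
    slice_interval_um = source$slice_interval_um,
    optical_slice_um  = source$optical_slice_um,
    pixel_size_um     = source$pixel_size_um,
    field_width_um    = source$pixel_size_um * dim(abundances)[3L],
    field_height_um   = source$pixel_size_um * dim(abundances)[2L],
    water_side        = source$water_side,
    provenance        = provenance
  ), class = "component_zstack")
}

#' @export
print.component_zstack <- function(x, ...) {
  d <- dim(x$abundances)
  cat(sprintf("component_zstack '%s': %d slices x %d x %d px, range %.3g-%.3g\n",
              x$component_id, d[1], d[2], d[3],
              min(x$abundances), max(x$abundances)))
  invisible(x)
}

#' Write unmixed component stacks as 32-bit float TIFFs
#'
#' One single-channel multi-page (z) float TIFF per component, named
#' `<component_id>.tif` under `dir`.
#'
#' @param components named list of `component_zstack`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_component_stacks <- function(components, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(components, function(comp) {
    d <- dim(comp$abundances)
    mx <- max(comp$abundances, 1)
    pages <- lapply(seq_len(d[1L]), function(z) comp$abundances[z, , ] / mx)
    p <- file.path(dir, paste0(comp$component_id, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 32L, compression = "none")
    yaml::write_yaml(list(scale = mx), paste0(p, ".yml"))
    p
  }, character(1L))
  invisible(paths)
}
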