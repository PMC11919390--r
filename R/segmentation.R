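#' Locate the substrate plane from the reflection channel
#'
#' The solid-liquid interface at the base of the sample produces a bright
#' plane in the reflected-light channel; its z position is taken as the z
#' index with maximum intensity averaged over xy slices. Ties are broken
#' toward the lowest z.
#'
#' @param stack A [stack3d()].
#' @param channel Channel name to use (default `"reflection"`).
#' @return 1-based z index of the base plane.
#' @export
find_base <- function(stack, channel = "reflection") {
  stopifnot(inherits(stack, "stack3d"))
  if (!channel %in% names(stack$channels))
    stop(sprintf("channel '%s' not present; available: %s", channel,
                 paste(names(stack$channels), collapse = ", ")))
  arr <- stack$channels[[channel]]
  means <- apply(arr, 1, mean)
  if (diff(range(means)) < 1e-12) {
    warning("reflection intensity is flat in z; using the lowest slice")
    return(1L)
  }
  which.max(means)  # first maximum = lowest z on ties
}

#' Segment sessile condensates from a two-channel stack
#'
#' Implements the stack-to-mask protocol: xy slices below the base plane
#' are discarded (the base slice itself is retained), the fluorescence
#' channel is smoothed with a Gaussian filter of voxel radius
#' `smooth_radius` (sigma = radius/2, truncated at 4 sigma), binarized with
#' a single Otsu threshold computed on the whole cropped volume, and
#' connected components (26-connectivity) are labelled. Components are
#' retained only if they touch the base plane and no other volume
#' boundary, so partially imaged condensates are excluded.
#'
#' @param stack A [stack3d()] with a `fluorescence` channel.
#' @param base 1-based z index of the base plane; computed with
#'   [find_base()] when `NULL`.
#' @param smooth_radius Gaussian filter radius in voxels.
#' @param connectivity 26 (default) or 6.
#' @param min_voxels Components smaller than this are dropped as noise.
#' @return A list of `condensate_mask` objects sorted by volume
#'   (descending), each holding the boolean voxels of its bounding box,
#'   the bounding box position within the cropped volume (z = 1 is the
#'   base slice), the voxel spacing, and an `id`.
#' @export
segment_stack <- function(stack, base = NULL, smooth_radius = 2,
                          connectivity = 26, min_voxels = 30) {
  stopifnot(inherits(stack, "stack3d"))
  if (is.null(base)) base <- find_base(stack)
  dims <- dim(stack$channels$fluorescence)
  if (base < 1 || base > dims[1]) stop("base index outside the stack")
  vol <- stack$channels$fluorescence[base:dims[1], , , drop = FALSE]
  dv <- dim(vol)

  # edge-replicated padding so the smoothing does not darken the volume
  # boundaries (the base slice in particular must not drop below the
  # threshold, or condensates would lose contact with the base plane)
  hw <- 2L * as.integer(smooth_radius)
  clampi <- function(n) pmin(pmax(seq(1L - hw, n + hw), 1L), n)
  padded <- vol[clampi(dv[1]), clampi(dv[2]), clampi(dv[3]), drop = FALSE]
  smp <- fft_convolve3(padded, gaussian_kernel3(smooth_radius / 2,
                                                half_width = hw))
  sm <- smp[hw + seq_len(dv[1]), hw + seq_len(dv[2]), hw + seq_len(dv[3])]
  rng <- range(sm)
  if (diff(rng) < 1e-12) return(list())
  norm <- (sm - rng[1]) / diff(rng)
  thr_norm <- EBImage::otsu(EBImage::Image(matrix(as.numeric(norm),
                                                  ncol = 1)),
                            range = c(0, 1), levels = 256)
  thr <- rng[1] + thr_norm * diff(rng)
  bin <- sm > thr
  if (!any(bin)) return(list())

  labels <- label_components_cpp(as.logical(bin), as.integer(dv),
                                 as.integer(connectivity))
  labels <- array(labels, dv)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  masks <- list()
  for (id in ids) {
    idx <- which(labels == id, arr.ind = TRUE)
    if (nrow(idx) < min_voxels) next
    zr <- range(idx[, 1]); yr <- range(idx[, 2]); xr <- range(idx[, 3])
    touches_base <- zr[1] == 1L
    touches_other <- zr[2] == dv[1] || yr[1] == 1L || yr[2] == dv[2] ||
      xr[1] == 1L || xr[2] == dv[3]
    if (!touches_base || touches_other) next
    vox <- array(FALSE, c(diff(zr), diff(yr), diff(xr)) + 1L)
    vox[cbind(idx[, 1] - zr[1] + 1L, idx[, 2] - yr[1] + 1L,
              idx[, 3] - xr[1] + 1L)] <- TRUE
    masks[[length(masks) + 1L]] <-
      structure(list(voxels = vox,
                     bbox = list(z = zr, y = yr, x = xr),
                     dims_cropped = dv,
                     spacing = stack$spacing,
                     n_voxels = nrow(idx),
                     id = id),
                class = "condensate_mask")
  }
  ord <- order(vapply(masks, function(m) m$n_voxels, numeric(1)),
               decreasing = TRUE)
  masks <- masks[ord]
  for (i in seq_along(masks)) masks[[i]]$id <- i
  masks
}

#' @export
print.condensate_mask <- function(x, ...) {
  cat(sprintf("condensate mask #%d: %d voxels, bbox %d slices in z\n",
              x$id, x$n_voxels, diff(x$bbox$z) + 1L))
  invisible(x)
}

#' Extract an axisymmetric profile from a condensate mask
#'
#' Converts a 3D condensate mask into (r, z) profile coordinates: each xy
#' slice is hole-filled, its radius taken as the equivalent-area disk
#' radius `sqrt(A / pi)` and augmented by the planar distance between the
#' slice's disk centre and the xy centroid axis of the whole droplet, so
#' that the radius is the mean distance from the optimal symmetry axis.
#' z is assigned at slice centres above the base (the substrate plane is
#' the bottom face of the base slice, so the base slice centre sits at
#' z = dz/2) and the apex point `(0, z_max)` is appended, with `z_max` the
#' top of the highest occupied slice.
#'
#' @param mask A `condensate_mask` from [segment_stack()].
#' @param spacing Voxel spacing; defaults to the spacing stored in the
#'   mask.
#' @return A [drop_profile()] with `source = "extracted"`.
#' @export
extract_profile <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "condensate_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]
  vox <- mask$voxels
  nzb <- dim(vox)[1]

  filled <- vector("list", nzb)
  for (j in seq_len(nzb)) {
    sl <- vox[j, , , drop = TRUE]
    if (!is.matrix(sl)) sl <- matrix(sl, dim(vox)[2], dim(vox)[3])
    if (any(sl)) {
      f <- EBImage::fillHull(EBImage::Image(sl * 1))
      filled[[j]] <- as.array(f) > 0.5
    } else {
      filled[[j]] <- sl
    }
  }
  # whole-droplet centroid axis (um, lab frame of the cropped volume)
  tot <- 0; cx <- 0; cy <- 0
  for (j in seq_len(nzb)) {
    sl <- filled[[j]]
    a <- sum(sl)
    if (a == 0) next
    idx <- which(sl, arr.ind = TRUE)
    cy <- cy + sum((mask$bbox$y[1] + idx[, 1] - 1 - 0.5) * dy)
    cx <- cx + sum((mask$bbox$x[1] + idx[, 2] - 1 - 0.5) * dx)
    tot <- tot + a
  }
  if (tot == 0) stop("empty mask")
  axis_xy <- c(cx / tot, cy / tot)

  r <- numeric(0); z <- numeric(0)
  skipped <- 0L
  jtop <- 0L
  for (j in seq_len(nzb)) {
    sl <- filled[[j]]
    a <- sum(sl)
    if (a == 0) { skipped <- skipped + 1L; next }
    jtop <- j
    idx <- which(sl, arr.ind = TRUE)
    cxy <- c(mean((mask$bbox$x[1] + idx[, 2] - 1 - 0.5) * dx),
             mean((mask$bbox$y[1] + idx[, 1] - 1 - 0.5) * dy))
    r_eq <- sqrt(a * dx * dy / pi)
    offset <- sqrt(sum((cxy - axis_xy)^2))
    # slice 1 of the cropped volume is the base slice; the substrate plane
    # is its bottom face, so slice centres sit at half-integer heights
    zj <- (mask$bbox$z[1] + j - 1 - 0.5) * dz
    r <- c(r, r_eq + offset)
    z <- c(z, zj)
  }
  if (skipped > 0)
    message(sprintf("extract_profile: skipped %d empty slice(s)", skipped))
  z_max <- (mask$bbox$z[1] + jtop - 1) * dz
  drop_profile(c(r, 0), c(z, z_max), source = "extracted")
}
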