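#' Optical configuration for the confocal imaging simulator
#'
#' Refractive indices and aperture of the imaging model: immersion oil
#' 1.518, borosilicate coverslip 1.523 (treated as index-matched to the
#' oil, a 0.3 percent mismatch), aqueous buffer 1.334, condensate 1.41
#' (protein-rich) or 1.33 (protein-poor), numerical aperture 1.4.
#'
#' @param n_oil,n_glass,n_buffer,n_condensate Refractive indices.
#' @param num_aperture Numerical aperture (0 < NA < n_oil).
#' @param n_rays Rays per focal cone (fixed angular grid; no randomness).
#' @param grid Rendering spacing of apparent images (um).
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(n_oil = 1.518, n_glass = 1.523,
                           n_buffer = 1.334, n_condensate = 1.41,
                           num_aperture = 1.4, n_rays = 41, grid = 0.25) {
  idx <- c(n_oil, n_glass, n_buffer, n_condensate)
  if (any(idx < 1)) stop("refractive indices must be >= 1")
  if (!(num_aperture > 0 && num_aperture < n_oil))
    stop("require 0 < NA < n_oil")
  structure(list(n_oil = n_oil, n_glass = n_glass, n_buffer = n_buffer,
                 n_condensate = n_condensate, num_aperture = num_aperture,
                 n_rays = as.integer(n_rays), grid = grid),
            class = "optical_config")
}

#' Refract a direction vector by Snell's law
#'
#' @param direction Unit vector (length 2 or 3), the incident ray
#'   direction.
#' @param normal Unit surface normal.
#' @param n1,n2 Refractive indices on the incident and transmitted sides.
#' @return A list with `direction` (unit vector, or `NULL` on total
#'   internal reflection) and `tir` flag.
#' @examples
#' snell_refract(c(sin(pi/4), -cos(pi/4)), c(0, 1), 1.518, 1.334)
#' @export
snell_refract <- function(direction, normal, n1, n2) {
  if (sqrt(sum(direction^2)) < 1e-12 || sqrt(sum(normal^2)) < 1e-12)
    stop("zero-length vector")
  d <- direction / sqrt(sum(direction^2))
  nn <- normal / sqrt(sum(normal^2))
  cosi <- -sum(d * nn)
  if (cosi < 0) { nn <- -nn; cosi <- -cosi }
  eta <- n1 / n2
  sin2t <- eta^2 * (1 - cosi^2)
  if (sin2t > 1) return(list(direction = NULL, tir = TRUE))
  out <- eta * d + (eta * cosi - sqrt(1 - sin2t)) * nn
  list(direction = out / sqrt(sum(out^2)), tir = FALSE)
}

#' Render the apparent confocal image of a spherical cap
#'
#' Deterministic meridional ray tracing: for every nominal focal position
#' on an (x, z) grid, a fan of rays spanning the numerical aperture
#' (uniform in pupil coordinate) is refracted at the substrate plane
#' (oil to buffer, or oil to condensate beneath the cap) and at the
#' spherical cap surface; the ideal focus is replaced by the cloud of
#' pairwise ray crossings, and the recorded intensity is the fraction of
#' those crossings lying inside the fluorescent cap. Nominal focal
#' positions are where the rays would converge in homogeneous oil, i.e.
#' uncorrected stage coordinates, which is what makes the apparent image
#' axially stretched relative to the true cap.
#'
#' @param cap A [spherical_cap()].
#' @param optics An [optical_config()].
#' @param z_extent Highest nominal focal height rendered, as a multiple of
#'   the true cap height.
#' @return A list of class `apparent_image`: `img` (matrix, rows = z),
#'   `x`, `z` (grid coordinates, um), `cap`, `optics`.
#' @export
render_apparent_image <- function(cap, optics = optical_config(),
                                  z_extent = 1.45) {
  stopifnot(inherits(cap, "spherical_cap"), inherits(optics, "optical_config"))
  g <- optics$grid
  # caps beyond 90 degrees bulge out to the sphere radius at the equator
  xmax <- max(cap$r_contact, cap$R_sphere) + 3
  xg <- seq(-xmax, xmax, by = g)
  zg <- seq(g / 2, z_extent * cap$height + 2, by = g)
  img <- trace_apparent_image_cpp(cap$R_sphere, cap$z_center,
                                  optics$n_oil, optics$n_buffer,
                                  optics$n_condensate, optics$num_aperture,
                                  optics$n_rays, xg, zg)
  structure(list(img = img, x = xg, z = zg, cap = cap, optics = optics),
            class = "apparent_image")
}

#' Extract an apparent drop profile from a rendered image
#'
#' For each nominal z the apparent radius is half the distance between the
#' left and right half-maximum crossings of the intensity row; the apex is
#' placed where the on-axis intensity column drops through the half level.
#'
#' @param im An `apparent_image` from [render_apparent_image()].
#' @param level Intensity threshold defining the apparent boundary.
#' @return A [drop_profile()] with `source = "extracted"`.
#' @export
apparent_profile <- function(im, level = 0.5) {
  stopifnot(inherits(im, "apparent_image"))
  img <- im$img; xg <- im$x; zg <- im$z
  r <- numeric(0); z <- numeric(0)
  lerp_at <- function(v1, v2, x1, x2) {
    if (abs(v2 - v1) < 1e-12) return((x1 + x2) / 2)
    x1 + (level - v1) / (v2 - v1) * (x2 - x1)
  }
  for (i in seq_along(zg)) {
    row <- img[i, ]
    if (max(row) < level) next
    above <- which(row >= level)
    lo <- above[1]; hi <- above[length(above)]
    xl <- if (lo > 1) lerp_at(row[lo - 1], row[lo], xg[lo - 1], xg[lo])
          else xg[lo]
    xr <- if (hi < length(xg)) lerp_at(row[hi], row[hi + 1], xg[hi],
                                       xg[hi + 1])
          else xg[hi]
    r <- c(r, (xr - xl) / 2)
    z <- c(z, zg[i])
  }
  if (length(r) < 3) stop("no apparent boundary found at this level")
  # apex where the on-axis intensity column last drops through the level
  # (off-axis caustic halos above the drop are not part of the profile)
  icx <- which.min(abs(xg))
  col <- img[, icx]
  jlast <- max(which(col >= level))
  z_apex <- if (jlast < length(zg)) {
    lerp_at(col[jlast], col[jlast + 1], zg[jlast], zg[jlast + 1])
  } else zg[jlast] + (zg[2] - zg[1]) / 2
  keep <- z < z_apex
  drop_profile(c(r[keep], 0), c(z[keep], z_apex), source = "extracted")
}

#' Vertical rescale factor aligning apparent and true contact angles
#'
#' Renders apparent images of a panel of spherical caps, extracts their
#' apparent profiles, and scans vertical shrink factors: each candidate
#' factor divides the apparent z coordinates before Young-Laplace fitting,
#' and the factor minimizing the summed absolute contact-angle error over
#' the panel is returned. A coarse grid is refined once around its
#' minimum. For index-matched optics the factor is 1 within tolerance.
#'
#' @param optics An [optical_config()].
#' @param true_thetas Panel of true contact angles (degrees).
#' @param radii Panel of contact radii (um); recycled against
#'   `true_thetas`.
#' @param factors Candidate factors for the coarse scan.
#' @param refine Step of the refinement scan around the coarse minimum.
#' @param fit_config Passed to [fit_profile()].
#' @return A list: `factor` (the optimal vertical rescale factor),
#'   `error_deg` (summed absolute theta error at the optimum), `table`
#'   (factor vs summed error for the coarse scan), `fits` (per-cap fitted
#'   theta at the optimal factor).
#' @export
apparent_axial_scale <- function(optics = optical_config(),
                                 true_thetas = c(90, 110, 120, 130),
                                 radii = 12,
                                 factors = seq(1.0, 1.4, by = 0.02),
                                 refine = 0.005,
                                 fit_config = list(min_contact_radius = 0)) {
  radii <- rep_len(radii, length(true_thetas))
  profs <- vector("list", length(true_thetas))
  for (i in seq_along(true_thetas)) {
    cap <- spherical_cap(true_thetas[i], radii[i])
    im <- render_apparent_image(cap, optics)
    profs[[i]] <- apparent_profile(im)
  }
  panel_error <- function(f) {
    err <- 0
    for (i in seq_along(profs)) {
      p <- rescale_profile(profs[[i]], 1 / f)
      res <- tryCatch(fit_profile(p, config = fit_config),
                      error = function(e) NULL)
      if (is.null(res) || !is.finite(res$theta))
        stop(sprintf("fit failed for cap theta = %g deg, r = %g um",
                     true_thetas[i], radii[i]))
      err <- err + abs(res$theta - true_thetas[i])
    }
    err
  }
  coarse <- vapply(factors, panel_error, numeric(1))
  best <- factors[which.min(coarse)]
  fine <- seq(best - 0.02, best + 0.02, by = refine)
  fine <- fine[fine > 0]
  fine_err <- vapply(fine, panel_error, numeric(1))
  f_opt <- fine[which.min(fine_err)]
  fits <- vapply(seq_along(profs), function(i) {
    fit_profile(rescale_profile(profs[[i]], 1 / f_opt),
                config = fit_config)$theta
  }, numeric(1))
  list(factor = f_opt, error_deg = min(fine_err),
       table = data.frame(factor = factors, error_deg = coarse),
       fits = data.frame(theta_true = true_thetas, r_contact = radii,
                         theta_fit = fits))
}

#' Anisotropic Gaussian model PSF
#'
#' A separable Gaussian point-spread function, elongated axially as is
#' typical for confocal detection; defaults (sigma 0.15 um lateral,
#' 0.55 um axial) approximate a 1.4 NA oil objective imaging at moderate
#' depth into an aqueous sample.
#'
#' @param sigma_lateral,sigma_axial Gaussian widths (um).
#' @param spacing Voxel spacing `c(dx, dy, dz)` (um).
#' @param extent Half-width of the grid in units of sigma; values below 3
#'   leave noticeable mass outside the grid and trigger a warning.
#' @return An object of class `psf`: `grid` (3D array (z, y, x), summing
#'   to 1), `spacing`, `sigma = c(lateral, axial)`.
#' @export
model_psf <- function(sigma_lateral = 0.15, sigma_axial = 0.55,
                      spacing = c(0.24, 0.24, 0.42), extent = 4) {
  if (sigma_lateral <= 0 || sigma_axial <= 0) stop("sigmas must be positive")
  if (extent < 3) warning("extent < 3 sigma truncates the PSF noticeably")
  half <- c(z = max(1, ceiling(extent * sigma_axial / spacing[3])),
            y = max(1, ceiling(extent * sigma_lateral / spacing[2])),
            x = max(1, ceiling(extent * sigma_lateral / spacing[1])))
  ax <- function(n, d, s) {
    x <- seq(-n, n) * d
    k <- exp(-x^2 / (2 * s^2))
    k
  }
  kz <- ax(half["z"], spacing[3], sigma_axial)
  ky <- ax(half["y"], spacing[2], sigma_lateral)
  kx <- ax(half["x"], spacing[1], sigma_lateral)
  g <- outer(outer(kz, ky), kx)
  g <- g / sum(g)
  structure(list(grid = g, spacing = spacing,
                 sigma = c(lateral = sigma_lateral, axial = sigma_axial)),
            class = "psf")
}

#' @export
print.psf <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("PSF: %d x %d x %d voxels (z, y, x), spacing %s um\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Measure a PSF proxy from bead stacks
#'
#' Emulates PSF measurement from z-stacks of sub-resolution fluorescent
#' beads: bright spots are detected, a fixed window around each is
#' extracted with sub-voxel recentring by centroid shift, the windows are
#' averaged, the modal background is subtracted, negatives are clipped and
#' the result normalized to unit sum. Windows overlapping another spot or
#' the stack boundary are rejected and counted.
#'
#' @param bead_stacks A list of [stack3d()] objects with a `fluorescence`
#'   channel containing one or more isolated bright spots.
#' @param bead_diameter Nominal bead diameter (um); sets the minimum
#'   separation below which spots are considered overlapping.
#' @param half_window Window half-size `c(z, y, x)` in voxels.
#' @return A `psf` object with attribute `n_rejected`.
#' @export
measure_psf_proxy <- function(bead_stacks, bead_diameter = 0.1,
                              half_window = c(8, 6, 6)) {
  if (inherits(bead_stacks, "stack3d")) bead_stacks <- list(bead_stacks)
  if (!length(bead_stacks)) stop("no bead stacks supplied")
  spacing <- bead_stacks[[1]]$spacing
  hw <- as.integer(half_window)
  acc <- NULL; n_used <- 0L; n_rejected <- 0L
  min_sep <- max(bead_diameter / min(spacing), 2 * max(hw) * 0.75)

  for (st in bead_stacks) {
    arr <- st$channels$fluorescence
    d <- dim(arr)
    bg <- stats::median(arr)
    thr <- bg + 0.5 * (max(arr) - bg)
    cand <- which(arr > thr, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    lab <- label_components_cpp(as.logical(arr > thr), as.integer(d), 26L)
    lab <- array(lab, d)
    for (id in setdiff(unique(as.integer(lab)), 0L)) {
      idx <- which(lab == id, arr.ind = TRUE)
      wts <- arr[idx]
      ctr <- colSums(idx * wts) / sum(wts)
      near <- vapply(setdiff(unique(as.integer(lab)), c(0L, id)),
                     function(other) {
        oidx <- which(lab == other, arr.ind = TRUE)
        octr <- colMeans(oidx)
        sqrt(sum((octr - ctr)^2)) < min_sep
      }, logical(1))
      ci <- round(ctr)
      if (any(near) ||
          any(ci - hw < 1) || any(ci + hw > d)) {
        n_rejected <- n_rejected + 1L
        next
      }
      win <- arr[(ci[1] - hw[1]):(ci[1] + hw[1]),
                 (ci[2] - hw[2]):(ci[2] + hw[2]),
                 (ci[3] - hw[3]):(ci[3] + hw[3])]
      # sub-voxel recentring by linear shift of the sampling grid
      win <- shift_array3(win, ctr - ci)
      acc <- if (is.null(acc)) win else acc + win
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0) stop("no usable bead spots found")
  avg <- acc / n_used
  # modal background from a coarse histogram
  h <- hist(avg, breaks = 64, plot = FALSE)
  mode_bg <- h$mids[which.max(h$counts)]
  avg <- pmax(avg - mode_bg, 0)
  s <- sum(avg)
  if (s <= 0) stop("PSF proxy is empty after background subtraction")
  out <- structure(list(grid = avg / s, spacing = spacing,
                        sigma = NULL),
                   class = "psf")
  attr(out, "n_rejected") <- n_rejected
  out
}

# trilinear shift of a 3D array by a fractional voxel offset: out(i) =
# in(i + shift), linearly interpolated, edge-clamped
shift_array3 <- function(arr, shift) {
  for (ax in 1:3) {
    s <- shift[ax]
    if (abs(s) < 1e-9) next
    n <- dim(arr)[ax]
    src <- seq_len(n) + s
    j0 <- pmin(pmax(floor(src), 1), n - 1)
    w <- pmin(pmax(src - j0, 0), 1)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    anew <- (1 - w) * a[j0, , , drop = FALSE] + w * a[j0 + 1, , , drop = FALSE]
    arr <- aperm(anew, order(perm))
  }
  arr
}

#' Convolve a stack with a PSF
#'
#' Zero-padded linear convolution of each channel's fluorescence with a
#' normalized PSF; total intensity is conserved up to boundary truncation.
#'
#' @param stack A [stack3d()].
#' @param psf A `psf` object with spacing matching the stack within 1
#'   percent.
#' @param channels Channels to blur (default only `fluorescence`; the
#'   reflection channel arises from a different contrast mechanism).
#' @return A [stack3d()].
#' @export
convolve_with_psf <- function(stack, psf, channels = "fluorescence") {
  stopifnot(inherits(stack, "stack3d"), inherits(psf, "psf"))
  if (any(abs(stack$spacing - psf$spacing) / stack$spacing > 0.01))
    stop("stack and PSF voxel spacing differ by more than 1 percent")
  chans <- stack$channels
  for (ch in channels) {
    if (!ch %in% names(chans)) stop(sprintf("no channel '%s'", ch))
    chans[[ch]] <- pmax(fft_convolve3(chans[[ch]], psf$grid), 0)
  }
  stack3d(chans, spacing = stack$spacing, base_index = stack$base_index,
          meta = c(stack$meta, list(psf_convolved = TRUE)))
}

#' Contact angle versus contact radius under PSF blurring
#'
#' Voxelizes spherical caps of fixed true contact angle over a panel of
#' contact radii, blurs each stack with the PSF, and runs the full
#' segmentation and Young-Laplace fitting pipeline (no axial rescale, no
#' minimum-radius filter). As the cap size approaches the PSF the fitted
#' contact angle deviates increasingly from the truth, which is the
#' behaviour motivating the 10 um minimum contact-radius rule.
#'
#' @param theta_true True contact angle (degrees).
#' @param radii Panel of contact radii (um). The default samples densely
#'   below 2 um, where the distortion by the default PSF rises well above
#'   the ~0.5 degree voxel-quantization noise of the pipeline, with sparse
#'   anchors at larger radii.
#' @param psf_sigma `c(lateral, axial)` Gaussian PSF widths (um); the PSF
#'   is rendered at each stack's voxel spacing.
#' @param spacing_fun Function mapping contact radius to voxel spacing;
#'   the default refines the grid for small caps and coarsens it for
#'   large ones to keep stacks tractable.
#' @return A data frame `r_contact_um`, `theta_fit_deg`, `ok` (fit
#'   success); failed radii are recorded and the study continues.
#' @export
theta_vs_radius_study <- function(theta_true = 120,
                                  radii = c(1, 1.25, 1.5, 1.75, 2, 5, 12,
                                            26),
                                  psf_sigma = c(0.15, 0.55),
                                  spacing_fun = NULL) {
  if (is.null(spacing_fun))
    spacing_fun <- function(r) {
      d <- max(0.2, 2 * r / 100)  # fine isotropic grid, coarsened for
      c(d, d, d)                  # large caps to keep stacks tractable
    }
  rows <- lapply(radii, function(r) {
    sp <- spacing_fun(r)
    cap <- spherical_cap(theta_true, r)
    st <- voxelize(cap_profile(cap, n_points = 400), spacing = sp,
                   pad = max(2, 6 * psf_sigma[2]))
    psf <- model_psf(psf_sigma[1], psf_sigma[2], spacing = sp)
    st <- convolve_with_psf(st, psf)
    th <- tryCatch({
      tab <- measure_contact_angles(st, rescale_factor = 1,
                                    apply_radius_filter = FALSE)
      if (nrow(tab) < 1 || !is.finite(tab$theta_deg[1]))
        stop("no condensate fitted")
      tab$theta_deg[1]
    }, error = function(e) NA_real_)
    data.frame(r_contact_um = r, theta_fit_deg = th, ok = is.finite(th))
  })
  do.call(rbind, rows)
}
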