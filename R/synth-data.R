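#' Two-channel confocal stack container
#'
#' A 3D voxel image with named channels, voxel spacing and the z index of
#' the substrate plane. Arrays are ordered `(z, y, x)`; the voxel with
#' index `i` (1-based) along an axis spans `[(i-1), i] * spacing` so its
#' centre sits at `(i - 0.5) * spacing`. The substrate plane z = 0 is the
#' bottom face of slice `base_index` (whose centre therefore sits at
#' z = spacing/2); the bright reflection plane is rendered one voxel thick
#' at `base_index`.
#'
#' @param channels Named list of 3D numeric arrays with identical
#'   dimensions; canonical names are `fluorescence` and `reflection`.
#' @param spacing Voxel spacing `c(dx, dy, dz)` in um/voxel.
#' @param base_index 1-based z index of the substrate plane.
#' @param meta Optional list of metadata (ground truth, seeds, ...).
#' @return An object of class `stack3d`.
#' @export
stack3d <- function(channels, spacing, base_index = 1L, meta = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- dim(channels[[1]])
  if (length(dims) != 3) stop("channels must be 3D arrays (z, y, x)")
  for (ch in channels) {
    if (!identical(dim(ch), dims)) stop("all channels must share dimensions")
    if (any(ch < 0)) stop("intensities must be non-negative")
  }
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive numbers (dx, dy, dz)")
  if (base_index < 1 || base_index > dims[1])
    stop("base_index outside the stack")
  structure(list(channels = channels, spacing = as.numeric(spacing),
                 base_index = as.integer(base_index), meta = meta),
            class = "stack3d")
}

#' @export
print.stack3d <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("stack3d: %d x %d x %d voxels (z, y, x), channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")),
      sprintf("  spacing %.3g x %.3g x %.3g um, base plane at z index %d\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$base_index))
  invisible(x)
}

#' Noise model for synthetic stacks
#'
#' @param gaussian_sigma Additive Gaussian noise scale (intensity units,
#'   >= 0).
#' @param poisson Apply Poisson (shot) noise to intensities first?
#' @param seed Integer seed; the generator is a pure function of
#'   (stack, model).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 5, poisson = FALSE, seed = 1L) {
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  structure(list(gaussian_sigma = gaussian_sigma, poisson = isTRUE(poisson),
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Voxelize an axisymmetric profile into a two-channel stack
#'
#' Renders the solid of revolution of a drop profile into a fluorescence
#' channel (uniform interior intensity over background) and a reflection
#' channel marking the substrate plane, emulating a two-channel confocal
#' z-stack of a sessile condensate. Membership is decided at voxel
#' centres (no antialiasing).
#'
#' @param profile A [drop_profile()].
#' @param spacing Voxel spacing `c(dx, dy, dz)` um; default
#'   `c(0.24, 0.24, 0.42)`, typical of a 63x/1.4 oil-immersion confocal
#'   stack.
#' @param intensities Named list or vector: `inside`, `background`,
#'   `reflection_peak`.
#' @param pad Lateral and top clearance around the drop (um).
#' @param below_base Depth of recorded volume below the substrate (um).
#' @param center_xy Lateral drop centre (um); defaults to the grid centre.
#' @return A [stack3d()] with channels `fluorescence` and `reflection`.
#' @examples
#' pr <- cap_profile(spherical_cap(90, 10))
#' st <- voxelize(pr, spacing = c(0.5, 0.5, 0.5))
#' @export
voxelize <- function(profile, spacing = c(0.24, 0.24, 0.42),
                     intensities = c(inside = 100, background = 5,
                                     reflection_peak = 1000),
                     pad = 3, below_base = 1.5, center_xy = NULL) {
  stopifnot(inherits(profile, "drop_profile"))
  if (any(spacing <= 0)) stop("spacing must be positive")
  inten <- as.list(intensities)
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]
  rmax <- max(profile$r); zmax <- max(profile$z)
  nx <- ceiling((2 * rmax + 2 * pad) / dx)
  ny <- ceiling((2 * rmax + 2 * pad) / dy)
  n_below <- max(1L, ceiling(below_base / dz))
  base_index <- n_below + 1L
  nz <- base_index + ceiling((zmax + pad) / dz)
  if (is.null(center_xy))
    center_xy <- c(nx * dx / 2, ny * dy / 2)
  if (center_xy[1] - rmax < 0 || center_xy[1] + rmax > nx * dx ||
      center_xy[2] - rmax < 0 || center_xy[2] + rmax > ny * dy)
    stop("drop does not fit inside the padded grid")

  # the substrate plane z = 0 is the bottom face of the base slice, so
  # slice centres sit at half-integer heights above it
  zc <- (seq_len(nz) - base_index + 0.5) * dz
  xc <- (seq_len(nx) - 0.5) * dx - center_xy[1]
  yc <- (seq_len(ny) - 0.5) * dy - center_xy[2]
  rho2 <- outer(yc^2, xc^2, `+`)  # (y, x) squared lateral distance

  # drop radius at each slice height (0 outside [0, zmax])
  r_of_z <- function(z) {
    out <- rep(0, length(z))
    ok <- z >= 0 & z <= zmax
    if (any(ok))
      out[ok] <- approx(profile$z, profile$r, xout = pmax(z[ok], 0),
                        rule = 2)$y
    out
  }
  rz <- r_of_z(zc)

  fl <- array(inten$background, dim = c(nz, ny, nx))
  for (iz in seq_len(nz)) {
    if (zc[iz] < 0 || rz[iz] <= 0) next
    inside <- rho2 <= rz[iz]^2
    if (any(inside)) {
      sl <- fl[iz, , ]
      sl[inside] <- inten$inside
      fl[iz, , ] <- sl
    }
  }
  rf <- array(inten$background, dim = c(nz, ny, nx))
  rf[base_index, , ] <- inten$reflection_peak

  stack3d(list(fluorescence = fl, reflection = rf),
          spacing = spacing, base_index = base_index,
          meta = list(center_xy = center_xy, z_max = zmax,
                      intensities = inten))
}

#' Apply an axial stretch to a profile or a stack
#'
#' Scales z coordinates by `factor`, emulating (for `factor > 1`) the
#' apparent axial elongation introduced by imaging an aqueous sample
#' through an oil-immersion objective. Applying the stretch with
#' `factor = 1.2` and then rescaling profile coordinates by `1/1.2` is the
#' round trip that motivates the correction used before fitting. For a
#' stack, z sampling above the base plane is linearly resampled; slices
#' below the base are untouched and the grid is extended as needed.
#'
#' @param x A [drop_profile()] or a [stack3d()].
#' @param factor Axial scale factor (> 0).
#' @return An object of the same kind as `x`.
#' @export
apply_axial_stretch <- function(x, factor) {
  if (!(factor > 0)) stop("factor must be positive")
  UseMethod("apply_axial_stretch")
}

#' @export
apply_axial_stretch.drop_profile <- function(x, factor) {
  drop_profile(x$r, x$z * factor, source = attr(x, "source"))
}

#' @export
apply_axial_stretch.stack3d <- function(x, factor) {
  dims <- dim(x$channels[[1]])
  nz <- dims[1]; b <- x$base_index
  n_above <- nz - b + 1L  # slices at or above the base plane, base included
  n_new <- if (factor >= 1) ceiling(n_above * factor) else n_above
  nz_new <- b - 1L + n_new
  # target slice k (k = 1 is the base slice) has centre height (k - 0.5)
  # in slice units; its source sits at height (k - 0.5)/factor
  src <- (seq_len(n_new) - 0.5) / factor - 0.5  # 0-based offset from base
  j0 <- floor(src); w <- src - j0
  chans <- lapply(x$channels, function(arr) {
    bg <- min(arr[nz, , ])
    get_slice <- function(j) {  # 0-based offset from the base slice
      if (j < 0) arr[b, , , drop = TRUE]
      else if (j >= n_above) array(bg, dims[2:3])
      else arr[b + j, , , drop = TRUE]
    }
    out <- array(bg, dim = c(nz_new, dims[2], dims[3]))
    if (b > 1) out[seq_len(b - 1L), , ] <- arr[seq_len(b - 1L), , ]
    for (k in seq_len(n_new)) {
      s0 <- get_slice(j0[k]); s1 <- get_slice(j0[k] + 1L)
      out[b - 1L + k, , ] <- (1 - w[k]) * s0 + w[k] * s1
    }
    out
  })
  # the reflection plane is tied to the substrate, not to sample content
  if ("reflection" %in% names(chans)) {
    refl <- x$channels$reflection
    out <- chans$reflection
    keepz <- seq_len(min(nz, nz_new))
    out[keepz, , ] <- refl[keepz, , ]
    if (nz_new > nz)
      out[(nz + 1L):nz_new, , ] <- min(refl[nz, , ])
    chans$reflection <- out
  }
  stack3d(chans, spacing = x$spacing, base_index = b,
          meta = c(x$meta, list(axial_stretch = factor)))
}

#' Add reproducible noise to a stack
#'
#' Poisson (shot) noise is applied to intensities first when enabled, then
#' Gaussian noise is added; the result is clipped at zero. The output is a
#' pure function of (stack, model): the model seed is used locally without
#' disturbing the caller's RNG state.
#'
#' @param stack A [stack3d()].
#' @param model A [noise_model()].
#' @return A [stack3d()] of the same geometry.
#' @export
add_noise <- function(stack, model) {
  stopifnot(inherits(stack, "stack3d"), inherits(model, "noise_model"))
  with_seed(model$seed, {
    chans <- lapply(stack$channels, function(arr) {
      v <- as.numeric(arr)
      if (model$poisson) v <- rpois(length(v), lambda = v)
      if (model$gaussian_sigma > 0)
        v <- v + rnorm(length(v), sd = model$gaussian_sigma)
      array(pmax(v, 0), dim = dim(arr))
    })
    stack3d(chans, spacing = stack$spacing, base_index = stack$base_index,
            meta = c(stack$meta, list(noise = unclass(model))))
  })
}

#' Generate synthetic cloud-point data from a Flory-Huggins model
#'
#' Computes the transition temperature `Tp` at each requested protein
#' volume fraction as the temperature at which that composition sits on the
#' model binodal, then adds Gaussian measurement noise, emulating
#' cloud-point measurement by temperature-ramp video microscopy.
#'
#' @param fh An [fh_params()] object.
#' @param phis Volume fractions in (0, 1).
#' @param sigma_T Gaussian noise on the transition temperature (K).
#' @param seed Integer seed.
#' @param T_range Temperatures (K) outside which a composition is flagged
#'   as having no transition.
#' @return A data frame with columns `phi`, `Tp` (K) and `flag` (TRUE for
#'   compositions with no transition inside `T_range`; their `Tp` is `NA`).
#' @export
gen_cloud_points <- function(fh, phis, sigma_T = 0.5, seed = 1L,
                             T_range = c(250, 400)) {
  stopifnot(inherits(fh, "fh_params"))
  if (any(phis <= 0 | phis >= 1)) stop("phis must lie in (0, 1)")
  Tp <- vapply(phis, function(p) binodal_temperature(fh, p), numeric(1))
  flag <- !is.finite(Tp) | Tp < T_range[1] | Tp > T_range[2]
  Tp[flag] <- NA_real_
  with_seed(seed, {
    noisy <- Tp + ifelse(flag, 0, rnorm(length(Tp), sd = sigma_T))
    data.frame(phi = phis, Tp = noisy, flag = flag)
  })
}
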