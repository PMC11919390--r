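#' Young-Laplace parameter set
#'
#' Parameters of the axisymmetric sessile-drop Young-Laplace equation in its
#' arc-length (Bashforth-Adams) form: apex radius of curvature `R0`,
#' capillary length `lc`, vertical translation `z0` of the theoretical
#' profile, and the arc length `smax` up to which the surface is integrated.
#' All lengths are in micrometres.
#'
#' @param R0 Apex radius of curvature (um, > 0).
#' @param lc Capillary length (um, > 0). Large values give the
#'   gravity-free (spherical-cap) limit.
#' @param z0 Vertical translation of the theoretical profile (um); in the
#'   apex-origin convention used here this is the lab-frame height of the
#'   apex.
#' @param smax Arc length from the apex up to which the surface is
#'   integrated (um, > 0).
#' @return An object of class `yl_params`.
#' @export
yl_params <- function(R0, lc, z0 = 0, smax) {
  stopifnot(is.numeric(R0), is.numeric(lc), is.numeric(z0), is.numeric(smax))
  if (!(R0 > 0)) stop("R0 must be positive")
  if (!(lc > 0)) stop("lc must be positive")
  if (!(smax > 0)) stop("smax must be positive")
  structure(list(R0 = R0, lc = lc, z0 = z0, smax = smax),
            class = "yl_params")
}

#' @export
print.yl_params <- function(x, ...) {
  cat(sprintf("Young-Laplace parameters: R0 = %.4g um, lc = %.4g um, ",
              x$R0, x$lc),
      sprintf("z0 = %.4g um, smax = %.4g um\n", x$z0, x$smax))
  invisible(x)
}

#' Axisymmetric drop profile
#'
#' An ordered set of (r, z) coordinates describing the axisymmetric surface
#' of a sessile drop, in micrometres, with z ascending and the apex point
#' (0, z_max) as the final row. Profiles with at least 8 points can be
#' fitted with [fit_profile()].
#'
#' @param r,z Numeric vectors of equal length: radial coordinate (>= 0) and
#'   height above the substrate (>= 0).
#' @param source Provenance tag, `"synthetic"` or `"extracted"`.
#' @param append_apex If `TRUE` and the last point does not already have
#'   r = 0, a point (0, max(z)) is appended.
#' @return A data frame of class `drop_profile` with columns `r` and `z`.
#' @export
drop_profile <- function(r, z, source = c("synthetic", "extracted"),
                         append_apex = FALSE) {
  source <- match.arg(source)
  stopifnot(length(r) == length(z))
  if (append_apex && (length(r) == 0 || r[length(r)] > 0)) {
    z_apex <- if (length(z)) max(z) else 0
    r <- c(r, 0)
    z <- c(z, z_apex)
  }
  if (any(r < 0)) stop("profile radii must be non-negative")
  if (any(z < -1e-9)) stop("profile heights must be non-negative")
  if (is.unsorted(z)) stop("profile must be ordered with ascending z")
  if (r[length(r)] != 0)
    stop("profile must terminate at the apex point (0, z_max)")
  structure(data.frame(r = r, z = pmax(z, 0)),
            source = source, class = c("drop_profile", "data.frame"))
}

#' @export
print.drop_profile <- function(x, ...) {
  cat(sprintf("Axisymmetric drop profile (%s): %d points, ",
              attr(x, "source"), nrow(x)),
      sprintf("apex height %.3f um, max radius %.3f um\n",
              max(x$z), max(x$r)))
  invisible(x)
}

#' Spherical cap
#'
#' A spherical cap sitting on the substrate plane z = 0: the gravity-free
#' limit of a sessile drop. The sphere radius is
#' `R = r_contact / sin(theta)` and the cap height `R * (1 - cos(theta))`.
#'
#' @param theta Contact angle in degrees, 0 < theta < 180.
#' @param r_contact Contact-line radius (um, > 0).
#' @param center_xy Lateral position of the symmetry axis (um).
#' @return An object of class `spherical_cap` with derived fields
#'   `R_sphere`, `z_center` (sphere centre height, negative for theta < 90)
#'   and `height`.
#' @export
spherical_cap <- function(theta, r_contact, center_xy = c(0, 0)) {
  if (!(theta > 0 && theta < 180))
    stop("theta must lie strictly between 0 and 180 degrees")
  if (!(r_contact > 0)) stop("r_contact must be positive")
  th <- deg2rad(theta)
  R <- r_contact / sin(th)
  structure(list(theta = theta, r_contact = r_contact,
                 center_xy = center_xy,
                 R_sphere = R, z_center = -R * cos(th),
                 height = R * (1 - cos(th))),
            class = "spherical_cap")
}

#' Integrate the sessile-drop Young-Laplace equation
#'
#' Integrates the arc-length form of the Young-Laplace equation from the
#' apex: `dpsi/ds = 2/R0 + h/lc^2 - sin(psi)/r`, with `h` the depth below
#' the apex, `dr/ds = cos(psi)` and the surface descending from the apex.
#' The apex singularity `sin(psi)/r` is regularized by its analytic limit
#' `1/R0`. A fixed-step fourth-order Runge-Kutta scheme with at least
#' `min_steps` steps over `[0, smax]` is used.
#'
#' @param params A [yl_params()] object.
#' @param n_points Number of output states, evenly spaced in arc length.
#' @param min_steps Minimum number of integration steps (step size is at
#'   most `smax / min_steps`).
#' @return A list with elements
#'   * `profile`: a [drop_profile()] with z measured from the arc endpoint
#'     (the endpoint is placed at z = 0; the apex is the final row),
#'   * `psi_end`: surface inclination at `smax` in degrees (equals the
#'     contact angle when the arc ends on the substrate),
#'   * `arc`: the raw integration states (s, psi in radians, r, u) where u
#'     is the signed vertical coordinate, 0 at the apex and negative below.
#' @examples
#' p <- yl_params(R0 = 10, lc = 1e6, smax = pi * 10 / 2)
#' out <- integrate_profile(p, n_points = 200)
#' out$psi_end  # 90 degrees: a hemisphere in the gravity-free limit
#' @export
integrate_profile <- function(params, n_points = 1000, min_steps = 2000) {
  stopifnot(inherits(params, "yl_params"), n_points >= 2)
  arc <- yl_arc_cpp(params$R0, params$lc, params$smax, as.integer(n_points),
                    as.integer(min_steps))
  u_end <- arc[nrow(arc), "u"]
  # endpoint at z = 0; apex (s = 0, r = 0) ends up as the last row
  z <- rev(arc[, "u"] - u_end)
  r <- rev(arc[, "r"])
  prof <- drop_profile(r = r, z = z, source = "synthetic")
  list(profile = prof,
       psi_end = unname(rad2deg(arc[nrow(arc), "psi"])),
       arc = arc)
}

#' Analytic spherical-cap profile
#'
#' Exact (r, z) coordinates of a spherical cap sampled uniformly in polar
#' angle from the contact line to the apex.
#'
#' @param cap A [spherical_cap()] object.
#' @param n_points Number of profile points (the apex point included).
#' @return A [drop_profile()].
#' @examples
#' cap_profile(spherical_cap(theta = 90, r_contact = 10), n_points = 50)
#' @export
cap_profile <- function(cap, n_points = 200) {
  stopifnot(inherits(cap, "spherical_cap"), n_points >= 2)
  th <- deg2rad(cap$theta)
  # polar angle from the upward axis: 0 at apex, th at the contact line
  ang <- seq(th, 0, length.out = n_points)
  r <- cap$R_sphere * sin(ang)
  z <- cap$z_center + cap$R_sphere * cos(ang)
  r[n_points] <- 0
  drop_profile(r = r, z = pmax(z, 0), source = "synthetic")
}

#' Read / write drop profiles as CSV
#'
#' Profiles are stored as two-column CSV (`r_um`, `z_um`), ascending z,
#' apex row last.
#'
#' @param profile A [drop_profile()].
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly;
#'   `read_profile_csv` returns a [drop_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "drop_profile"))
  write.csv(data.frame(r_um = profile$r, z_um = profile$z),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @param source Provenance tag for the profile read from disk.
#' @export
read_profile_csv <- function(path, source = "extracted") {
  d <- read.csv(path)
  if (!all(c("r_um", "z_um") %in% names(d)))
    stop("profile CSV must have columns r_um and z_um")
  drop_profile(d$r_um, d$z_um, source = source)
}
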