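#' Axial rescale of a profile before fitting
#'
#' Divides the z coordinates of an extracted profile by 1.2 (i.e. applies
#' `factor = 1/1.2`) to correct for the apparent axial stretch caused by
#' imaging an aqueous sample with an oil-immersion objective; radial
#' coordinates are untouched. Applied before Young-Laplace fitting.
#'
#' @param profile A [drop_profile()].
#' @param factor Vertical scale factor (> 0).
#' @return A rescaled [drop_profile()].
#' @export
rescale_profile <- function(profile, factor = 1 / 1.2) {
  stopifnot(inherits(profile, "drop_profile"))
  if (!(factor > 0)) stop("factor must be positive")
  drop_profile(profile$r, profile$z * factor, source = attr(profile, "source"))
}

#' Estimate the integration arc length from a profile
#'
#' Returns 1.2 times the smoothed cumulative distance between consecutive
#' profile coordinates: radii are smoothed with a centred 7-point moving
#' average (window clipped at the array ends) and the segment lengths
#' `sqrt((Rbar[i+1]-Rbar[i])^2 + (Z[i+1]-Z[i])^2)` are summed for
#' i = 4 .. N-1.
#'
#' @param profile A [drop_profile()] with at least 8 points.
#' @return Arc-length estimate in um.
#' @export
estimate_smax <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("r", "z") %in% names(profile)))
  n <- nrow(profile)
  if (n < 8) stop("at least 8 profile points are required")
  r <- profile$r; z <- profile$z
  rbar <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 3):min(n, i + 3)
    mean(r[w])
  }, numeric(1))
  i <- 4:(n - 1)
  1.2 * sum(sqrt((rbar[i + 1] - rbar[i])^2 + (z[i + 1] - z[i])^2))
}

#' Young-Laplace fit objective
#'
#' Integrates the Young-Laplace equation for the trial parameters,
#' generates `n_trial` points evenly spaced in arc length from 0 to smax,
#' translates them vertically by z0, and returns the mean squared distance
#' from each observed profile point to its nearest trial point (um^2).
#'
#' @param params A [yl_params()] object.
#' @param profile A [drop_profile()].
#' @param n_trial Number of trial points (default 1000).
#' @return The objective value in um^2 (`Inf` if the integration leaves
#'   the valid domain).
#' @export
yl_objective <- function(params, profile, n_trial = 1000) {
  stopifnot(inherits(params, "yl_params"), inherits(profile, "drop_profile"))
  val <- yl_lambda_cpp(params$R0, params$lc, params$z0, params$smax,
                       profile$r, profile$z, as.integer(n_trial), 2000L)
  if (val < 0) Inf else val
}

# initial apex radius from a circle fit (Kasa algebraic fit) to the upper
# half of the profile, mirrored about the symmetry axis
circle_init <- function(profile) {
  top <- profile[profile$z >= max(profile$z) / 2, , drop = FALSE]
  if (nrow(top) < 3) top <- profile
  x <- c(top$r, -top$r); y <- c(top$z, top$z)
  # centre on the axis: r^2 + z^2 = 2 b z + c with c = R^2 - b^2
  fit <- lm(I(x^2 + y^2) ~ y)
  b <- coef(fit)[2] / 2
  R2 <- coef(fit)[1] + b^2
  R0 <- if (is.finite(R2) && R2 > 0) sqrt(R2) else max(profile$r)
  list(R0 = unname(R0), z_center = unname(b))
}

#' Fit the Young-Laplace equation to a drop profile
#'
#' Minimizes the nearest-trial-point objective over (R0, lc, z0) by
#' Nelder-Mead, with the arc length fixed at [estimate_smax()] during
#' optimization. R0 is initialized from a circle fit to the upper half of
#' the profile, lc at 100 um (fitted in log space to stay positive and
#' tame the near-degenerate gravity-free regime), and z0 at the observed
#' apex height. After convergence the theoretical profile is re-integrated
#' until it crosses the substrate plane z = 0, smax is redefined at the
#' crossing, and the contact angle is read off as `theta = |psi(smax)|`
#' in degrees (the sign in the defining convention is pure orientation; a
#' hemisphere reports 90 degrees). If the fit quality `lambda * N / smax`
#' exceeds `quality_threshold`, the optimization is restarted from 0.5x
#' and 2x the initial R0 and the best result kept.
#'
#' @param profile A [drop_profile()] (already rescaled if an axial
#'   correction is being applied) with at least 8 points.
#' @param config Optional list overriding defaults: `n_trial` (1000),
#'   `maxit` (2000), `reltol` (1e-9), `quality_threshold` (0.5 um),
#'   `min_contact_radius` (10 um), `lc_init` (100 um), `lc_min` (lower
#'   bound on the fitted capillary length; defaults to twice the profile
#'   extent, since sessile condensates sit far below their capillary
#'   length and smaller values let gravity curvature overfit noise).
#' @return An object of class `fit_result`: `theta` (degrees), `params`
#'   (optimized [yl_params()], smax redefined at the base crossing),
#'   `lambda_val` (um^2), `contact_radius` (um), `quality_metric`
#'   (`lambda * N / smax`, um), `accepted` (quality and minimum-radius
#'   rules both satisfied), `n_points`, `reason` (why a result was
#'   rejected, or `NA`).
#' @export
fit_profile <- function(profile, config = list()) {
  stopifnot(inherits(profile, "drop_profile"))
  cfg <- modifyList(list(n_trial = 1000L, maxit = 2000L, reltol = 1e-9,
                         quality_threshold = 0.5, min_contact_radius = 10,
                         lc_init = 100, lc_min = NULL), config)
  n <- nrow(profile)
  if (n < 8) stop("at least 8 profile points are required for fitting")
  smax0 <- estimate_smax(profile)
  init <- circle_init(profile)
  z_apex <- max(profile$z)
  # capillary lengths below the drop scale would let gravity curvature
  # overfit image noise; sessile condensates sit far below their
  # capillary length, so lc is bounded below by twice the profile extent
  lc_min <- if (is.null(cfg$lc_min))
    2 * max(2 * max(profile$r), z_apex) else cfg$lc_min
  lc_init <- max(cfg$lc_init, 1.5 * lc_min)

  run_once <- function(R0_init) {
    obj <- function(par) {
      v <- yl_lambda_cpp(exp(par[1]), lc_min + exp(par[2]), par[3], smax0,
                         profile$r, profile$z, as.integer(cfg$n_trial),
                         2000L)
      if (v < 0) 1e6 else v
    }
    par0 <- c(log(R0_init), log(lc_init - lc_min), z_apex)
    opt <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(reltol = cfg$reltol, maxit = cfg$maxit))
    # Nelder-Mead simplexes collapse prematurely in the long curved
    # valley of (R0, lc, z0); restart from the solution until converged
    for (i in 1:4) {
      opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                    control = list(reltol = cfg$reltol, maxit = cfg$maxit))
      improved <- opt$value - opt2$value > 1e-3 * abs(opt$value)
      opt <- opt2
      if (!improved) break
    }
    list(R0 = exp(opt$par[1]), lc = lc_min + exp(opt$par[2]),
         z0 = opt$par[3], lambda = opt$value,
         convergence = opt$convergence)
  }

  finish <- function(sol) {
    # re-integrate until the theoretical profile reaches z = 0 and
    # redefine smax at the crossing
    cross <- find_base_crossing(sol$R0, sol$lc, sol$z0, smax0)
    if (is.null(cross)) {
      return(structure(list(theta = NA_real_, params = NULL,
                            lambda_val = sol$lambda, contact_radius = NA_real_,
                            quality_metric = Inf, accepted = FALSE,
                            n_points = n,
                            reason = "theoretical profile never reaches z = 0"),
                       class = "fit_result"))
    }
    theta <- rad2deg(abs(cross$psi))
    quality <- sol$lambda * n / cross$smax
    reasons <- character(0)
    if (!(quality <= cfg$quality_threshold))
      reasons <- c(reasons, sprintf("poor fit: lambda*N/smax = %.3g um > %.3g um",
                                    quality, cfg$quality_threshold))
    if (!(cross$r >= cfg$min_contact_radius))
      reasons <- c(reasons, sprintf("contact radius %.3g um < %.3g um",
                                    cross$r, cfg$min_contact_radius))
    structure(list(theta = theta,
                   params = yl_params(sol$R0, sol$lc, sol$z0,
                                      smax = cross$smax),
                   lambda_val = sol$lambda,
                   contact_radius = cross$r,
                   quality_metric = quality,
                   accepted = length(reasons) == 0,
                   n_points = n,
                   reason = if (length(reasons)) paste(reasons,
                                                       collapse = "; ")
                            else NA_character_),
              class = "fit_result")
  }

  sol <- run_once(init$R0)
  res <- finish(sol)
  if (!is.finite(res$quality_metric) ||
      res$quality_metric > cfg$quality_threshold) {
    for (f in c(0.5, 2)) {
      sol2 <- run_once(init$R0 * f)
      res2 <- finish(sol2)
      if (is.finite(res2$quality_metric) &&
          res2$quality_metric < res$quality_metric) res <- res2
    }
  }
  res
}

# integrate up to 3x smax and locate the first crossing of z = 0; returns
# psi (rad), r and arc length at the crossing, or NULL
find_base_crossing <- function(R0, lc, z0, smax, n_grid = 3000) {
  arc <- tryCatch(yl_arc_cpp(R0, lc, 3 * smax, as.integer(n_grid),
                             as.integer(2 * n_grid)),
                  error = function(e) NULL)
  if (is.null(arc)) {
    # integration blows up before 3 smax (e.g. psi reaching 180 degrees);
    # retry on successively shorter arcs
    for (f in c(2, 1.5, 1.25, 1, 0.75, 0.5)) {
      arc <- tryCatch(yl_arc_cpp(R0, lc, f * smax, as.integer(n_grid),
                                 as.integer(2 * n_grid)),
                      error = function(e) NULL)
      if (!is.null(arc)) break
    }
    if (is.null(arc)) return(NULL)
  }
  z <- arc[, "u"] + z0
  below <- which(z <= 0)
  if (length(below) == 0 || below[1] == 1) return(NULL)
  i <- below[1]
  w <- z[i - 1] / (z[i - 1] - z[i])  # linear interpolation weight
  lerp <- function(col)
    unname(arc[i - 1, col] + w * (arc[i, col] - arc[i - 1, col]))
  list(psi = lerp("psi"), r = lerp("r"), smax = lerp("s"))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Young-Laplace fit: theta = %.2f deg, contact radius = %.2f um\n",
              x$theta, x$contact_radius),
      sprintf("  lambda = %.3g um^2, quality lambda*N/smax = %.3g um, N = %d\n",
              x$lambda_val, x$quality_metric, x$n_points),
      sprintf("  accepted: %s%s\n", x$accepted,
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Partition fit results by the acceptance rules
#'
#' Applies the two rejection rules: fit quality `lambda * N / smax`
#' above 0.5 um (poorly fit), and contact radius below 10 um (dominated
#' by the point-spread function). Each discarded result carries its
#' reasons.
#'
#' @param results A list of `fit_result` objects.
#' @param quality_threshold Maximum accepted `lambda * N / smax` (um).
#' @param min_contact_radius Minimum accepted contact radius (um).
#' @return A list with elements `kept` and `discarded` (both lists of
#'   `fit_result`; discarded entries have their `reason` field populated).
#' @export
quality_filter <- function(results, quality_threshold = 0.5,
                           min_contact_radius = 10) {
  kept <- list(); discarded <- list()
  for (res in results) {
    reasons <- character(0)
    if (!is.finite(res$quality_metric) ||
        res$quality_metric > quality_threshold)
      reasons <- c(reasons,
                   sprintf("poor fit: lambda*N/smax = %.3g um > %.3g um",
                           res$quality_metric, quality_threshold))
    if (!is.finite(res$contact_radius) ||
        res$contact_radius < min_contact_radius)
      reasons <- c(reasons, sprintf("contact radius %.3g um < %.3g um",
                                    res$contact_radius, min_contact_radius))
    res$accepted <- length(reasons) == 0
    res$reason <- if (length(reasons)) paste(reasons, collapse = "; ")
                  else NA_character_
    if (res$accepted) kept[[length(kept) + 1L]] <- res
    else discarded[[length(discarded) + 1L]] <- res
  }
  list(kept = kept, discarded = discarded)
}

#' Full stack-to-contact-angle pipeline
#'
#' Convenience wrapper: locate the base plane, segment condensates,
#' extract axisymmetric profiles, apply the axial rescale, fit the
#' Young-Laplace equation and apply the acceptance rules.
#'
#' @param stack A [stack3d()].
#' @param rescale_factor Vertical factor applied to profiles before
#'   fitting (default `1/1.2`; use 1 for unaberrated synthetic data).
#' @param apply_radius_filter Apply the 10 um minimum contact radius rule?
#' @param fit_config Passed to [fit_profile()].
#' @return A data frame with one row per condensate: `id`, `theta_deg`,
#'   `R0_um`, `lc_um`, `z0_um`, `smax_um`, `lambda_um2`,
#'   `contact_radius_um`, `quality_um`, `n_points`, `accepted`, `reason`.
#' @export
measure_contact_angles <- function(stack, rescale_factor = 1 / 1.2,
                                   apply_radius_filter = TRUE,
                                   fit_config = list()) {
  base <- find_base(stack)
  masks <- segment_stack(stack, base = base)
  if (!apply_radius_filter) fit_config$min_contact_radius <- 0
  rows <- lapply(masks, function(m) {
    prof <- extract_profile(m)
    prof <- rescale_profile(prof, rescale_factor)
    res <- tryCatch(fit_profile(prof, config = fit_config),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(id = m$id, theta_deg = NA_real_, R0_um = NA_real_,
                        lc_um = NA_real_, z0_um = NA_real_, smax_um = NA_real_,
                        lambda_um2 = NA_real_, contact_radius_um = NA_real_,
                        quality_um = NA_real_, n_points = nrow(prof),
                        accepted = FALSE, reason = "fit error"))
    data.frame(id = m$id, theta_deg = res$theta,
               R0_um = if (is.null(res$params)) NA_real_ else res$params$R0,
               lc_um = if (is.null(res$params)) NA_real_ else res$params$lc,
               z0_um = if (is.null(res$params)) NA_real_ else res$params$z0,
               smax_um = if (is.null(res$params)) NA_real_ else res$params$smax,
               lambda_um2 = res$lambda_val,
               contact_radius_um = res$contact_radius,
               quality_um = res$quality_metric,
               n_points = res$n_points,
               accepted = res$accepted,
               reason = res$reason)
  })
  do.call(rbind, rows)
}
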