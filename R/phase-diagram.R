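#' Flory-Huggins model parameters
#'
#' Parameters of a Flory-Huggins free energy per lattice site,
#' `f(phi) = (phi/n) log(phi) + (1 - phi) log(1 - phi) + chi phi (1 - phi)`,
#' with a temperature-dependent interaction parameter
#' `chi(T) = A + B / T`. For upper-critical-solution-temperature (UCST)
#' behaviour, as shown by Ddx4 condensates, `B > 0` so that `chi`
#' decreases on heating.
#'
#' Defaults emulate an intrinsically disordered protein of 236 residues
#' with a critical temperature near 320 K.
#'
#' @param n_chain Effective polymer length in lattice sites (>= 1);
#'   conventionally the residue count of the construct.
#' @param A Entropic (temperature-independent) part of chi.
#' @param B Enthalpic coefficient of chi (K).
#' @return An object of class `fh_params` with derived critical point
#'   fields `phi_c = 1/(1 + sqrt(n))` and `chi_c = (1 + 1/sqrt(n))^2 / 2`.
#' @export
fh_params <- function(n_chain = 236, A = -1, B = 501.5) {
  if (n_chain < 1) stop("n_chain must be >= 1")
  sqn <- sqrt(n_chain)
  structure(list(n_chain = n_chain, A = A, B = B,
                 phi_c = 1 / (1 + sqn),
                 chi_c = (1 + 1 / sqn)^2 / 2),
            class = "fh_params")
}

#' @export
print.fh_params <- function(x, ...) {
  cat(sprintf("Flory-Huggins model: n = %g, chi(T) = %.4g + %.4g/T\n",
              x$n_chain, x$A, x$B),
      sprintf("  critical point: phi_c = %.4g, chi_c = %.4g",
              x$phi_c, x$chi_c))
  if (x$B > 0)
    cat(sprintf(", Tc = %.2f K", x$B / (x$chi_c - x$A)))
  cat("\n")
  invisible(x)
}

# free energy, first derivative (exchange chemical potential) and
# grand-potential-like combination g = f - phi f' used in the equal-osmotic
# condition, per lattice site in units of kT
fh_f <- function(phi, n, chi)
  phi / n * log(phi) + (1 - phi) * log(1 - phi) + chi * phi * (1 - phi)
fh_fp <- function(phi, n, chi)
  (log(phi) + 1) / n - log(1 - phi) - 1 + chi * (1 - 2 * phi)
fh_g <- function(phi, n, chi) fh_f(phi, n, chi) - phi * fh_fp(phi, n, chi)

# spinodal compositions: roots of f''(phi) = 1/(n phi) + 1/(1-phi) - 2 chi
fh_spinodal <- function(n, chi) {
  a <- 2 * chi * n
  b <- -(2 * chi * n - n + 1)
  cc <- 1
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(NULL)
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  roots[roots > 0 & roots < 1]
}

#' Binodal (coexistence) compositions at one value of chi
#'
#' Solves the two-phase coexistence conditions of the Flory-Huggins free
#' energy: equal exchange chemical potential `f'(phi1) = f'(phi2)` and the
#' equal osmotic condition `f(phi1) - phi1 f'(phi1) = f(phi2) - phi2
#' f'(phi2)` (the common-tangent construction), with the two compositions
#' bracketed on either side of the critical composition.
#'
#' @param n Chain length in lattice sites.
#' @param chi Interaction parameter.
#' @return `c(phi_dilute, phi_dense)`, or `NULL` in the one-phase region
#'   (`chi <= chi_c`).
#' @export
binodal_at_chi <- function(n, chi) {
  sqn <- sqrt(n)
  chi_c <- (1 + 1 / sqn)^2 / 2
  if (chi <= chi_c + 1e-12) return(NULL)
  sp <- fh_spinodal(n, chi)
  if (length(sp) != 2) return(NULL)
  # dense composition conjugate to a dilute phi1: f'(phi2) = f'(phi1),
  # phi2 on the increasing branch of f' beyond the dense spinodal
  eps <- 1e-13
  fp_sp2 <- fh_fp(sp[2], n, chi)
  conj <- function(phi1) {
    target <- fh_fp(phi1, n, chi)
    if (target < fp_sp2) return(NA_real_)
    uniroot(function(p) fh_fp(p, n, chi) - target,
            c(sp[2], 1 - eps), tol = 1e-15)$root
  }
  # f' is increasing on (0, sp1); the dilute candidate must offer a
  # conjugate, i.e. f'(phi1) >= f'(sp2).  Work in log(phi1): deep quenches
  # push the dilute branch many orders of magnitude below the critical
  # composition.
  t_floor <- log(1e-250)
  lo <- if (fh_fp(exp(t_floor), n, chi) >= fp_sp2) t_floor else
    uniroot(function(t) fh_fp(exp(t), n, chi) - fp_sp2,
            c(t_floor, log(sp[1])), tol = 1e-14)$root + 1e-9
  osm <- function(t) {
    phi1 <- exp(t)
    phi2 <- conj(phi1)
    if (!is.finite(phi2)) return(NA_real_)
    fh_g(phi1, n, chi) - fh_g(phi2, n, chi)
  }
  hi <- log(sp[1]) - 1e-10
  flo <- osm(lo); fhi <- osm(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
  root <- uniroot(osm, c(lo, hi), tol = 1e-14)$root
  phi1 <- exp(root)
  phi2 <- conj(phi1)
  c(phi_dilute = phi1, phi_dense = phi2)
}

#' Binodal compositions at a temperature
#'
#' Evaluates `chi(T) = A + B/T` and solves the coexistence conditions.
#'
#' @param fh An [fh_params()] object.
#' @param T Temperature (K).
#' @return A list with `phi_dilute`, `phi_dense` and `one_phase`
#'   (TRUE when `chi(T) <= chi_c` or no coexistence exists).
#' @export
binodal_at_T <- function(fh, T) {
  stopifnot(inherits(fh, "fh_params"), T > 0)
  chi <- fh$A + fh$B / T
  bn <- binodal_at_chi(fh$n_chain, chi)
  if (is.null(bn))
    return(list(phi_dilute = NA_real_, phi_dense = NA_real_,
                one_phase = TRUE, chi = chi))
  list(phi_dilute = unname(bn[1]), phi_dense = unname(bn[2]),
       one_phase = FALSE, chi = chi)
}

# chi at which a composition phi sits on the binodal (dilute branch for
# phi < phi_c, dense branch above); the branches are monotone in chi
chi_on_binodal <- function(n, phi) {
  sqn <- sqrt(n)
  chi_c <- (1 + 1 / sqn)^2 / 2
  phi_c <- 1 / (1 + sqn)
  branch <- if (phi < phi_c) 1 else 2
  f <- function(chi) {
    bn <- binodal_at_chi(n, chi)
    if (is.null(bn)) return(NA_real_)
    bn[branch] - phi
  }
  lo <- chi_c * (1 + 1e-7); hi <- chi_c + 0.05
  flo <- f(lo)
  # just above chi_c both branches are at phi_c: sign of (phi_c - phi)
  while (is.finite(f(hi)) && f(hi) * flo > 0 && hi < chi_c + 50)
    hi <- chi_c + (hi - chi_c) * 2
  if (!is.finite(flo) || !is.finite(f(hi)) || f(hi) * flo > 0)
    return(NA_real_)
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# temperature at which phi sits on the binodal of an fh model
binodal_temperature <- function(fh, phi) {
  chi <- chi_on_binodal(fh$n_chain, phi)
  if (!is.finite(chi) || chi <= fh$A) return(NA_real_)
  fh$B / (chi - fh$A)
}

#' Sample a binodal curve over a temperature grid
#'
#' @param fh An [fh_params()] object.
#' @param T_grid Temperatures (K).
#' @return A data frame `T_K`, `phi_dilute`, `phi_dense` (NA in the
#'   one-phase region).
#' @export
binodal_curve <- function(fh, T_grid) {
  rows <- lapply(T_grid, function(T) {
    b <- binodal_at_T(fh, T)
    data.frame(T_K = T, phi_dilute = b$phi_dilute, phi_dense = b$phi_dense)
  })
  do.call(rbind, rows)
}

#' Fit Flory-Huggins theory to cloud-point data
#'
#' Treats cloud points as binodal crossings: for each observed volume
#' fraction the value of chi at which it sits on the binodal is computed
#' (independent of A and B), and `chi(T) = A + B/T` is then fitted by
#' least squares of the predicted transition temperature
#' `T(phi) = B / (chi*(phi) - A)` against the observed `Tp`. The linear
#' regression of `chi*` on `1/Tp` supplies the starting point.
#'
#' @param points Data frame with columns `phi` and `Tp` (K); rows with
#'   missing `Tp` are dropped.
#' @param n_chain Chain length (fixed from the construct length).
#' @return An [fh_params()] object with attributes `residuals` (K) and
#'   `rms` (K); a fit with `B <= 0` (no UCST) is flagged with a warning.
#' @export
fit_cloud_points <- function(points, n_chain = 236) {
  stopifnot(all(c("phi", "Tp") %in% names(points)))
  pts <- points[is.finite(points$Tp), , drop = FALSE]
  if (nrow(pts) < 3) stop("at least 3 cloud points are required")
  chi_star <- vapply(pts$phi, function(p) chi_on_binodal(n_chain, p),
                     numeric(1))
  ok <- is.finite(chi_star)
  if (sum(ok) < 3) stop("fewer than 3 usable cloud points")
  pts <- pts[ok, ]; chi_star <- chi_star[ok]
  init <- coef(lm(chi_star ~ I(1 / pts$Tp)))
  obj <- function(par) {
    A <- par[1]; B <- par[2]
    Tpred <- B / (chi_star - A)
    if (any(!is.finite(Tpred)) || any(Tpred <= 0)) return(1e10)
    sum((Tpred - pts$Tp)^2)
  }
  fit <- optim(c(init[1], init[2]), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  A <- unname(fit$par[1]); B <- unname(fit$par[2])
  if (B <= 0) warning("fitted B <= 0: no UCST behaviour (degenerate fit)")
  out <- fh_params(n_chain = n_chain, A = A, B = B)
  res <- B / (chi_star - A) - pts$Tp
  attr(out, "residuals") <- res
  attr(out, "rms") <- sqrt(mean(res^2))
  out
}

#' Degree of phase separation
#'
#' The difference between the protein volume fraction inside condensates
#' and in the coexisting dilute (buffer) phase at a reference temperature;
#' condensate water content is approximately `1 - delta_phi`.
#'
#' @param fh An [fh_params()] object.
#' @param T_ref Reference temperature (K); default 295.15 K (22 C, the
#'   temperature of contact-angle measurement).
#' @return A list with `value` (`phi_dense - phi_dilute`, or `NA` in the
#'   one-phase region), `one_phase`, `T_ref`, and the branch compositions.
#' @export
delta_phi <- function(fh, T_ref = 295.15) {
  b <- binodal_at_T(fh, T_ref)
  if (b$one_phase)
    return(list(value = NA_real_, one_phase = TRUE, T_ref = T_ref,
                phi_dilute = NA_real_, phi_dense = NA_real_))
  list(value = b$phi_dense - b$phi_dilute, one_phase = FALSE,
       T_ref = T_ref, phi_dilute = b$phi_dilute, phi_dense = b$phi_dense)
}
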