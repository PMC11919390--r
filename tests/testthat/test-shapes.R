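test_that("zero-gravity integration reproduces a sphere", {
  out <- integrate_profile(yl_params(R0 = 10, lc = 1e6, smax = pi * 10 / 2),
                           n_points = 1000)
  expect_equal(out$psi_end, 90, tolerance = 1e-6)
  expect_equal(max(out$profile$r), 10, tolerance = 1e-6)
  # analytic apex limit: dpsi/ds -> 1/R0 at s -> 0
  arc <- out$arc
  dpsi <- diff(arc[1:2, "psi"]) / diff(arc[1:2, "s"])
  expect_equal(dpsi, 1 / 10, tolerance = 1e-4)
})

test_that("integration matches an independent adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  R0 <- 10; lc <- 20; smax <- 25
  out <- integrate_profile(yl_params(R0 = R0, lc = lc, smax = smax),
                           n_points = 1000)
  rhs <- function(s, y, p) {
    sp_over_r <- if (y[2] < 1e-12) 1 / R0 else sin(y[1]) / y[2]
    list(c(2 / R0 - y[3] / lc^2 - sp_over_r, cos(y[1]), -sin(y[1])))
  }
  s0 <- 1e-8
  sol <- deSolve::lsoda(c(psi = s0 / R0, r = s0, u = -s0^2 / (2 * R0)),
                        times = c(s0, out$arc[-1, "s"]), func = rhs,
                        parms = NULL, rtol = 1e-12, atol = 1e-12)
  expect_lt(max(abs(sol[-1, "r"] - out$arc[-1, "r"])), 1e-6)
  expect_lt(max(abs(sol[-1, "u"] - out$arc[-1, "u"])), 1e-6)
})

test_that("integration fails loudly when the state leaves its domain", {
  # arc longer than the closed sphere: psi passes 180 degrees
  expect_error(integrate_profile(yl_params(10, 1e6, smax = 4 * pi * 10),
                                 n_points = 100),
               "integration failed")
})

test_that("spherical cap geometry and profiles are exact", {
  cap <- spherical_cap(theta = 120, r_contact = 10)
  expect_equal(cap$R_sphere, 11.547, tolerance = 1e-4)
  expect_equal(cap$height, 17.321, tolerance = 1e-4)

  hemi <- cap_profile(spherical_cap(90, 10), n_points = 101)
  expect_equal(hemi$r[1], 10, tolerance = 1e-9)
  expect_equal(max(hemi$z), 10, tolerance = 1e-9)
  mid <- hemi[-nrow(hemi), ]
  expect_equal(mid$r, sqrt(pmax(100 - mid$z^2, 0)), tolerance = 1e-9)

  expect_s3_class(cap_profile(spherical_cap(179.9, 5), 50), "drop_profile")
  expect_error(spherical_cap(180, 5), "between 0 and 180")
  expect_error(spherical_cap(0, 5), "between 0 and 180")
})

test_that("gravity-free limit agrees with the analytic cap everywhere", {
  for (theta in c(60, 90, 140)) {
    R0 <- 8
    smax <- theta * pi / 180 * R0
    out <- integrate_profile(yl_params(R0, lc = 1e5 * R0, smax = smax),
                             n_points = 400)
    cap <- cap_profile(spherical_cap(theta, R0 * sin(theta * pi / 180)),
                       n_points = 400)
    expect_lt(max(abs(out$profile$r - cap$r)), 1e-3)
    expect_lt(max(abs(out$profile$z - cap$z)), 1e-3)
  }
})

test_that("decreasing the capillary length never raises the drop height", {
  R0 <- 10; smax <- 20
  heights <- vapply(c(1e6, 1e3, 100, 50, 30), function(lc) {
    max(integrate_profile(yl_params(R0, lc, smax = smax), 200)$profile$z)
  }, numeric(1))
  expect_true(all(diff(heights) <= 1e-9))
})

test_that("halving the integration step leaves the endpoint unchanged", {
  p <- yl_params(10, 50, smax = 20)
  a <- integrate_profile(p, 200, min_steps = 2000)$arc
  b <- integrate_profile(p, 200, min_steps = 4000)$arc
  expect_lt(abs(a[200, "r"] - b[200, "r"]), 1e-6)
  expect_lt(abs(a[200, "u"] - b[200, "u"]), 1e-6)
})

test_that("profiles enforce their invariants and survive CSV round trips", {
  expect_error(drop_profile(c(1, 0.5), c(1, 0.5)), "ascending")
  expect_error(drop_profile(c(1, 0.5), c(0.5, 1)), "apex")
  expect_error(drop_profile(c(-1, 0), c(0, 1)), "non-negative")
  pr <- cap_profile(spherical_cap(110, 7), 60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(pr, path)
  back <- read_profile_csv(path)
  expect_equal(back$r, pr$r, tolerance = 1e-12)
  expect_equal(back$z, pr$z, tolerance = 1e-12)
})
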