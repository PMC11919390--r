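test_that("the vertical rescale divides z and leaves r untouched", {
  pr <- drop_profile(c(3, 2, 0), c(0, 1.2, 2.4))
  rs <- rescale_profile(pr)  # default 1/1.2
  expect_equal(rs$z, c(0, 1, 2), tolerance = 1e-12)
  expect_identical(rs$r, pr$r)
  expect_equal(rescale_profile(pr, 1)$z, pr$z)
})

test_that("the arc-length estimate reproduces its hand-computed value", {
  # 20 collinear points with constant radius and 1 um z spacing: the
  # smoothed radii are constant, each of the 16 summed segments has
  # length 1, and the 1.2 margin gives 19.2
  pr <- data.frame(r = rep(5, 20), z = 0:19)
  expect_equal(estimate_smax(pr), 1.2 * 16, tolerance = 1e-12)

  doubled <- data.frame(r = 2 * pr$r, z = 2 * pr$z)
  expect_equal(estimate_smax(doubled), 2 * estimate_smax(pr),
               tolerance = 1e-12)

  expect_error(estimate_smax(data.frame(r = rep(5, 7), z = 0:6)),
               "at least 8")
})

test_that("the objective is zero on self-generated data and additive in
           single-point displacements", {
  p <- yl_params(12, 800, z0 = 0, smax = 20)
  out <- integrate_profile(p, n_points = 1000)
  prof <- out$profile
  z0 <- max(prof$z)  # apex height equals the z0 of the trial family
  expect_lt(yl_objective(yl_params(12, 800, z0 = z0, smax = 20), prof),
            1e-6)

  # displacing one point by d normal to a dense arc adds d^2/N
  d <- 0.2
  i <- 300
  r2 <- prof$r; z2 <- prof$z
  # outward normal direction at a point on the arc
  tang <- c(diff(prof$r[c(i - 1, i + 1)]), diff(prof$z[c(i - 1, i + 1)]))
  nrm <- c(tang[2], -tang[1]) / sqrt(sum(tang^2))
  r2[i] <- r2[i] + d * nrm[1]; z2[i] <- z2[i] + d * nrm[2]
  ord <- order(z2)  # the displacement may locally reorder z
  prof2 <- drop_profile(pmax(r2, 0)[ord], z2[ord], append_apex = FALSE)
  lam <- yl_objective(yl_params(12, 800, z0 = z0, smax = 20), prof2)
  expect_equal(lam, d^2 / nrow(prof2), tolerance = 0.05)
})

test_that("nearest-point search matches exhaustive pairwise search", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      np <- sample(5:40, 1); nt <- sample(10:200, 1)
      px <- runif(np, 0, 20); pz <- runif(np, 0, 20)
      tx <- runif(nt, 0, 20); tz <- runif(nt, 0, 20)
      fast <- condensateADSA:::nearest_sqdist_cpp(px, pz, tx, tz)
      brute <- apply(outer(px, tx, `-`)^2 + outer(pz, tz, `-`)^2, 1, min)
      expect_equal(fast, brute, tolerance = 1e-12)
    }
  })
})

test_that("fits recover known parameters on clean profiles", {
  hemi <- sessile_profile(90, 15, lc = 1e5, n_points = 120)
  res <- fit_profile(hemi)
  expect_lt(abs(res$theta - 90), 0.5)

  pr <- sessile_profile(120, 15, lc = 500, n_points = 120)
  res <- fit_profile(pr)
  expect_lt(abs(res$theta - 120), 0.5)
  expect_lt(abs(res$params$lc - 500) / 500, 0.2)
  expect_lt(abs(res$contact_radius - 15), 0.2)
  expect_true(res$accepted)
})

test_that("the optimum is never beaten by the generating parameters", {
  for (theta in c(80, 120)) {
    pr <- sessile_profile(theta, 14, lc = 600, n_points = 100)
    res <- fit_profile(pr)
    smax0 <- estimate_smax(pr)
    truth <- yl_objective(yl_params(res$params$R0, 600, max(pr$z),
                                    smax = smax0), pr)
    # evaluate both at the same fixed smax used during optimization
    fitted <- yl_objective(yl_params(res$params$R0, res$params$lc,
                                     res$params$z0, smax = smax0), pr)
    expect_lt(fitted, truth + 1e-8)
  }
})

test_that("corrupted profiles fail the quality gate", {
  pr <- sessile_profile(110, 15, lc = 500, n_points = 90)
  n <- nrow(pr)
  bad <- pr$r
  idx <- seq(2, n - 1, by = 3)  # a third of the points, 1 um corruption
  bad[idx] <- bad[idx] + rep(c(1, -1), length.out = length(idx))
  res <- fit_profile(drop_profile(pmax(bad, 0), pr$z, append_apex = FALSE))
  expect_gt(res$quality_metric, 0.5)
  expect_false(res$accepted)
  expect_match(res$reason, "poor fit")
})

test_that("the quality filter partitions results with recorded reasons", {
  mk <- function(q, rc) structure(list(theta = 100, params = NULL,
                                       lambda_val = 0.1, contact_radius = rc,
                                       quality_metric = q, accepted = NA,
                                       n_points = 50, reason = NA),
                                  class = "fit_result")
  out <- quality_filter(list(mk(0.6, 20), mk(0.1, 8), mk(0.4, 12)))
  expect_length(out$kept, 1)
  expect_length(out$discarded, 2)
  expect_match(out$discarded[[1]]$reason, "poor fit")
  expect_match(out$discarded[[2]]$reason, "contact radius")
  expect_equal(out$kept[[1]]$quality_metric, 0.4)
})

test_that("noiseless parameter recovery holds over the design sweep", {
  worst <- 0
  for (theta in c(70, 90, 110, 130)) for (rc in c(12, 20, 35))
    for (lc in c(200, 1000)) {
      pr <- sessile_profile(theta, rc, lc, n_points = 120)
      res <- fit_profile(pr)
      worst <- max(worst, abs(res$theta - theta))
    }
  expect_lt(worst, 0.5)
})

test_that("recovery degrades gracefully under 0.25 um profile noise", {
  worst <- 0
  for (theta in c(70, 90, 110, 130)) for (rc in c(12, 20, 35)) {
    pr <- noisy_profile(sessile_profile(theta, rc, 500, n_points = 120),
                        sigma = 0.25, seed = theta + rc)
    res <- fit_profile(pr)
    worst <- max(worst, abs(res$theta - theta))
  }
  expect_lt(worst, 2)
})

test_that("axial aberration closure: stretch then rescale recovers theta", {
  cap <- spherical_cap(120, 12)
  st <- apply_axial_stretch(voxelize(cap_profile(cap, 400)), 1.2)
  with_rescale <- measure_contact_angles(st, rescale_factor = 1 / 1.2)
  expect_lt(abs(with_rescale$theta_deg[1] - 120), 2)
  expect_true(with_rescale$accepted[1])
  without <- measure_contact_angles(st, rescale_factor = 1)
  expect_gt(abs(without$theta_deg[1] - 120), 2)
})
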