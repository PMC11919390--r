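test_that("Snell refraction honours its closed-form angles", {
  # normal incidence is unchanged
  out <- snell_refract(c(0, 1), c(0, -1), 1.518, 1.334)
  expect_equal(out$direction, c(0, 1), tolerance = 1e-12)
  expect_false(out$tir)

  # 45 degrees from oil into buffer refracts to arcsin(1.518 sin45 / 1.334)
  inc <- c(sin(pi / 4), cos(pi / 4))
  out <- snell_refract(inc, c(0, -1), 1.518, 1.334)
  ang <- atan2(out$direction[1], out$direction[2]) * 180 / pi
  expect_equal(ang, asin(1.518 * sin(pi / 4) / 1.334) * 180 / pi,
               tolerance = 0.1)

  # 80 degrees is beyond the critical angle
  inc80 <- c(sin(80 * pi / 180), cos(80 * pi / 180))
  expect_true(snell_refract(inc80, c(0, -1), 1.518, 1.334)$tir)
  expect_error(snell_refract(c(0, 0), c(0, 1), 1, 1.3), "zero-length")
})

test_that("refraction is reversible along the ray path", {
  withr::with_seed(21, {
    for (i in 1:25) {
      th <- runif(1, 0, 0.9)
      d <- c(sin(th), cos(th))
      nr <- c(sin(runif(1, -0.3, 0.3)), -cos(runif(1, 0, 0.2)))
      nr <- nr / sqrt(sum(nr^2))
      out <- snell_refract(d, nr, 1.334, 1.41)
      back <- snell_refract(-out$direction, nr, 1.41, 1.334)
      expect_lt(max(abs(back$direction + d)), 1e-9)
    }
  })
})

test_that("index-matched optics image the cap without distortion", {
  om <- optical_config(n_oil = 1.334, n_glass = 1.334, n_buffer = 1.334,
                       n_condensate = 1.334, num_aperture = 1.2)
  cap <- spherical_cap(120, 10)
  ap <- apparent_profile(render_apparent_image(cap, om))
  expect_lt(abs(max(ap$z) - cap$height), 0.3)
  expect_lt(abs(ap$r[1] - 10), om$grid + 1e-9)
})

test_that("oil-into-water imaging stretches the apparent cap axially", {
  cap <- spherical_cap(120, 12)
  ap <- apparent_profile(render_apparent_image(
    cap, optical_config(n_condensate = 1.33)))
  ratio <- max(ap$z) / cap$height
  expect_gt(ratio, 1.1)
  expect_lt(ratio, 1.3)
  # near the substrate rays traverse negligible sample depth, so the
  # apparent lateral extent at the base equals the true contact radius
  expect_lt(abs(ap$r[1] - 12), 0.25 + 1e-9)
})

test_that("the model PSF is normalized with the requested moments", {
  psf <- model_psf(0.15, 0.45, spacing = c(0.05, 0.05, 0.15))
  expect_equal(sum(psf$grid), 1, tolerance = 1e-6)
  expect_equal(psf_sigma_along(psf, 1), 0.45, tolerance = 0.01)
  expect_equal(psf_sigma_along(psf, 3), 0.15, tolerance = 0.01)
  # axial/lateral FWHM ratio follows the sigma ratio for a Gaussian
  p3 <- model_psf(0.1, 0.3, spacing = c(0.02, 0.02, 0.06))
  expect_equal(psf_sigma_along(p3, 1) / psf_sigma_along(p3, 3), 3,
               tolerance = 0.02)
  expect_warning(model_psf(0.15, 0.55, extent = 2), "truncates")
})

test_that("the bead-stack PSF proxy recovers a known Gaussian", {
  st <- make_bead_stack(list(c(6.05, 2.43, 2.37)))
  psf <- measure_psf_proxy(list(st), half_window = c(12, 8, 8))
  expect_equal(sum(psf$grid), 1, tolerance = 1e-6)
  expect_equal(psf_sigma_along(psf, 1), 0.55, tolerance = 0.1)
  expect_equal(psf_sigma_along(psf, 3), 0.15, tolerance = 0.1)
})

test_that("averaging shifted copies of one bead equals the single bead", {
  one <- measure_psf_proxy(list(make_bead_stack(list(c(6.0, 2.4, 2.4)))),
                           half_window = c(10, 7, 7))
  shifts <- list(c(6.0, 2.4, 2.4), c(7.1, 2.9, 1.9), c(5.2, 1.8, 2.8))
  stacks <- lapply(shifts, function(s) make_bead_stack(list(s)))
  avg <- measure_psf_proxy(stacks, half_window = c(10, 7, 7))
  expect_lt(max(abs(avg$grid - one$grid)), 0.02 * max(one$grid))
})

test_that("overlapping beads are rejected and counted", {
  # two resolved spots, but closer than the extraction window allows
  st <- make_bead_stack(list(c(6.0, 2.4, 2.4), c(6.0, 3.2, 2.4)))
  expect_error(measure_psf_proxy(list(st), half_window = c(10, 7, 7)),
               "no usable bead spots")
  arr <- array(10, c(30, 30, 30))
  flat <- stack3d(list(fluorescence = arr), spacing = c(0.1, 0.1, 0.2))
  expect_error(measure_psf_proxy(list(flat)), "no usable|no spots")
})

test_that("PSF convolution is linear, energy conserving, and exact", {
  st <- voxelize(cap_profile(spherical_cap(90, 4), 200),
                 spacing = c(0.3, 0.3, 0.3), below_base = 2.5,
                 intensities = c(inside = 100, background = 0,
                                 reflection_peak = 100))
  # delta kernel: identity
  delta <- structure(list(grid = array(c(rep(0, 13), 1, rep(0, 13)),
                                       c(3, 3, 3)),
                          spacing = c(0.3, 0.3, 0.3), sigma = NULL),
                     class = "psf")
  same <- convolve_with_psf(st, delta)
  expect_equal(same$channels$fluorescence, st$channels$fluorescence,
               tolerance = 1e-10)

  psf <- model_psf(0.2, 0.4, spacing = c(0.3, 0.3, 0.3))
  blurred <- convolve_with_psf(st, psf)
  # total intensity is conserved (zero background, object away from edges)
  expect_equal(sum(blurred$channels$fluorescence),
               sum(st$channels$fluorescence), tolerance = 1e-6)
  expect_error(convolve_with_psf(st, model_psf(0.2, 0.4,
                                               spacing = c(0.4, 0.4, 0.4))),
               "spacing")

  # FFT convolution equals the direct triple sum on a 16^3 stack
  withr::with_seed(5, {
    vol <- array(runif(16^3), c(16, 16, 16))
    kern <- array(runif(125), c(5, 5, 5))
  })
  kern <- kern / sum(kern)
  expect_lt(max(abs(condensateADSA:::fft_convolve3(vol, kern) -
                    direct_convolve3(vol, kern))) / max(vol), 1e-10)
})
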