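test_that("the base plane is the z slice with maximum mean reflection", {
  arr <- array(10, c(30, 32, 32))
  refl <- arr; refl[12, , ] <- 1000
  st <- stack3d(list(fluorescence = arr, reflection = refl),
                spacing = c(0.4, 0.4, 0.4), base_index = 12)
  expect_identical(find_base(st), 12L)

  # ties break toward the lowest slice
  refl2 <- arr; refl2[5, , ] <- 1000; refl2[9, , ] <- 1000
  st2 <- stack3d(list(fluorescence = arr, reflection = refl2),
                 spacing = c(0.4, 0.4, 0.4), base_index = 5)
  expect_identical(find_base(st2), 5L)

  # xy averaging suppresses voxel noise on a 128^2 slice
  withr::with_seed(7, {
    refl3 <- array(pmax(rnorm(30 * 128 * 128, 10, 10), 0), c(30, 128, 128))
    refl3[12, , ] <- refl3[12, , ] + 100
  })
  st3 <- stack3d(list(fluorescence = array(10, c(30, 128, 128)),
                      reflection = refl3),
                 spacing = c(0.4, 0.4, 0.4), base_index = 12)
  expect_identical(find_base(st3), 12L)

  # flat reflection falls back to the lowest slice with a warning
  st4 <- stack3d(list(fluorescence = arr, reflection = arr),
                 spacing = c(0.4, 0.4, 0.4), base_index = 1)
  expect_warning(b <- find_base(st4), "flat")
  expect_identical(b, 1L)
  expect_error(find_base(st, channel = "nope"), "available")
})

test_that("a clean hemisphere yields one mask with the analytic volume", {
  st <- voxelize(cap_profile(spherical_cap(90, 15), 400),
                 spacing = c(0.5, 0.5, 0.5))
  masks <- segment_stack(st)
  expect_length(masks, 1)
  vol <- masks[[1]]$n_voxels * 0.5^3
  expect_equal(vol, 2 / 3 * pi * 15^3, tolerance = 0.02)
})

test_that("components touching a lateral boundary are excluded", {
  pr <- cap_profile(spherical_cap(90, 6), 200)
  st <- voxelize(pr, spacing = c(0.4, 0.4, 0.4))
  expect_length(segment_stack(st), 1)
  # translate the drop against the x edge of the same grid
  st2 <- voxelize(pr, spacing = c(0.4, 0.4, 0.4), center_xy = c(6.0, 9))
  expect_length(segment_stack(st2), 0)
})

test_that("an all-background stack segments to nothing", {
  arr <- array(5, c(20, 24, 24))
  refl <- arr; refl[3, , ] <- 500
  st <- stack3d(list(fluorescence = arr, reflection = refl),
                spacing = c(0.4, 0.4, 0.4), base_index = 3)
  expect_length(segment_stack(st), 0)
})

test_that("extracted profiles match the analytic cap within one voxel", {
  st <- voxelize(cap_profile(spherical_cap(90, 15), 400),
                 spacing = c(0.5, 0.5, 0.5))
  prof <- extract_profile(segment_stack(st)[[1]])
  n <- nrow(prof)
  body <- prof[prof$z <= 14 & prof$r > 0, ]
  expect_lt(max(abs(body$r - sqrt(pmax(15^2 - body$z^2, 0)))), 0.5)
  expect_equal(prof$r[n], 0)
  expect_lt(abs(prof$z[n] - 15), 0.5)
  expect_false(is.unsorted(prof$z))
})

test_that("interior holes do not change the extracted profile", {
  st <- voxelize(cap_profile(spherical_cap(90, 10), 300),
                 spacing = c(0.5, 0.5, 0.5))
  masks <- segment_stack(st)
  solid <- extract_profile(masks[[1]])
  hollow <- masks[[1]]
  d <- dim(hollow$voxels)
  cy <- round(d[2] / 2); cx <- round(d[3] / 2)
  # hollow out a core in the lower slices, well inside every boundary
  hollow$voxels[3:8, (cy - 5):(cy + 5), (cx - 5):(cx + 5)] <- FALSE
  carved <- extract_profile(hollow)
  expect_equal(carved$r, solid$r, tolerance = 1e-12)
  expect_equal(carved$z, solid$z, tolerance = 1e-12)
})

test_that("slice radii are augmented by the centre-to-axis distance", {
  # hand-built mask: cylinder whose top slice is shifted laterally by
  # 0.6 um, exercising the augmentation directly
  dims <- c(3, 41, 41)
  vox <- array(FALSE, dims)
  disk <- function(cy, cx, rad) {
    m <- array(FALSE, dims[2:3])
    for (y in seq_len(dims[2])) for (x in seq_len(dims[3]))
      if ((y - cy)^2 + (x - cx)^2 <= rad^2) m[y, x] <- TRUE
    m
  }
  vox[1, , ] <- disk(21, 21, 12)
  vox[2, , ] <- disk(21, 21, 12)
  vox[3, , ] <- disk(21, 24, 12)   # 3 voxels = 0.6 um off axis
  mask <- structure(list(voxels = vox,
                         bbox = list(z = c(1L, 3L), y = c(1L, 41L),
                                     x = c(1L, 41L)),
                         dims_cropped = dims,
                         spacing = c(0.2, 0.2, 0.2),
                         n_voxels = sum(vox), id = 1L),
                    class = "condensate_mask")
  prof <- extract_profile(mask)
  # disks are identical, so the unaugmented radii agree; slices 1-2 sit
  # 0.2 um from the centroid axis and slice 3 sits 0.4 um from it
  expect_equal(prof$r[3] - prof$r[1], 0.2, tolerance = 1e-6)
  expect_gt(prof$r[3], prof$r[1])
})

test_that("voxelize -> segment -> extract recovers cap profiles end to end", {
  for (theta in c(70, 90, 120)) {
    cap <- spherical_cap(theta, 12)
    st <- voxelize(cap_profile(cap, 400), spacing = c(0.4, 0.4, 0.4))
    prof <- extract_profile(segment_stack(st)[[1]])
    th <- theta * pi / 180
    r_true <- function(z) {
      d2 <- cap$R_sphere^2 - (z - cap$z_center)^2
      sqrt(pmax(d2, 0))
    }
    body <- prof[prof$r > 0 & prof$z <= cap$height - 0.4, ]
    expect_lt(max(abs(body$r - r_true(body$z))), 0.4)
  }
})
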