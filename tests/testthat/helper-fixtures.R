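# shared fixtures and independent oracles used across the test files

# synthetic Gaussian bead stack for PSF-proxy tests
make_bead_stack <- function(centers, spacing = c(0.1, 0.1, 0.2),
                            dims = c(60, 48, 48), sigma = c(0.15, 0.55),
                            amplitude = 500, background = 10) {
  arr <- array(background, dims)
  zc <- (seq_len(dims[1]) - 0.5) * spacing[3]
  yc <- (seq_len(dims[2]) - 0.5) * spacing[2]
  xc <- (seq_len(dims[3]) - 0.5) * spacing[1]
  g <- function(v, c0, s) exp(-(v - c0)^2 / (2 * s^2))
  for (ctr in centers) {
    for (i in seq_len(dims[1])) {
      arr[i, , ] <- arr[i, , ] + amplitude * g(zc[i], ctr[1], sigma[2]) *
        outer(g(yc, ctr[2], sigma[1]), g(xc, ctr[3], sigma[1]))
    }
  }
  stack3d(list(fluorescence = arr), spacing = spacing, base_index = 1)
}

# discrete second moment of a psf grid along one axis (1 = z, 3 = x)
psf_sigma_along <- function(psf, axis) {
  d <- dim(psf$grid)
  step <- psf$spacing[c(3, 2, 1)][axis]
  coord <- (seq_len(d[axis]) - (d[axis] + 1) / 2) * step
  m <- apply(psf$grid, axis, sum)
  sqrt(sum(m * coord^2) / sum(m))
}

# brute-force triple-sum linear convolution (oracle for the FFT engine)
direct_convolve3 <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern); h <- (dk - 1L) / 2L
  out <- array(0, dv)
  for (i in seq_len(dv[1])) for (j in seq_len(dv[2]))
    for (k in seq_len(dv[3])) {
      acc <- 0
      for (a in -h[1]:h[1]) for (b in -h[2]:h[2]) for (cc in -h[3]:h[3]) {
        ii <- i - a; jj <- j - b; kk <- k - cc
        if (ii >= 1 && ii <= dv[1] && jj >= 1 && jj <= dv[2] &&
            kk >= 1 && kk <= dv[3])
          acc <- acc + vol[ii, jj, kk] *
            kern[a + h[1] + 1, b + h[2] + 1, cc + h[3] + 1]
      }
      out[i, j, k] <- acc
    }
  out
}

# common-tangent construction on a dense phi grid via the lower convex
# hull of the free energy (oracle for the coexistence solver)
grid_common_tangent <- function(n, chi, n_grid = 1e5) {
  phi <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  f <- phi / n * log(phi) + (1 - phi) * log(1 - phi) + chi * phi * (1 - phi)
  # monotone-chain lower hull over (phi, f)
  hull <- integer(0)
  for (i in seq_along(phi)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cross <- (phi[b] - phi[a]) * (f[i] - f[a]) -
               (f[b] - f[a]) * (phi[i] - phi[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  gaps <- diff(phi[hull])
  k <- which.max(gaps)
  c(phi[hull[k]], phi[hull[k + 1]])
}

# noiseless sessile profile with additive radial noise, apex preserved
noisy_profile <- function(profile, sigma, seed) {
  n <- nrow(profile)
  withr::with_seed(seed, {
    r <- c(pmax(profile$r[-n] + rnorm(n - 1, 0, sigma), 0), 0)
  })
  drop_profile(r, profile$z)
}
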