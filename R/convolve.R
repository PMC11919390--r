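# FFT-based linear (zero-padded) convolution of 3D arrays.  Used both for
# Gaussian pre-smoothing during segmentation and for PSF blurring of
# simulated stacks; tested against a direct triple-sum oracle.

fft_convolve3 <- function(vol, kern) {
  dv <- dim(vol); dk <- dim(kern)
  stopifnot(length(dv) == 3, length(dk) == 3)
  if (any(dk %% 2 == 0)) stop("kernel dimensions must be odd")
  pd <- mapply(function(a, b) stats::nextn(a + b - 1L, c(2, 3, 5)), dv, dk)
  pv <- array(0, pd); pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk <- array(0, pd); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
  full <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / prod(pd)
  off <- (dk - 1L) / 2L
  full[off[1] + seq_len(dv[1]), off[2] + seq_len(dv[2]),
       off[3] + seq_len(dv[3])]
}

# separable Gaussian kernel on a voxel grid; sigma and half-width in voxels
gaussian_kernel3 <- function(sigma, half_width = ceiling(4 * sigma)) {
  sigma <- rep_len(sigma, 3)
  half_width <- rep_len(pmax(half_width, 1), 3)
  k1 <- lapply(1:3, function(i) {
    x <- seq(-half_width[i], half_width[i])
    k <- exp(-x^2 / (2 * sigma[i]^2))
    k / sum(k)
  })
  outer(outer(k1[[1]], k1[[2]]), k1[[3]])
}
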