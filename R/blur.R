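# Anisotropic Gaussian blur used both as the generator's PSF stand-in and as
# the denoising step of preprocessing.  Separable discrete Gaussian kernels,
# clamp-to-edge padding; sigma is in voxels, per axis.

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# arr: 3D array dim c(nz, ny, nx); sigmas in voxel units.
blur3d <- function(arr, sigma_z, sigma_xy) {
  if (sigma_z <= 0 && sigma_xy <= 0) return(arr)
  kz <- gauss_kernel_1d(sigma_z)
  kxy <- gauss_kernel_1d(sigma_xy)
  sep_conv_3d(arr, kz, kxy, kxy)
}
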