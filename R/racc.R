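#' Parameters for regression-adjusted colocalisation colour mapping
#'
#' @param theta_deg Penalisation angle in degrees, in `(0, 90]`.  Smaller
#'   angles attenuate intensity pairs away from the regression line more
#'   aggressively; larger angles are more permissive.
#' @param foreground_mask Optional [binary_volume()] restricting the voxels
#'   entering the regression and the map; `NULL` evaluates every voxel.
#' @return An object of class `racc_params`.
#' @export
racc_params <- function(theta_deg = 45, foreground_mask = NULL) {
  stopifnot(theta_deg > 0, theta_deg <= 90)
  if (!is.null(foreground_mask))
    stopifnot(inherits(foreground_mask, "binary_volume"))
  structure(list(theta_deg = theta_deg, foreground_mask = foreground_mask),
            class = "racc_params")
}

#' Regression-adjusted colocalisation map of a channel pair
#'
#' Normalises both channels to `[0, 1]` over the in-mask voxels, fits an
#' orthogonal (total-least-squares) regression line to the paired
#' intensities, and maps every voxel to
#' `w * (a + b) / 2` where `w = max(0, 1 - d / D)`, `d` is the voxel's
#' perpendicular distance from the line in the normalised intensity plane
#' and `D = (sqrt(2) / 2) * theta / 90` is the penalisation cutoff.  Voxels
#' on the line with both intensities high map to bright values; voxels far
#' from the line, or on the line but dim in both channels, map to dark
#' values.  Orthogonal regression makes the map invariant to swapping the
#' two channels, and min–max normalisation makes it invariant to affine
#' rescaling of either channel.
#'
#' @param ch_a,ch_b [voxel_grid()]s of the two channels (same shape).
#' @param params A [racc_params()].
#' @return An object of class `racc_map`: `values` (3D array in `[0, 1]`,
#'   zero outside the mask), `slope` and `intercept` of the fitted line in
#'   normalised intensity space, and `theta_deg`.
#' @examples
#' a <- array(runif(4 * 8 * 8), c(4, 8, 8))
#' m <- racc_map(voxel_grid(a, 0.35, 0.1), voxel_grid(a, 0.35, 0.1))
#' racc_summary(m)  # perfectly correlated pair
#' @export
racc_map <- function(ch_a, ch_b, params = racc_params()) {
  stopifnot(inherits(ch_a, "voxel_grid"), inherits(ch_b, "voxel_grid"))
  if (!identical(dim(ch_a$data), dim(ch_b$data)))
    stop("channels have different shapes")
  mask <- if (is.null(params$foreground_mask)) array(TRUE, dim(ch_a$data)) else
    params$foreground_mask$mask
  if (!identical(dim(mask), dim(ch_a$data)))
    stop("foreground mask has a different shape")
  if (sum(mask) < 2) stop("need at least 2 in-mask voxels")

  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) <= 0) stop("regression undefined: constant channel")
    (v - r[1]) / diff(r)
  }
  a <- norm01(ch_a$data[mask])
  b <- norm01(ch_b$data[mask])

  # orthogonal regression: first principal axis of the centred pairs
  mu <- c(mean(a), mean(b))
  cv <- stats::cov(cbind(a, b))
  eg <- eigen(cv, symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  if (sum(abs(v1)) < 1e-15) stop("regression undefined: degenerate scatter")
  nrm <- c(-v1[2], v1[1])                      # unit normal to the line
  d <- abs((a - mu[1]) * nrm[1] + (b - mu[2]) * nrm[2])
  D <- (sqrt(2) / 2) * params$theta_deg / 90
  w <- pmax(0, 1 - d / D)
  vals <- w * (a + b) / 2

  out <- array(0, dim(ch_a$data))
  out[mask] <- vals
  slope <- if (abs(v1[1]) < 1e-12) Inf else v1[2] / v1[1]
  intercept <- if (is.finite(slope)) mu[2] - slope * mu[1] else NA_real_
  structure(list(values = out, mask = mask, slope = slope,
                 intercept = intercept, theta_deg = params$theta_deg),
            class = "racc_map")
}

#' Mean in-mask RACC value
#'
#' Collapses a [racc_map()] to one comparable scalar per cell: the
#' arithmetic mean of the map over the evaluated voxels.
#'
#' @param map A `racc_map`.
#' @return A single number in `[0, 1]`.
#' @export
racc_summary <- function(map) {
  stopifnot(inherits(map, "racc_map"))
  if (sum(map$mask) == 0) stop("empty mask")
  mean(map$values[map$mask])
}
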