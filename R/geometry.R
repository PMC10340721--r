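#' Acquisition geometry of a confocal z-stack (time) series
#'
#' Describes the physical sampling of an acquisition: number of optical
#' sections, axial step, lateral pixel size, number of time frames and the
#' frame interval.  The two bundled presets mirror a typical live-cell
#' protocol: time-lapse mitochondrial imaging with 10 slices at a 0.25 um
#' z-step over 9 frames no more than 30 s apart, and static three-channel
#' vesicle imaging with 12 or more slices at a 0.35 um z-step.
#'
#' @param n_slices Number of z-planes (>= 1).
#' @param voxel_z_um Axial step in micrometres (> 0).
#' @param voxel_xy_um Lateral pixel size in micrometres (> 0).  Defaults to
#'   0.1 um, typical Nyquist-range sampling for a 100x/1.4 NA objective.
#' @param n_frames Number of time points (>= 1).
#' @param frame_interval_s Seconds between consecutive frames.
#' @param n_xy_px Lateral image size in pixels (images are square).
#' @return An object of class `acq_geometry`.
#' @examples
#' g <- acq_geometry(n_slices = 10, voxel_z_um = 0.25, n_frames = 9)
#' g$voxel_volume_um3
#' @export
acq_geometry <- function(n_slices, voxel_z_um, voxel_xy_um = 0.1,
                         n_frames = 1, frame_interval_s = 30,
                         n_xy_px = 128) {
  stopifnot(n_slices >= 1, n_frames >= 1, voxel_z_um > 0, voxel_xy_um > 0,
            frame_interval_s > 0, n_xy_px >= 8)
  structure(list(
    n_slices = as.integer(n_slices),
    voxel_z_um = voxel_z_um,
    voxel_xy_um = voxel_xy_um,
    n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s,
    n_xy_px = as.integer(n_xy_px),
    voxel_volume_um3 = voxel_z_um * voxel_xy_um^2
  ), class = "acq_geometry")
}

#' @rdname acq_geometry
#' @export
mito_geometry <- function(n_slices = 10, voxel_z_um = 0.25, voxel_xy_um = 0.1,
                          n_frames = 9, frame_interval_s = 30,
                          n_xy_px = 128) {
  acq_geometry(n_slices, voxel_z_um, voxel_xy_um, n_frames,
               frame_interval_s, n_xy_px)
}

#' @rdname acq_geometry
#' @export
vesicle_geometry <- function(n_slices = 12, voxel_z_um = 0.35,
                             voxel_xy_um = 0.1, n_xy_px = 160) {
  acq_geometry(n_slices, voxel_z_um, voxel_xy_um, n_frames = 1,
               n_xy_px = n_xy_px)
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf(
    "<acq_geometry> %d slices x %d px^2, voxel %.3g x %.3g x %.3g um, %d frame(s)\n",
    x$n_slices, x$n_xy_px, x$voxel_xy_um, x$voxel_xy_um, x$voxel_z_um,
    x$n_frames))
  invisible(x)
}

#' Single-channel 3D intensity volume
#'
#' A thin container pairing a 3D intensity array (indexed `[z, y, x]`,
#' 1-based) with its physical voxel dimensions.
#'
#' @param intensities Non-negative numeric 3D array with dim `c(nz, ny, nx)`.
#' @param voxel_z_um,voxel_xy_um Physical voxel sizes in micrometres.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, voxel_z_um, voxel_xy_um) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3,
            all(dim(intensities) >= 1), voxel_z_um > 0, voxel_xy_um > 0)
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(data = intensities, voxel_z_um = voxel_z_um,
                 voxel_xy_um = voxel_xy_um),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), voxel %.3g/%.3g um, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], x$voxel_xy_um, x$voxel_z_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary (thresholded) 3D volume
#'
#' @param mask Logical 3D array, same indexing convention as [voxel_grid()].
#' @param voxel_z_um,voxel_xy_um Physical voxel sizes in micrometres.
#' @param provenance List recording how the mask was obtained (threshold
#'   method, realised threshold value, configuration).  Always populated.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_z_um, voxel_xy_um,
                          provenance = list(method = "direct")) {
  stopifnot(is.array(mask), length(dim(mask)) == 3, is.logical(mask),
            voxel_z_um > 0, voxel_xy_um > 0, is.list(provenance),
            length(provenance) > 0)
  structure(list(mask = mask, voxel_z_um = voxel_z_um,
                 voxel_xy_um = voxel_xy_um, provenance = provenance),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d, %d foreground voxels (%s)\n",
              d[1], d[2], d[3], sum(x$mask),
              x$provenance$method %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

voxel_volume_um3 <- function(x) x$voxel_z_um * x$voxel_xy_um^2

# Internal: seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Internal: derive a per-unit child seed from a master seed, kept < 2^31.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483629)
}
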