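#' Scenario for a synthetic three-channel vesicle stack
#'
#' Describes a static scene of vesicular puncta of seven colocalisation
#' classes, rendered into three channels playing the roles of GFP-LC3
#' (autophagosome membrane), LysoTracker (lysosomes) and MitoTracker
#' (mitochondria).  Class membership fixes the channels a punctum appears
#' in: AP -> LC3 only, LYS -> LYSO only, AL -> LC3+LYSO, MITO -> MITO only,
#' AM -> LC3+MITO, ML -> LYSO+MITO, AML -> all three.  Because the class is
#' scripted, it is exact ground truth for the downstream classifier.
#'
#' @param counts Named integer vector of per-class punctum counts; names
#'   from `c("AP","LYS","AL","MITO","AM","ML","AML")`, missing classes are 0.
#' @param radius_range_um Length-2 numeric: vesicle radii are drawn
#'   uniformly from this range (one radius per punctum, shared by all of a
#'   punctum's channel spheres so partial overlap is well defined).
#' @param mito_radius_range_um Radius range for MITO-only structures.
#' @param overlap_fraction Fraction of a punctum's volume shared between its
#'   channel spheres in colocalised classes, in `(0, 1]`.  `1` renders
#'   identical spheres.  Non-colocalised puncta share no voxels at all.
#' @param min_gap_um Minimum clearance kept between distinct puncta.
#' @param intensity_amplitude,gaussian_sd,poisson_scaling,psf_sigma_xy,psf_sigma_z
#'   Rendering and noise parameters, as in [mito_scenario()].
#' @return An object of class `vesicle_scenario`.
#' @seealso [simulate_vesicle_stack()]
#' @export
vesicle_scenario <- function(counts, radius_range_um = c(0.2, 0.35),
                             mito_radius_range_um = c(0.25, 0.4),
                             overlap_fraction = 0.5, min_gap_um = 0.2,
                             intensity_amplitude = 100, gaussian_sd = 2,
                             poisson_scaling = 1, psf_sigma_xy = 0.5,
                             psf_sigma_z = 0.4) {
  full <- stats::setNames(integer(length(COLOC_CLASSES)), COLOC_CLASSES)
  if (length(counts) > 0) {
    stopifnot(!is.null(names(counts)), all(names(counts) %in% COLOC_CLASSES),
              all(counts >= 0))
    full[names(counts)] <- as.integer(counts)
  }
  stopifnot(length(radius_range_um) == 2, all(radius_range_um > 0),
            overlap_fraction > 0, overlap_fraction <= 1, min_gap_um >= 0)
  structure(list(
    counts = full, radius_range_um = radius_range_um,
    mito_radius_range_um = mito_radius_range_um,
    overlap_fraction = overlap_fraction, min_gap_um = min_gap_um,
    intensity_amplitude = intensity_amplitude, gaussian_sd = gaussian_sd,
    poisson_scaling = poisson_scaling, psf_sigma_xy = psf_sigma_xy,
    psf_sigma_z = psf_sigma_z
  ), class = "vesicle_scenario")
}

# Centre distance (um) at which two equal spheres of radius r share a given
# volume fraction of one sphere; lens-volume formula inverted numerically.
overlap_offset_um <- function(r, fraction) {
  if (fraction >= 1) return(0)
  frac_at <- function(d) (pi / 12) * (4 * r + d) * (2 * r - d)^2 / ((4 / 3) * pi * r^3)
  stats::uniroot(function(d) frac_at(d) - fraction, c(0, 2 * r),
                 tol = 1e-10)$root
}

#' Simulate a three-channel vesicle z-stack with known colocalisation classes
#'
#' Places puncta of the requested classes on a jittered grid (guaranteeing
#' zero voxel contact between distinct puncta), renders each punctum as a
#' blurred sphere into every channel of its class, and returns the noisy
#' channels plus exact ground truth.  Within a colocalised punctum the
#' channel spheres share `overlap_fraction` of their volume; the secondary
#' spheres are displaced laterally from the defining channel's sphere.
#'
#' @param geometry An [acq_geometry()] (single time point).
#' @param scenario A [vesicle_scenario()].
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `vesicle_sim` with elements `channels` (named
#'   list LC3/LYSO/MITO of [voxel_grid()]) and `truth` (per-punctum table,
#'   per-channel ground-truth masks and label volumes).
#' @examples
#' g <- vesicle_geometry(n_xy_px = 96)
#' sc <- vesicle_scenario(c(AP = 5, LYS = 3))
#' sim <- simulate_vesicle_stack(g, sc, seed = 1)
#' table(sim$truth$puncta$class)
#' @export
simulate_vesicle_stack <- function(geometry, scenario, seed) {
  stopifnot(inherits(geometry, "acq_geometry"),
            inherits(scenario, "vesicle_scenario"))
  with_seed(seed, {
    dims <- c(geometry$n_slices, geometry$n_xy_px, geometry$n_xy_px)
    n_total <- sum(scenario$counts)
    if (n_total == 0) stop("scenario places no puncta")
    r_max_um <- max(scenario$radius_range_um, scenario$mito_radius_range_um)
    off_max_um <- overlap_offset_um(max(scenario$radius_range_um),
                                    scenario$overlap_fraction)
    # grid pitch: each punctum group is re-centred on its site, so no
    # member sphere centre strays more than (2/3) * offset from the site;
    # neighbouring groups can then never touch
    pitch_um <- 2 * r_max_um + (4 / 3) * off_max_um + scenario$min_gap_um
    pitch_px <- ceiling(pitch_um / geometry$voxel_xy_um) + 1
    n_sites <- floor((geometry$n_xy_px - 2) / pitch_px)
    if (n_sites^2 < n_total)
      stop(sprintf(
        "placement error: %d puncta requested but only %d separated sites fit; enlarge the field or reduce counts",
        n_total, n_sites^2))
    site_xy <- expand.grid(
      y = round(seq(pitch_px / 2 + 1, by = pitch_px, length.out = n_sites)),
      x = round(seq(pitch_px / 2 + 1, by = pitch_px, length.out = n_sites)))
    site_xy <- site_xy[sample.int(nrow(site_xy), n_total), , drop = FALSE]

    classes <- rep(names(scenario$counts), times = scenario$counts)
    classes <- classes[sample.int(length(classes))]
    zc <- ceiling(dims[1] / 2)

    ch_masks <- lapply(CHANNEL_ROLES, function(ch) array(FALSE, dims))
    names(ch_masks) <- CHANNEL_ROLES
    rows <- vector("list", n_total)

    for (i in seq_len(n_total)) {
      cls <- classes[i]
      chans <- CLASS_CHANNELS[[cls]]
      rng <- if (cls == "MITO") scenario$mito_radius_range_um else
        scenario$radius_range_um
      r_um <- stats::runif(1, rng[1], rng[2])
      rxy <- r_um / geometry$voxel_xy_um
      rz <- max(r_um / geometry$voxel_z_um, 0.6)
      off <- ellipsoid_offsets(rz, rxy)
      centre <- c(zc + sample(-1:1, 1), site_xy$y[i], site_xy$x[i])
      defining <- CLASS_DEFINING_CHANNEL[[cls]]
      # lateral displacement directions for the secondary channel spheres
      d_px <- overlap_offset_um(r_um, scenario$overlap_fraction) /
        geometry$voxel_xy_um
      secondaries <- setdiff(chans, defining)
      ang0 <- stats::runif(1, 0, 2 * pi)
      centres <- list()
      centres[[defining]] <- centre
      for (j in seq_along(secondaries)) {
        a <- ang0 + (j - 1) * 2 * pi / 3
        centres[[secondaries[j]]] <-
          c(centre[1], centre[2] + d_px * sin(a), centre[3] + d_px * cos(a))
      }
      # re-centre the group on its grid site to bound its spatial extent
      grp <- do.call(rbind, centres)
      shift <- centre - colMeans(grp)
      shift[1] <- 0
      centres <- lapply(centres, function(p) round(p + shift))
      vol_vox <- NA_integer_
      cen_zyx <- NULL
      for (ch in chans) {
        idx <- stamp_indices(centres[[ch]], off, dims)
        ch_masks[[ch]][idx] <- TRUE
        if (ch == defining) {
          vol_vox <- length(idx)
          ai <- arrayInd(idx, dims)
          cen_zyx <- colMeans(ai)
        }
      }
      rows[[i]] <- data.frame(
        punctum_id = i, class = cls, radius_um = r_um,
        z = cen_zyx[1], y = cen_zyx[2], x = cen_zyx[3],
        volume_um3 = vol_vox * geometry$voxel_volume_um3)
    }

    channels <- lapply(ch_masks, function(m) {
      img <- render_volume(m, scenario, geometry)
      voxel_grid(img, geometry$voxel_z_um, geometry$voxel_xy_um)
    })
    truth <- list(
      puncta = do.call(rbind, rows),
      masks = ch_masks,
      labels = lapply(ch_masks, canonical_labels),
      geometry = geometry)
    structure(list(channels = channels, truth = truth),
              class = "vesicle_sim")
  })
}
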