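#' Scenario for a synthetic mitochondrial time-lapse
#'
#' Parameters of the simulated tubular mitochondrial network and of the
#' fission/fusion events scripted onto it.  The rendered channel mimics a
#' potential-sensitive mitochondrial dye (e.g. TMRE): a curvilinear network
#' of tubules of roughly constant radius, imaged through a PSF-like
#' anisotropic Gaussian blur with photon (Poisson) and read (Gaussian) noise.
#'
#' @param n_tubules Number of tubular segments in the first frame.
#' @param tubule_radius_um Tubule radius in micrometres.
#' @param tubule_length_um Approximate tubule centre-line length.
#' @param events `NULL` or a data.frame with columns `frame` (transition
#'   index `t`, meaning the event happens between frames `t` and `t + 1`,
#'   `1 <= t <= n_frames - 1`), `type` (`"fission"` or `"fusion"`), and
#'   optionally `structure` / `structure2` (ground-truth label ids in frame
#'   `t`; `NA` lets the generator pick an eligible structure or pair).
#' @param intensity_amplitude Peak signal level in arbitrary units.
#' @param gaussian_sd Read-noise standard deviation (same units).
#' @param poisson_scaling Gain of the photon-noise term: intensities are
#'   drawn as `rpois(I / g) * g`.  `0` disables photon noise.
#' @param psf_sigma_xy,psf_sigma_z PSF-like blur sigmas in voxels.
#' @param max_bridge_um Longest gap a scripted fusion may bridge.
#' @param on_unrealisable What to do when an auto-picked event cannot be
#'   realised (no eligible structure, no collision-free bridge): `"error"`
#'   (default; scripted schedules are contracts) or `"skip"` (drop the
#'   event — used for rate-drawn scenarios where the realised ground truth,
#'   not the request, is what downstream stages are scored against).
#' @return An object of class `mito_scenario`.
#' @seealso [simulate_mito_timelapse()]
#' @export
mito_scenario <- function(n_tubules = 6, tubule_radius_um = 0.25,
                          tubule_length_um = 3, events = NULL,
                          intensity_amplitude = 100, gaussian_sd = 2,
                          poisson_scaling = 1, psf_sigma_xy = 0.5,
                          psf_sigma_z = 0.4, max_bridge_um = 3,
                          on_unrealisable = c("error", "skip")) {
  on_unrealisable <- match.arg(on_unrealisable)
  stopifnot(n_tubules >= 1, tubule_radius_um > 0, tubule_length_um > 0,
            intensity_amplitude > 0, gaussian_sd >= 0, poisson_scaling >= 0)
  if (!is.null(events)) {
    stopifnot(is.data.frame(events), all(c("frame", "type") %in% names(events)))
    if (!all(events$type %in% c("fission", "fusion")))
      stop("event type must be 'fission' or 'fusion'")
    if (is.null(events$structure)) events$structure <- NA_integer_
    if (is.null(events$structure2)) events$structure2 <- NA_integer_
  }
  structure(list(
    n_tubules = as.integer(n_tubules), tubule_radius_um = tubule_radius_um,
    tubule_length_um = tubule_length_um, events = events,
    intensity_amplitude = intensity_amplitude, gaussian_sd = gaussian_sd,
    poisson_scaling = poisson_scaling, psf_sigma_xy = psf_sigma_xy,
    psf_sigma_z = psf_sigma_z, max_bridge_um = max_bridge_um,
    on_unrealisable = on_unrealisable
  ), class = "mito_scenario")
}

# ---- rasterisation helpers -------------------------------------------------

# Voxel offsets of an axis-aligned ellipsoid with semi-axes (rz, rxy, rxy).
ellipsoid_offsets <- function(rz, rxy) {
  cz <- ceiling(rz); cxy <- ceiling(rxy)
  g <- expand.grid(z = -cz:cz, y = -cxy:cxy, x = -cxy:cxy)
  keep <- (g$z / rz)^2 + (g$y / rxy)^2 + (g$x / rxy)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

# Stamp offsets at integer centres; returns linear indices into dims.
stamp_indices <- function(centres, offsets, dims) {
  if (is.null(dim(centres))) centres <- matrix(centres, nrow = 1)
  pts <- offsets[rep(seq_len(nrow(offsets)), times = nrow(centres)), , drop = FALSE] +
    centres[rep(seq_len(nrow(centres)), each = nrow(offsets)), , drop = FALSE]
  keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
    pts[, 2] >= 1 & pts[, 2] <= dims[2] &
    pts[, 3] >= 1 & pts[, 3] <= dims[3]
  pts <- pts[keep, , drop = FALSE]
  unique(pts[, 1] + dims[1] * (pts[, 2] - 1) + dims[1] * dims[2] * (pts[, 3] - 1))
}

# Random persistent walk for a tubule centre line, reflected at the margins.
tubule_centreline <- function(dims, n_steps, margin_xy, margin_z) {
  p <- c(stats::runif(1, margin_z + 1, dims[1] - margin_z),
         stats::runif(1, margin_xy + 1, dims[2] - margin_xy),
         stats::runif(1, margin_xy + 1, dims[3] - margin_xy))
  ang <- stats::runif(1, 0, 2 * pi)
  d <- c(stats::runif(1, -0.1, 0.1), sin(ang), cos(ang))
  d <- d / sqrt(sum(d^2))
  path <- matrix(0, n_steps, 3)
  for (i in seq_len(n_steps)) {
    path[i, ] <- p
    d <- d + c(0.05, 0.25, 0.25) * stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    p2 <- p + d
    lo <- c(margin_z + 1, margin_xy + 1, margin_xy + 1)
    hi <- c(dims[1] - margin_z, dims[2] - margin_xy, dims[3] - margin_xy)
    refl <- p2 < lo | p2 > hi
    d[refl] <- -d[refl]
    p <- pmin(pmax(p + d, lo), hi)
  }
  path
}

# Render the initial network of non-touching tubules; returns logical mask.
render_tubules <- function(geometry, scenario) {
  dims <- c(geometry$n_slices, geometry$n_xy_px, geometry$n_xy_px)
  rxy <- scenario$tubule_radius_um / geometry$voxel_xy_um
  rz <- max(scenario$tubule_radius_um / geometry$voxel_z_um, 0.6)
  off <- ellipsoid_offsets(rz, rxy)
  n_steps <- max(4L, round(scenario$tubule_length_um / geometry$voxel_xy_um))
  margin_xy <- ceiling(rxy) + 2
  margin_z <- min(ceiling(rz) + 1, floor((dims[1] - 1) / 2))
  mask <- array(FALSE, dims)
  for (k in seq_len(scenario$n_tubules)) {
    placed <- FALSE
    for (try in 1:40) {
      path <- tubule_centreline(dims, n_steps, margin_xy, margin_z)
      idx <- stamp_indices(round(path), off, dims)
      forbidden <- dilate_box(mask, 2)
      if (!any(forbidden[idx])) {
        mask[idx] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place tubule %d without contact; reduce n_tubules or enlarge the field", k))
  }
  mask
}

# ---- scripted events -------------------------------------------------------

# Principal axis of a voxel set in voxel units, accounting for anisotropy.
principal_axis_vox <- function(coords, voxel_z_um, voxel_xy_um) {
  phys <- coords
  phys[, 1] <- phys[, 1] * voxel_z_um / voxel_xy_um
  if (nrow(phys) < 3) return(c(0, 0, 1))
  v <- stats::prcomp(phys, center = TRUE)$rotation[, 1]
  v[1] <- v[1] * voxel_z_um / voxel_xy_um  # back to voxel units
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

# Cut one structure into exactly two by erasing a thin separating slab
# perpendicular to its principal axis.  Returns list(mask, location) or NULL.
apply_fission <- function(mask, lab, target, voxel_z_um, voxel_xy_um) {
  coords <- which(lab == target, arr.ind = TRUE)
  if (nrow(coords) < 12) return(NULL)
  axis <- principal_axis_vox(coords, voxel_z_um, voxel_xy_um)
  thr <- 0.5 * sum(abs(axis)) + 1e-6   # slab wide enough to break 26-adjacency
  proj <- as.vector(coords %*% axis)
  for (q in c(0.5, stats::runif(6, 0.25, 0.75))) {
    cutpos <- stats::quantile(proj, q, names = FALSE)
    cut <- abs(proj - cutpos) <= thr
    if (!any(cut) || all(cut)) next
    keep <- coords[!cut, , drop = FALSE]
    m2 <- mask
    rem <- coords[cut, , drop = FALSE]
    m2[rem] <- FALSE
    # the parent must split into exactly two pieces, none vanishing
    sub <- array(FALSE, dim(mask))
    sub[keep] <- TRUE
    nl <- max(cc_label_3d(sub))
    if (nl == 2L) {
      loc <- round(colMeans(rem))
      # snap to a voxel of the removed slab (inside the parent's footprint)
      d2 <- (rem[, 1] - loc[1])^2 + (rem[, 2] - loc[2])^2 + (rem[, 3] - loc[3])^2
      loc <- rem[which.min(d2), ]
      return(list(mask = m2, location = loc))
    }
  }
  NULL
}

# Join two structures with a bridging cylinder of tubule radius.
apply_fusion <- function(mask, lab, a, b, scenario, geometry) {
  ca <- which(lab == a, arr.ind = TRUE)
  cb <- which(lab == b, arr.ind = TRUE)
  if (nrow(ca) == 0 || nrow(cb) == 0) return(NULL)
  sub_a <- ca[sample.int(nrow(ca), min(nrow(ca), 300)), , drop = FALSE]
  sub_b <- cb[sample.int(nrow(cb), min(nrow(cb), 300)), , drop = FALSE]
  sc <- c(geometry$voxel_z_um, geometry$voxel_xy_um, geometry$voxel_xy_um)
  pa <- sweep(sub_a, 2, sc, `*`); pb <- sweep(sub_b, 2, sc, `*`)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  ij <- arrayInd(which.min(d2), dim(d2))
  dist_um <- sqrt(max(d2[ij], 0))
  if (dist_um > scenario$max_bridge_um)
    stop(sprintf("no feasible bridge between structures %d and %d (gap %.2f um)",
                 a, b, dist_um))
  p1 <- sub_a[ij[1], ]; p2 <- sub_b[ij[2], ]
  n_pt <- max(2L, ceiling(2 * sqrt(sum((p2 - p1)^2))))
  line <- sapply(seq(0, 1, length.out = n_pt), function(t) round(p1 + t * (p2 - p1)))
  rxy <- scenario$tubule_radius_um / geometry$voxel_xy_um
  rz <- max(scenario$tubule_radius_um / geometry$voxel_z_um, 0.6)
  idx <- stamp_indices(t(line), ellipsoid_offsets(rz, rxy), dim(mask))
  m2 <- mask
  m2[idx] <- TRUE
  loc <- round((p1 + p2) / 2)
  loc <- pmin(pmax(loc, 1), dim(mask))
  list(mask = m2, location = loc)
}

# Auto-picked targets are restricted to structures untouched by an earlier
# event of the same transition: interacting events (e.g. a fusion whose
# product is fissioned again before the next frame) can cancel in the
# frame-to-frame overlap graph and would make scripted counts unobservable.
pick_fission_target <- function(lab, eligible) {
  sizes <- label_sizes(lab)
  ok <- intersect(which(sizes >= 25), eligible)
  if (length(ok) == 0) return(NA_integer_)
  if (length(ok) == 1) ok else sample(ok, 1)
}

# Candidate fusion pairs ranked by centroid distance, restricted to
# eligible (untouched) structures.
pick_fusion_pairs <- function(lab, geometry, eligible, max_candidates = 30) {
  k <- max(lab)
  if (k < 2) return(NULL)
  cen <- label_centroids(lab)
  sc <- c(geometry$voxel_z_um, geometry$voxel_xy_um, geometry$voxel_xy_um)
  phys <- sweep(cen, 2, sc, `*`)
  d <- as.matrix(stats::dist(phys))
  cmb <- utils::combn(k, 2)
  dd <- d[cbind(cmb[1, ], cmb[2, ])]
  elig <- cmb[1, ] %in% eligible & cmb[2, ] %in% eligible
  if (!any(elig)) return(NULL)
  cmb <- cmb[, elig, drop = FALSE]
  dd <- dd[elig]
  ord <- order(dd)
  lapply(ord[seq_len(min(length(ord), max_candidates))],
         function(i) c(cmb[1, i], cmb[2, i]))
}

# ---- main entry ------------------------------------------------------------

#' Simulate a mitochondrial time-lapse with scripted fission/fusion events
#'
#' Generates `n_frames` single-channel z-stacks of a tubular network.  The
#' first frame renders `n_tubules` non-touching tubules; each scripted event
#' then modifies the ground-truth mask between consecutive frames: a fission
#' erases a thin separating slab through one structure (yielding exactly two
#' children that both overlap the parent's footprint), a fusion draws a
#' bridging cylinder between two structures.  Each frame is rendered through
#' a PSF-like Gaussian blur followed by Poisson and Gaussian noise.
#'
#' The returned ground truth stores, per frame, the noise-free binary mask,
#' its canonical labelling and structure count, plus the realised event list
#' (one row per event, with the transition index and a voxel location inside
#' the participating structures' footprint).
#'
#' @param geometry An [acq_geometry()]; `n_frames >= 1`.
#' @param scenario A [mito_scenario()].
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `mito_sim` with elements `frames` (list of
#'   [voxel_grid()]) and `truth` (masks, labels, counts, events).
#' @examples
#' g <- mito_geometry(n_frames = 4, n_xy_px = 64)
#' sc <- mito_scenario(n_tubules = 2,
#'                     events = data.frame(frame = 2, type = "fission"))
#' sim <- simulate_mito_timelapse(g, sc, seed = 1)
#' sim$truth$counts
#' @export
simulate_mito_timelapse <- function(geometry, scenario, seed) {
  stopifnot(inherits(geometry, "acq_geometry"), inherits(scenario, "mito_scenario"))
  ev <- scenario$events
  if (!is.null(ev) && nrow(ev) > 0) {
    if (any(ev$frame < 1 | ev$frame > geometry$n_frames - 1))
      stop("event frame index must lie in [1, n_frames - 1]")
  }
  with_seed(seed, {
    masks <- vector("list", geometry$n_frames)
    masks[[1]] <- render_tubules(geometry, scenario)
    events_out <- list()
    if (geometry$n_frames > 1) {
      for (t in seq_len(geometry$n_frames - 1)) {
        m <- masks[[t]]
        todo <- if (is.null(ev)) ev else ev[ev$frame == t, , drop = FALSE]
        if (!is.null(todo) && nrow(todo) > 0) {
          touched <- array(FALSE, dim(m))
          for (i in seq_len(nrow(todo))) {
            lab <- canonical_labels(m)
            k <- max(lab)
            eligible <- setdiff(seq_len(k), unique(lab[touched & lab > 0L]))
            type <- todo$type[i]
            if (type == "fission") {
              target <- todo$structure[i]
              if (!is.na(target) && (target < 1 || target > k))
                stop(sprintf("fission targets non-existent structure %d (frame %d has %d)",
                             target, t, k))
              if (is.na(target)) target <- pick_fission_target(lab, eligible)
              res <- if (is.na(target)) NULL else
                apply_fission(m, lab, target, geometry$voxel_z_um, geometry$voxel_xy_um)
              if (is.null(res) && is.na(todo$structure[i])) {
                # auto-pick: try other untouched structures before giving up
                for (alt in intersect(order(-label_sizes(lab)), eligible)) {
                  target <- alt
                  res <- apply_fission(m, lab, alt, geometry$voxel_z_um, geometry$voxel_xy_um)
                  if (!is.null(res)) break
                }
              }
              if (is.null(res)) {
                if (scenario$on_unrealisable == "skip" && is.na(todo$structure[i]))
                  next
                stop(sprintf("could not realise scripted fission at transition %d", t))
              }
              touched[lab == target] <- TRUE
            } else {
              a <- todo$structure[i]; b <- todo$structure2[i]
              if (!is.na(a) && !is.na(b)) {
                if (a < 1 || a > k || b < 1 || b > k || a == b)
                  stop(sprintf("fusion targets invalid structure pair (%s, %s) at frame %d",
                               a, b, t))
                pair <- c(a, b)
                res <- apply_fusion(m, lab, a, b, scenario, geometry)
                # the bridge must reduce the count by exactly one
                if (!is.null(res) && max(cc_label_3d(res$mask)) != k - 1L)
                  stop(sprintf("bridge between structures %d and %d touches a third structure",
                               a, b))
              } else {
                pairs <- pick_fusion_pairs(lab, geometry, eligible)
                if (is.null(pairs)) {
                  if (scenario$on_unrealisable == "skip") next
                  stop(sprintf("could not realise scripted fusion at transition %d: no eligible structure pair", t))
                }
                res <- NULL
                for (pair in pairs) {
                  cand <- tryCatch(
                    apply_fusion(m, lab, pair[1], pair[2], scenario, geometry),
                    error = function(e) NULL)
                  if (!is.null(cand) &&
                      max(cc_label_3d(cand$mask)) == k - 1L) {
                    res <- cand
                    break
                  }
                }
              }
              if (is.null(res)) {
                if (scenario$on_unrealisable == "skip" && is.na(todo$structure[i]))
                  next
                stop(sprintf("could not realise scripted fusion at transition %d", t))
              }
              touched[lab == pair[1] | lab == pair[2]] <- TRUE
              touched[res$mask & !m] <- TRUE
            }
            m <- res$mask
            events_out[[length(events_out) + 1]] <- data.frame(
              frame_from = t, frame_to = t + 1L, type = type,
              z = res$location[1], y = res$location[2], x = res$location[3])
          }
        }
        masks[[t + 1]] <- m
      }
    }
    labels <- lapply(masks, canonical_labels)
    counts <- vapply(labels, max, integer(1))
    frames <- lapply(masks, function(m) {
      img <- render_volume(m, scenario, geometry)
      voxel_grid(img, geometry$voxel_z_um, geometry$voxel_xy_um)
    })
    events_df <- if (length(events_out)) do.call(rbind, events_out) else
      data.frame(frame_from = integer(0), frame_to = integer(0),
                 type = character(0), z = integer(0), y = integer(0),
                 x = integer(0))
    structure(list(
      frames = frames,
      truth = list(masks = masks, labels = labels, counts = counts,
                   events = events_df, geometry = geometry)
    ), class = "mito_sim")
  })
}

# Render a binary mask to a noisy intensity volume.
render_volume <- function(mask, scenario, geometry) {
  img <- blur3d(mask * scenario$intensity_amplitude,
                scenario$psf_sigma_z, scenario$psf_sigma_xy)
  if (scenario$poisson_scaling > 0) {
    g <- scenario$poisson_scaling
    img <- array(stats::rpois(length(img), pmax(img, 0) / g) * g, dim(img))
  }
  if (scenario$gaussian_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, scenario$gaussian_sd), dim(img))
  pmax(img, 0)
}
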