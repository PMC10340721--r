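#' Label mitochondrial structures and compute morphometrics
#'
#' 26-connected labelling of a binary volume with canonical label order
#' (size descending, then first-voxel scan order), plus structure count,
#' per-structure volumes in cubic micrometres and centroids.  An empty mask
#' yields count 0 and a flagged zero mean volume.
#'
#' @param bv A [binary_volume()].
#' @return A list with `labels` (integer array, 0 = background) and `stats`,
#'   a list with `structure_count`, `mean_volume_um3`, `total_volume_um3`,
#'   `volumes_um3`, `centroids` and `empty` (flag set when no structures).
#' @examples
#' m <- array(FALSE, c(4, 10, 10)); m[2:3, 2:4, 2:4] <- TRUE; m[2:3, 7:9, 7:9] <- TRUE
#' s <- label_structures(binary_volume(m, 0.25, 0.1))
#' s$stats$structure_count
#' @export
label_structures <- function(bv) {
  stopifnot(inherits(bv, "binary_volume"))
  lab <- canonical_labels(bv$mask)
  k <- max(lab)
  vv <- voxel_volume_um3(bv)
  if (k == 0L) {
    stats <- list(structure_count = 0L, mean_volume_um3 = 0,
                  total_volume_um3 = 0, volumes_um3 = numeric(0),
                  centroids = label_centroids(lab), empty = TRUE)
  } else {
    sizes <- label_sizes(lab)
    vols <- sizes * vv
    stats <- list(structure_count = k, mean_volume_um3 = mean(vols),
                  total_volume_um3 = sum(vols), volumes_um3 = vols,
                  centroids = label_centroids(lab), empty = FALSE)
  }
  list(labels = lab, stats = stats)
}

# Overlap edge list between two label arrays: one row per (label_t,
# label_t1) pair sharing >= min_overlap voxels.
overlap_edges <- function(lab_t, lab_t1, min_overlap) {
  both <- lab_t > 0L & lab_t1 > 0L
  if (!any(both)) {
    return(data.frame(from = integer(0), to = integer(0), voxels = integer(0)))
  }
  a <- lab_t[both]; b <- lab_t1[both]
  k2 <- max(b)
  key <- (a - 1) * k2 + b
  cnt <- table(key)
  keyv <- as.numeric(names(cnt))
  edges <- data.frame(from = as.integer((keyv - 1) %/% k2 + 1),
                      to = as.integer((keyv - 1) %% k2 + 1),
                      voxels = as.integer(cnt))
  edges[edges$voxels >= min_overlap, , drop = FALSE]
}

# Centroid of the overlap region between one label pair.
overlap_centroid <- function(lab_t, lab_t1, from, to) {
  idx <- which(lab_t == from & lab_t1 == to, arr.ind = TRUE)
  colMeans(idx)
}

# Snap a continuous (z, y, x) point to the nearest voxel of a mask.
snap_to_mask <- function(p, mask) {
  idx <- which(mask, arr.ind = TRUE)
  d2 <- (idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2 + (idx[, 3] - p[3])^2
  idx[which.min(d2), ]
}

#' Detect and localise fission and fusion events between consecutive frames
#'
#' Builds the bipartite overlap graph between the labelled structures of two
#' consecutive binarized frames (an edge whenever two structures share at
#' least `min_overlap_voxels` voxels).  A frame-`t` structure overlapping
#' `n >= 2` frame-`t+1` structures emits `n - 1` fission events; a
#' frame-`t+1` structure overlapped by `m >= 2` frame-`t` structures emits
#' `m - 1` fusion events.  Each event is localised at the midpoint of the
#' centroids of the two involved overlap regions (the largest-overlap
#' counterpart is the principal), snapped to the nearest voxel of the union
#' footprint of the participating structures.  Structures without any
#' counterpart are reported separately as appearances/disappearances, never
#' as events.
#'
#' @param bv_t,bv_t1 [binary_volume()]s of frames `t` and `t + 1` (same
#'   shape).
#' @param min_overlap_voxels Minimum shared voxels for an overlap edge.
#' @return A list with `events` (data.frame: `type`, `z`, `y`, `x`,
#'   `parent_labels`, `child_labels`), `appeared`, `disappeared` (label
#'   vectors) and the two label volumes.
#' @examples
#' m1 <- array(FALSE, c(1, 3, 12)); m1[1, 2, 2:11] <- TRUE
#' m2 <- m1; m2[1, 2, 6] <- FALSE
#' ev <- detect_events(binary_volume(m1, 0.25, 0.1), binary_volume(m2, 0.25, 0.1))
#' ev$events$type
#' @export
detect_events <- function(bv_t, bv_t1, min_overlap_voxels = 1) {
  stopifnot(inherits(bv_t, "binary_volume"), inherits(bv_t1, "binary_volume"),
            min_overlap_voxels >= 1)
  if (!identical(dim(bv_t$mask), dim(bv_t1$mask)))
    stop("frame masks have different shapes")
  lab_t <- canonical_labels(bv_t$mask)
  lab_t1 <- canonical_labels(bv_t1$mask)
  edges <- overlap_edges(lab_t, lab_t1, min_overlap_voxels)

  events <- list()
  emit <- function(type, loc, parents, children) {
    events[[length(events) + 1]] <<- data.frame(
      type = type, z = loc[1], y = loc[2], x = loc[3],
      parent_labels = paste(parents, collapse = ";"),
      child_labels = paste(children, collapse = ";"))
  }

  # fission: one frame-t parent split across several frame-t1 children
  for (p in unique(edges$from)) {
    e <- edges[edges$from == p, , drop = FALSE]
    if (nrow(e) < 2) next
    e <- e[order(-e$voxels, e$to), , drop = FALSE]
    foot <- lab_t == p
    for (ch in e$to) foot <- foot | lab_t1 == ch
    c1 <- overlap_centroid(lab_t, lab_t1, p, e$to[1])
    for (j in 2:nrow(e)) {
      cj <- overlap_centroid(lab_t, lab_t1, p, e$to[j])
      loc <- snap_to_mask((c1 + cj) / 2, foot)
      emit("fission", loc, p, e$to)
    }
  }
  # fusion: several frame-t parents merged into one frame-t1 child
  for (ch in unique(edges$to)) {
    e <- edges[edges$to == ch, , drop = FALSE]
    if (nrow(e) < 2) next
    e <- e[order(-e$voxels, e$from), , drop = FALSE]
    foot <- lab_t1 == ch
    for (p in e$from) foot <- foot | lab_t == p
    c1 <- overlap_centroid(lab_t, lab_t1, e$from[1], ch)
    for (j in 2:nrow(e)) {
      cj <- overlap_centroid(lab_t, lab_t1, e$from[j], ch)
      loc <- snap_to_mask((c1 + cj) / 2, foot)
      emit("fusion", loc, e$from, ch)
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), z = integer(0), y = integer(0),
               x = integer(0), parent_labels = character(0),
               child_labels = character(0))
  list(events = ev,
       appeared = setdiff(seq_len(max(lab_t1)), edges$to),
       disappeared = setdiff(seq_len(max(lab_t)), edges$from),
       labels_t = lab_t, labels_t1 = lab_t1)
}

#' Summarise a binarized time series per cell
#'
#' Runs [detect_events()] on every consecutive frame pair and
#' [label_structures()] on every frame, then averages over the series to
#' per-cell values — the hierarchy used for group statistics, where frames
#' are averaged within a cell before cells are compared.
#'
#' @param frames List of [binary_volume()]s (>= 2 for event summaries).
#' @param min_overlap_voxels Passed to [detect_events()].
#' @return A list with `per_pair` (data.frame: transition, fission and
#'   fusion counts), `per_frame` (data.frame of per-frame morphometrics),
#'   `events` (all localised events with `frame_from` column) and
#'   `cell_summary` (mean fission/fusion per transition, mean structure
#'   count and mean structure volume over frames).
#' @export
summarise_series <- function(frames, min_overlap_voxels = 1) {
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, inherits, logical(1), "binary_volume")))
  if (length(frames) < 2)
    stop("at least 2 frames are required for an event summary")
  per_frame <- do.call(rbind, lapply(seq_along(frames), function(i) {
    s <- label_structures(frames[[i]])$stats
    data.frame(frame = i, structure_count = s$structure_count,
               mean_volume_um3 = s$mean_volume_um3,
               total_volume_um3 = s$total_volume_um3)
  }))
  pair_rows <- vector("list", length(frames) - 1)
  all_events <- vector("list", length(frames) - 1)
  for (t in seq_len(length(frames) - 1)) {
    det <- detect_events(frames[[t]], frames[[t + 1]], min_overlap_voxels)
    pair_rows[[t]] <- data.frame(
      transition = t,
      fission = sum(det$events$type == "fission"),
      fusion = sum(det$events$type == "fusion"))
    if (nrow(det$events))
      all_events[[t]] <- cbind(frame_from = t, det$events)
  }
  per_pair <- do.call(rbind, pair_rows)
  events <- if (any(!vapply(all_events, is.null, logical(1))))
    do.call(rbind, all_events[!vapply(all_events, is.null, logical(1))]) else
    data.frame(frame_from = integer(0), type = character(0), z = integer(0),
               y = integer(0), x = integer(0), parent_labels = character(0),
               child_labels = character(0))
  list(per_pair = per_pair, per_frame = per_frame, events = events,
       cell_summary = data.frame(
         mean_fission = mean(per_pair$fission),
         mean_fusion = mean(per_pair$fusion),
         mean_structure_count = mean(per_frame$structure_count),
         mean_structure_volume_um3 = mean(per_frame$mean_volume_um3)))
}
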