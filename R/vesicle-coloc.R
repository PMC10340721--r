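#' Colocalisation rule
#'
#' Two binarized puncta are colocalised when they share at least
#' `min_shared_voxels` voxels.  With `classes_exclusive = TRUE` (default)
#' every punctum is assigned to exactly one of the seven classes, so the
#' reported single-channel pools (AP, LYS, MITO) exclude colocalised
#' vesicles; the inclusive mode counts each pairwise class irrespective of
#' the third channel.
#'
#' @param min_shared_voxels Integer >= 1.
#' @param classes_exclusive Logical.
#' @return An object of class `coloc_rule`.
#' @export
coloc_rule <- function(min_shared_voxels = 1, classes_exclusive = TRUE) {
  stopifnot(min_shared_voxels >= 1, is.logical(classes_exclusive))
  structure(list(min_shared_voxels = as.integer(min_shared_voxels),
                 classes_exclusive = classes_exclusive),
            class = "coloc_rule")
}

#' Detect puncta in one channel
#'
#' Binarize, size-filter and label one channel of a vesicle stack.  A
#' constant (e.g. all-background) channel yields an empty set rather than a
#' thresholding error.
#'
#' @param grid A [voxel_grid()] of the channel.
#' @param role Channel role: `"LC3"`, `"LYSO"` or `"MITO"`.
#' @param config A [preprocess_config()]; `config$min_voxels` is the size
#'   filter applied after thresholding.
#' @param max_foreground_fraction,min_peak_snr Guards against channels that
#'   contain no real signal: Otsu assumes a bimodal histogram, and on a
#'   noise-only channel it splits the noise itself, flooding the field.  A
#'   channel is treated as background-only (empty set) when its bright tail
#'   (99.99th percentile) sits less than `min_peak_snr` robust noise
#'   deviations (MAD) above the median, or when the thresholded foreground
#'   exceeds `max_foreground_fraction` of the volume.  Vesicular channels
#'   with real puncta occupy a few percent of the volume and are orders of
#'   magnitude above these guards.
#' @return An object of class `puncta_set`: role, label volume, per-punctum
#'   volumes (um^3) and centroids, the filtered [binary_volume()] and count.
#' @export
detect_puncta <- function(grid, role, config = preprocess_config(),
                          max_foreground_fraction = 0.25,
                          min_peak_snr = 8) {
  stopifnot(inherits(grid, "voxel_grid"))
  role <- match.arg(role, CHANNEL_ROLES)
  v <- as.vector(grid$data)
  # robust noise scale from the upper quartile: detector offsets clip a
  # large share of the background at zero, which deflates the MAD
  med <- stats::median(v)
  noise_scale <- (stats::quantile(v, 0.75, names = FALSE) - med) / 0.6745
  no_signal <- diff(range(v)) <= 0 ||
    (noise_scale > 0 &&
       stats::quantile(v, 0.9999, names = FALSE) <
         med + min_peak_snr * noise_scale)
  empty_set <- function(reason) {
    binary_volume(array(FALSE, dim(grid$data)), grid$voxel_z_um,
                  grid$voxel_xy_um, provenance = list(method = reason))
  }
  if (no_signal && config$threshold == "otsu") {
    bv <- empty_set("background_channel")
  } else {
    bv <- binarize(grid, config)
    if (mean(bv$mask) > max_foreground_fraction &&
        config$threshold == "otsu") {
      bv <- empty_set("background_channel")
    } else {
      bv <- apply_size_filter(bv, config$min_voxels)
    }
  }
  ls <- label_structures(bv)
  structure(list(role = role, labels = ls$labels, stats = ls$stats,
                 mask = bv, n = ls$stats$structure_count),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set> %s: %d puncta, mean volume %.3g um^3\n",
              x$role, x$n, x$stats$mean_volume_um3))
  invisible(x)
}

# Shared-voxel counts between every punctum of `ps` and a mask.
shared_with_mask <- function(ps, mask) {
  k <- ps$n
  if (k == 0L) return(integer(0))
  tabulate(ps$labels[mask], nbins = k)
}

#' Classify puncta into the seven colocalisation classes
#'
#' Assigns every autophagosomal (LC3), lysosomal (LYSO) and mitochondrial
#' (MITO) punctum to one of AP, LYS, AL, MITO, AM, ML, AML by voxel overlap
#' of the binarized masks.  In exclusive mode: an LC3 punctum overlapping
#' both LYSO and MITO is an automitolysosome (AML); LC3+MITO only, an
#' automitosome (AM); LC3+LYSO only, an autolysosome (AL); LC3 alone, an
#' autophagosome (AP).  A LYSO punctum not overlapping LC3 is a mitolysosome
#' (ML) when it overlaps MITO, otherwise a free lysosome (LYS); MITO
#' structures without any vesicle overlap stay in the MITO class.  The
#' reported mean volume of a class uses its defining channel's puncta (LC3
#' for AP/AL/AM/AML, LYSO for LYS/ML, MITO for MITO).
#'
#' @param lc3,lyso,mito `puncta_set` objects (from [detect_puncta()]) sharing one geometry.
#' @param rule A [coloc_rule()].
#' @return An object of class `coloc_table`: data.frame with one row per
#'   class (`class`, `count`, `mean_volume_um3`) plus per-punctum
#'   assignments in `attr(, "assignments")`.
#' @export
classify_puncta <- function(lc3, lyso, mito, rule = coloc_rule()) {
  stopifnot(inherits(lc3, "puncta_set"), inherits(lyso, "puncta_set"),
            inherits(mito, "puncta_set"), inherits(rule, "coloc_rule"))
  if (!identical(dim(lc3$labels), dim(lyso$labels)) ||
      !identical(dim(lc3$labels), dim(mito$labels)))
    stop("puncta sets do not share one geometry")
  m <- rule$min_shared_voxels
  lyso_mask <- lyso$labels > 0L
  mito_mask <- mito$labels > 0L
  lc3_mask <- lc3$labels > 0L

  lc3_ly <- shared_with_mask(lc3, lyso_mask) >= m
  lc3_mi <- shared_with_mask(lc3, mito_mask) >= m
  ly_lc3 <- shared_with_mask(lyso, lc3_mask) >= m
  ly_mi <- shared_with_mask(lyso, mito_mask) >= m
  mi_lc3 <- shared_with_mask(mito, lc3_mask) >= m
  mi_ly <- shared_with_mask(mito, lyso_mask) >= m

  excl <- rule$classes_exclusive
  # indicator per class over its defining channel's puncta
  members <- list(
    AP   = !lc3_ly & !lc3_mi,
    LYS  = !ly_lc3 & !ly_mi,
    AL   = if (excl) lc3_ly & !lc3_mi else lc3_ly,
    MITO = !mi_lc3 & !mi_ly,
    AM   = if (excl) lc3_mi & !lc3_ly else lc3_mi,
    ML   = if (excl) ly_mi & !ly_lc3 else ly_mi,
    AML  = lc3_ly & lc3_mi)
  vols <- list(LC3 = lc3$stats$volumes_um3, LYSO = lyso$stats$volumes_um3,
               MITO = mito$stats$volumes_um3)
  tab <- data.frame(
    class = COLOC_CLASSES,
    count = vapply(COLOC_CLASSES, function(cl) sum(members[[cl]]), integer(1)),
    mean_volume_um3 = vapply(COLOC_CLASSES, function(cl) {
      v <- vols[[CLASS_DEFINING_CHANNEL[[cl]]]][members[[cl]]]
      if (length(v) == 0) 0 else mean(v)
    }, numeric(1)),
    row.names = NULL)
  # per-punctum class labels (exclusive partition; NA marks membership
  # already carried by another channel's punctum)
  lc3_class <- ifelse(lc3_ly & lc3_mi, "AML",
               ifelse(lc3_mi, "AM", ifelse(lc3_ly, "AL", "AP")))
  lyso_class <- ifelse(ly_lc3, NA_character_, ifelse(ly_mi, "ML", "LYS"))
  mito_class <- ifelse(mi_lc3 | mi_ly, NA_character_, "MITO")
  attr(tab, "assignments") <- list(LC3 = lc3_class, LYSO = lyso_class,
                                   MITO = mito_class)
  class(tab) <- c("coloc_table", "data.frame")
  tab
}

#' Mitochondrial morphometrics from the static MITO channel
#'
#' @param mito A `puncta_set` (from [detect_puncta()]) of the MITO channel.
#' @return A list: `count`, `mean_volume_um3` and `empty` flag.
#' @export
mito_morphometrics <- function(mito) {
  stopifnot(inherits(mito, "puncta_set"))
  list(count = mito$stats$structure_count,
       mean_volume_um3 = mito$stats$mean_volume_um3,
       empty = mito$stats$empty)
}
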