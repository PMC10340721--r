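#' Effect profile of one treatment group
#'
#' Group-level distributions from which per-cell scenarios are drawn.
#' Treatments exist only as labels with an effect profile — event rates,
#' per-class punctum count means and dispersions — not as pharmacology.
#'
#' @param fission_rate,fusion_rate Mean scripted events per frame
#'   transition of the time-lapse modality (realised counts are Poisson).
#' @param n_tubules Tubules in the first frame of each cell.
#' @param vesicle_means Named numeric vector of mean per-class punctum
#'   counts (names from the seven classes).
#' @param vesicle_cv Coefficient of variation of the between-cell counts
#'   (counts are drawn Normal(mean, cv * mean), rounded, floored at 0);
#'   0.12 emulates moderate cell-to-cell heterogeneity.
#' @param radius_scale Multiplier on the vesicle radius range (volume
#'   effects).
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(fission_rate = 1.5, fusion_rate = 1.2,
                          n_tubules = 6, vesicle_means = NULL,
                          vesicle_cv = 0.12, radius_scale = 1) {
  stopifnot(fission_rate >= 0, fusion_rate >= 0, vesicle_cv >= 0,
            radius_scale > 0)
  structure(list(fission_rate = fission_rate, fusion_rate = fusion_rate,
                 n_tubules = as.integer(n_tubules),
                 vesicle_means = vesicle_means, vesicle_cv = vesicle_cv,
                 radius_scale = radius_scale),
            class = "group_profile")
}

draw_mito_scenario <- function(profile, geometry) {
  nt <- geometry$n_frames - 1
  ev <- NULL
  if (nt >= 1) {
    nf <- stats::rpois(nt, profile$fission_rate)
    nu <- stats::rpois(nt, profile$fusion_rate)
    rows <- list()
    for (t in seq_len(nt)) {
      if (nf[t] > 0) rows[[length(rows) + 1]] <-
          data.frame(frame = t, type = rep("fission", nf[t]))
      if (nu[t] > 0) rows[[length(rows) + 1]] <-
          data.frame(frame = t, type = rep("fusion", nu[t]))
    }
    if (length(rows)) ev <- do.call(rbind, rows)
  }
  mito_scenario(n_tubules = profile$n_tubules, events = ev,
                on_unrealisable = "skip")
}

draw_vesicle_scenario <- function(profile) {
  mu <- profile$vesicle_means
  if (is.null(mu))
    stop("group profile has no vesicle_means but the vesicle modality was requested")
  counts <- pmax(0, round(stats::rnorm(length(mu), mu, profile$vesicle_cv * mu)))
  names(counts) <- names(mu)
  base <- vesicle_scenario(counts)
  base$radius_range_um <- base$radius_range_um * profile$radius_scale
  base$mito_radius_range_um <- base$mito_radius_range_um * profile$radius_scale
  base
}

#' Simulate a multi-group imaging experiment to disk
#'
#' Draws `n_cells_per_group` cells per treatment group from each group's
#' [group_profile()], writes one time-lapse stack (TMRE-like channel) and/or
#' one three-channel vesicle stack per cell as float TIFFs, and a JSON
#' manifest mapping every file to its cell, group and scripted ground truth
#' (realised event counts, per-class punctum counts).  Fully deterministic
#' given the seed.
#'
#' @param design Named list: group name -> [group_profile()].  At least two
#'   groups are required so downstream statistics are testable.
#' @param n_cells_per_group Cells per group.
#' @param seed Master seed; per-cell seeds are derived from it.
#' @param out_dir Output directory (created; must not already contain a
#'   manifest).
#' @param modality `"both"`, `"mito"` or `"vesicle"`.
#' @param mito_geometry_,vesicle_geometry_ Acquisition geometries.
#' @return The manifest (invisibly); written to `out_dir/manifest.json`.
#' @export
simulate_experiment <- function(design, n_cells_per_group = 9, seed = 1,
                                out_dir, modality = c("both", "mito", "vesicle"),
                                mito_geometry_ = mito_geometry(),
                                vesicle_geometry_ = vesicle_geometry()) {
  modality <- match.arg(modality)
  stopifnot(is.list(design), length(design) >= 2, !is.null(names(design)),
            all(vapply(design, inherits, logical(1), "group_profile")),
            n_cells_per_group >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path))
    stop(sprintf("output collision: %s already exists", manifest_path))

  cells <- list()
  idx <- 0L
  for (g in names(design)) {
    prof <- design[[g]]
    for (i in seq_len(n_cells_per_group)) {
      idx <- idx + 1L
      cell_id <- sprintf("%s_cell%02d", g, i)
      cseed <- child_seed(seed, idx)
      entry <- list(cell_id = cell_id, group = g, seed = cseed)
      if (modality %in% c("both", "mito")) {
        sc <- with_seed(cseed, draw_mito_scenario(prof, mito_geometry_))
        sim <- simulate_mito_timelapse(mito_geometry_, sc, seed = cseed + 1L)
        f <- file.path(out_dir, paste0(cell_id, "_mito.tif"))
        if (file.exists(f)) stop(sprintf("output collision: %s", f))
        write_stack_tiff(lapply(sim$frames, function(v) v$data), f)
        entry$mito_file <- basename(f)
        entry$mito_truth <- list(
          n_frames = mito_geometry_$n_frames,
          structure_counts = sim$truth$counts,
          n_fission = sum(sim$truth$events$type == "fission"),
          n_fusion = sum(sim$truth$events$type == "fusion"))
      }
      if (modality %in% c("both", "vesicle")) {
        sc <- with_seed(cseed + 2L, draw_vesicle_scenario(prof))
        sim <- simulate_vesicle_stack(vesicle_geometry_, sc, seed = cseed + 3L)
        f <- file.path(out_dir, paste0(cell_id, "_vesicle.tif"))
        if (file.exists(f)) stop(sprintf("output collision: %s", f))
        write_stack_tiff(lapply(sim$channels, function(v) v$data), f)
        true_counts <- table(factor(sim$truth$puncta$class,
                                    levels = COLOC_CLASSES))
        entry$vesicle_file <- basename(f)
        entry$vesicle_truth <- list(class_counts = as.list(true_counts))
      }
      cells[[idx]] <- entry
    }
  }
  manifest <- list(
    format_version = "1.0",
    seed = seed,
    modality = modality,
    groups = names(design),
    n_cells_per_group = n_cells_per_group,
    mito_geometry = if (modality != "vesicle") unclass(mito_geometry_),
    vesicle_geometry = if (modality != "mito") unclass(vesicle_geometry_),
    cells = cells)
  write_manifest(manifest, manifest_path)
  invisible(manifest)
}
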