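test_that("label_structures handles the empty mask and exact cube arithmetic", {
  empty <- binary_volume(array(FALSE, c(4, 8, 8)), 0.25, 0.1)
  s <- label_structures(empty)$stats
  expect_equal(s$structure_count, 0L)
  expect_equal(s$mean_volume_um3, 0)
  expect_true(s$empty)

  m <- array(FALSE, c(8, 12, 12))
  m[2:4, 2:4, 2:4] <- TRUE
  m[2:4, 8:10, 8:10] <- TRUE
  s2 <- label_structures(binary_volume(m, 0.25, 0.1))$stats
  expect_equal(s2$structure_count, 2L)
  # 27 voxels x 0.1 x 0.1 x 0.25 um
  expect_equal(s2$mean_volume_um3, 0.0675)
})

test_that("labelling and volumes agree with a flood-fill oracle on random scenes", {
  vv <- 0.25 * 0.1^2
  for (seed in 1:5) {
    mask <- random_blob_mask(c(10, 28, 28), 12, seed + 40)
    ls <- label_structures(binary_volume(mask, 0.25, 0.1))
    expect_equal(ls$stats$structure_count, max(flood_fill_labels(mask)))
    expect_equal(sort(ls$stats$volumes_um3, decreasing = TRUE),
                 flood_fill_sizes(mask) * vv)
    # bookkeeping identity: mean volume x count == total mask volume
    expect_equal(ls$stats$mean_volume_um3 * ls$stats$structure_count,
                 sum(mask) * vv, tolerance = 1e-12)
  }
})

test_that("identical frames yield no events", {
  mask <- random_blob_mask(c(6, 20, 20), 6, 3)
  bv <- binary_volume(mask, 0.25, 0.1)
  det <- detect_events(bv, bv)
  expect_equal(nrow(det$events), 0)
  expect_length(det$appeared, 0)
  expect_length(det$disappeared, 0)
})

test_that("removing a rod's middle voxel is one fission located at the gap", {
  m1 <- array(FALSE, c(1, 3, 12))
  m1[1, 2, 2:11] <- TRUE
  m2 <- m1
  m2[1, 2, 6] <- FALSE
  det <- detect_events(binary_volume(m1, 0.25, 0.1),
                       binary_volume(m2, 0.25, 0.1))
  expect_equal(det$events$type, "fission")
  expect_equal(det$events$y, 2)
  expect_true(abs(det$events$x - 6) <= 1)
  # reversed direction is the mirror fusion at the same place
  det_r <- detect_events(binary_volume(m2, 0.25, 0.1),
                         binary_volume(m1, 0.25, 0.1))
  expect_equal(det_r$events$type, "fusion")
  expect_equal(det_r$events[, c("z", "y", "x")], det$events[, c("z", "y", "x")])
})

test_that("frame order swap exchanges fission and fusion exactly", {
  g <- mito_geometry(n_frames = 2, n_xy_px = 96)
  sc <- mito_scenario(n_tubules = 4, gaussian_sd = 0, poisson_scaling = 0,
                      events = data.frame(frame = c(1, 1),
                                          type = c("fission", "fusion")))
  sim <- simulate_mito_timelapse(g, sc, seed = 17)
  b1 <- binary_volume(sim$truth$masks[[1]], 0.25, 0.1)
  b2 <- binary_volume(sim$truth$masks[[2]], 0.25, 0.1)
  fwd <- detect_events(b1, b2)
  rev <- detect_events(b2, b1)
  swap <- c(fission = "fusion", fusion = "fission")
  expect_equal(sort(unname(swap[fwd$events$type])), sort(rev$events$type))
  expect_equal(fwd$events[order(fwd$events$z, fwd$events$y, fwd$events$x),
                          c("z", "y", "x")],
               rev$events[order(rev$events$z, rev$events$y, rev$events$x),
                          c("z", "y", "x")],
               ignore_attr = TRUE)
})

test_that("count bookkeeping holds across scripted clean transitions", {
  g <- mito_geometry(n_frames = 6, n_xy_px = 96)
  ev <- data.frame(frame = c(1, 2, 2, 3, 4, 5),
                   type = c("fission", "fission", "fission", "fusion",
                            "fission", "fusion"))
  sc <- mito_scenario(n_tubules = 4, gaussian_sd = 0, poisson_scaling = 0,
                      events = ev)
  sim <- simulate_mito_timelapse(g, sc, seed = 23)
  for (t in 1:5) {
    e <- sum(sim$truth$events$type == "fission" &
               sim$truth$events$frame_from == t)
    f <- sum(sim$truth$events$type == "fusion" &
               sim$truth$events$frame_from == t)
    expect_equal(sim$truth$counts[t + 1] - sim$truth$counts[t], e - f)
    det <- detect_events(binary_volume(sim$truth$masks[[t]], 0.25, 0.1),
                         binary_volume(sim$truth$masks[[t + 1]], 0.25, 0.1))
    expect_equal(sum(det$events$type == "fission"), e)
    expect_equal(sum(det$events$type == "fusion"), f)
  }
})

test_that("shape mismatch and short series are rejected", {
  b1 <- binary_volume(array(FALSE, c(2, 4, 4)), 0.25, 0.1)
  b2 <- binary_volume(array(FALSE, c(2, 4, 5)), 0.25, 0.1)
  expect_error(detect_events(b1, b2), "different shapes")
  expect_error(summarise_series(list(b1)), "at least 2 frames")
})

test_that("series summary of identical frames is static; averages are exact", {
  mask <- random_blob_mask(c(6, 24, 24), 8, 5)
  frames <- replicate(4, binary_volume(mask, 0.25, 0.1), simplify = FALSE)
  s <- summarise_series(frames)
  expect_equal(s$cell_summary$mean_fission, 0)
  expect_equal(s$cell_summary$mean_fusion, 0)
  expect_equal(s$cell_summary$mean_structure_count,
               max(flood_fill_labels(mask)))
  expect_equal(unique(s$per_frame$structure_count),
               max(flood_fill_labels(mask)))
})

test_that("series summary equals an independent per-pair recomputation", {
  g <- mito_geometry(n_frames = 5, n_xy_px = 96)
  sc <- mito_scenario(n_tubules = 4, gaussian_sd = 0, poisson_scaling = 0,
                      events = data.frame(frame = c(1, 2, 4),
                                          type = c("fission", "fusion",
                                                   "fission")))
  sim <- simulate_mito_timelapse(g, sc, seed = 29)
  frames <- lapply(sim$frames, function(f)
    binarize(f, preprocess_config()))
  s <- summarise_series(frames)
  # brute force: per-pair counts via the overlap multiplicity definition
  brute <- t(vapply(1:4, function(t) {
    la <- flood_fill_labels(frames[[t]]$mask)
    lb <- flood_fill_labels(frames[[t + 1]]$mask)
    both <- la > 0 & lb > 0
    pairs <- unique(cbind(la[both], lb[both]))
    fis <- sum(pmax(table(factor(pairs[, 1])) - 1, 0))
    fus <- sum(pmax(table(factor(pairs[, 2])) - 1, 0))
    c(fis, fus)
  }, numeric(2)))
  expect_equal(s$per_pair$fission, unname(brute[, 1]))
  expect_equal(s$per_pair$fusion, unname(brute[, 2]))
  expect_equal(s$cell_summary$mean_fission, mean(brute[, 1]))
  expect_equal(s$cell_summary$mean_fusion, mean(brute[, 2]))
})
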