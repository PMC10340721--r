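test_that("event-free noise-free time-lapse is static and truth is empty", {
  g <- mito_geometry(n_frames = 5, n_xy_px = 64)
  sc <- mito_scenario(n_tubules = 2, gaussian_sd = 0, poisson_scaling = 0)
  sim <- simulate_mito_timelapse(g, sc, seed = 4)
  expect_equal(nrow(sim$truth$events), 0)
  for (t in 2:5) {
    expect_identical(sim$truth$masks[[t]], sim$truth$masks[[1]])
    expect_identical(sim$frames[[t]]$data, sim$frames[[1]]$data)
  }
  # binarized rendered frames are identical too
  m1 <- binarize(sim$frames[[1]], preprocess_config())$mask
  m3 <- binarize(sim$frames[[3]], preprocess_config())$mask
  expect_identical(m1, m3)
})

test_that("a scripted fission raises the structure count from its transition on", {
  g <- mito_geometry(n_frames = 5, n_xy_px = 64)
  sc <- mito_scenario(n_tubules = 1, gaussian_sd = 0, poisson_scaling = 0,
                      events = data.frame(frame = 3, type = "fission"))
  sim <- simulate_mito_timelapse(g, sc, seed = 11)
  # counts checked against an independent flood-fill on the truth masks
  oracle_counts <- vapply(sim$truth$masks,
                          function(m) max(flood_fill_labels(m)), integer(1))
  expect_equal(oracle_counts, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(sim$truth$counts, oracle_counts)
  ev <- sim$truth$events
  expect_equal(ev$type, "fission")
  expect_equal(ev$frame_from, 3)
  # location lies inside the parent's footprint
  expect_true(sim$truth$masks[[3]][ev$z, ev$y, ev$x])
})

test_that("the generator is bit-reproducible for a fixed seed", {
  g <- mito_geometry(n_frames = 3, n_xy_px = 48)
  sc <- mito_scenario(n_tubules = 2,
                      events = data.frame(frame = 1, type = "fission"))
  s1 <- simulate_mito_timelapse(g, sc, seed = 21)
  s2 <- simulate_mito_timelapse(g, sc, seed = 21)
  expect_identical(lapply(s1$frames, `[[`, "data"),
                   lapply(s2$frames, `[[`, "data"))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_mito_timelapse(g, sc, seed = 22)
  expect_false(identical(s1$frames[[1]]$data, s3$frames[[1]]$data))
})

test_that("scripted events validate frames and structure ids", {
  g <- mito_geometry(n_frames = 3, n_xy_px = 48)
  bad_frame <- mito_scenario(n_tubules = 1,
                             events = data.frame(frame = 3, type = "fission"))
  expect_error(simulate_mito_timelapse(g, bad_frame, seed = 1),
               "frame index")
  bad_id <- mito_scenario(n_tubules = 1,
                          events = data.frame(frame = 1, type = "fission",
                                              structure = 5))
  expect_error(simulate_mito_timelapse(g, bad_id, seed = 1),
               "non-existent structure")
  bad_pair <- mito_scenario(n_tubules = 2,
                            events = data.frame(frame = 1, type = "fusion",
                                                structure = 1, structure2 = 1))
  expect_error(simulate_mito_timelapse(g, bad_pair, seed = 1),
               "invalid structure pair")
})

test_that("a distant fusion with no feasible bridge names the pair", {
  g <- mito_geometry(n_frames = 2, n_xy_px = 96)
  sc <- mito_scenario(n_tubules = 2, tubule_length_um = 1.2,
                      max_bridge_um = 0.01,
                      events = data.frame(frame = 1, type = "fusion",
                                          structure = 1, structure2 = 2))
  expect_error(simulate_mito_timelapse(g, sc, seed = 2),
               "no feasible bridge between structures 1 and 2")
})

test_that("vesicle channels carry exactly the scripted puncta with zero cross-class contact", {
  g <- vesicle_geometry(n_xy_px = 96)
  sim <- simulate_vesicle_stack(g, vesicle_scenario(c(AP = 5, LYS = 3)),
                                seed = 9)
  expect_equal(max(flood_fill_labels(sim$truth$masks$LC3)), 5L)
  expect_equal(max(flood_fill_labels(sim$truth$masks$LYSO)), 3L)
  expect_equal(sum(sim$truth$masks$MITO), 0)
  # brute-force overlap check on the ground-truth masks
  expect_equal(sum(sim$truth$masks$LC3 & sim$truth$masks$LYSO), 0)
})

test_that("every punctum is rendered into exactly the channels of its class", {
  g <- vesicle_geometry(n_xy_px = 128)
  counts <- c(AP = 3, LYS = 3, AL = 3, MITO = 2, AM = 2, ML = 2, AML = 3)
  sim <- simulate_vesicle_stack(g, vesicle_scenario(counts), seed = 14)
  expect_equal(as.vector(table(factor(sim$truth$puncta$class,
                                      levels = names(counts)))),
               as.vector(counts))
  # per-channel component totals must equal the sum of counts of the
  # classes rendered into that channel
  chan_classes <- list(
    LC3 = c("AP", "AL", "AM", "AML"),
    LYSO = c("LYS", "AL", "ML", "AML"),
    MITO = c("MITO", "AM", "ML", "AML"))
  for (ch in names(chan_classes)) {
    expect_equal(max(flood_fill_labels(sim$truth$masks[[ch]])),
                 sum(counts[chan_classes[[ch]]]),
                 info = ch)
  }
  # AML puncta overlap both other channels in the ground truth
  aml <- sim$truth$puncta[sim$truth$puncta$class == "AML", ]
  lab_lc3 <- sim$truth$labels$LC3
  for (i in seq_len(nrow(aml))) {
    id <- lab_lc3[round(aml$z[i]), round(aml$y[i]), round(aml$x[i])]
    expect_gt(sum(lab_lc3 == id & sim$truth$masks$LYSO), 0)
    expect_gt(sum(lab_lc3 == id & sim$truth$masks$MITO), 0)
  }
})

test_that("full overlap renders coincident spheres; placement limits error out", {
  g <- vesicle_geometry(n_xy_px = 64)
  sim <- simulate_vesicle_stack(
    g, vesicle_scenario(c(AL = 3), overlap_fraction = 1), seed = 5)
  expect_identical(sim$truth$masks$LC3, sim$truth$masks$LYSO)
  expect_error(
    simulate_vesicle_stack(g, vesicle_scenario(c(AP = 500)), seed = 5),
    "placement error")
})

test_that("simulate_experiment writes one stack per cell per modality plus a manifest", {
  design <- list(a = group_profile(vesicle_means = c(AP = 4, LYS = 4)),
                 b = group_profile(vesicle_means = c(AP = 4, LYS = 8)))
  out <- tempfile()
  man <- simulate_experiment(design, n_cells_per_group = 3, seed = 7,
                             out_dir = out, modality = "vesicle",
                             vesicle_geometry_ = vesicle_geometry(n_xy_px = 64))
  files <- list.files(out)
  expect_equal(sum(grepl("_vesicle\\.tif$", files)), 6)
  expect_true("manifest.json" %in% files)
  expect_equal(length(man$cells), 6)
  # group effect survives into the manifest ground truth by construction
  ap_b <- vapply(man$cells[4:6],
                 function(cl) cl$vesicle_truth$class_counts$LYS, integer(1))
  expect_true(mean(ap_b) > 4)
  # determinism: a second run writes an identical manifest
  out2 <- tempfile()
  man2 <- simulate_experiment(design, n_cells_per_group = 3, seed = 7,
                              out_dir = out2, modality = "vesicle",
                              vesicle_geometry_ = vesicle_geometry(n_xy_px = 64))
  expect_identical(man$cells, man2$cells)
  # path collision is refused
  expect_error(simulate_experiment(design, n_cells_per_group = 3, seed = 7,
                                   out_dir = out, modality = "vesicle"),
               "collision")
  unlink(c(out, out2), recursive = TRUE)
})
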