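vg <- function(px = 96) vesicle_geometry(n_xy_px = px)

puncta_from_sim <- function(sim, cfg = preprocess_config()) {
  list(LC3 = detect_puncta(sim$channels$LC3, "LC3", cfg),
       LYSO = detect_puncta(sim$channels$LYSO, "LYSO", cfg),
       MITO = detect_puncta(sim$channels$MITO, "MITO", cfg))
}

test_that("puncta detection recovers clean rendered spheres and empty channels", {
  sim <- simulate_vesicle_stack(vg(), vesicle_scenario(c(AP = 5, LYS = 3)),
                                seed = 2)
  ps <- puncta_from_sim(sim)
  expect_equal(ps$LC3$n, 5L)
  expect_equal(ps$LYSO$n, 3L)
  # all-background MITO channel (constant zero before noise is impossible
  # here, so build one directly)
  zero <- voxel_grid(array(0, dim(sim$channels$MITO$data)), 0.35, 0.1)
  expect_equal(detect_puncta(zero, "MITO")$n, 0L)
})

test_that("the size filter inside detect_puncta removes sub-threshold spheres", {
  a <- array(0, c(6, 24, 24))
  a[3, 5:6, 5:6] <- 100                     # 4 voxels
  a[3:4, 15:18, 15:18] <- 100               # 32 voxels
  g <- voxel_grid(a, 0.35, 0.1)
  cfg <- preprocess_config(denoise = "none", min_voxels = 8)
  expect_equal(detect_puncta(g, "LC3", cfg)$n, 1L)
  cfg2 <- preprocess_config(denoise = "none", min_voxels = 64)
  expect_equal(detect_puncta(g, "LC3", cfg2)$n, 0L)
})

test_that("pure AML scenes classify as AML only; isolated LC3 is AP", {
  sim <- simulate_vesicle_stack(vg(), vesicle_scenario(c(AML = 4),
                                                       overlap_fraction = 1),
                                seed = 6)
  ps <- puncta_from_sim(sim)
  tab <- classify_puncta(ps$LC3, ps$LYSO, ps$MITO)
  expect_equal(tab$count[tab$class == "AML"], 4L)
  expect_equal(sum(tab$count[tab$class != "AML"]), 0L)

  sim2 <- simulate_vesicle_stack(vg(), vesicle_scenario(c(AP = 6)), seed = 6)
  ps2 <- puncta_from_sim(sim2)
  tab2 <- classify_puncta(ps2$LC3, ps2$LYSO, ps2$MITO)
  expect_equal(tab2$count[tab2$class == "AP"], 6L)
  expect_equal(sum(tab2$count[tab2$class != "AP"]), 0L)
})

test_that("a mixed seven-class scene is recovered exactly, volumes included", {
  counts <- c(AP = 5, LYS = 3, AL = 7, MITO = 4, AM = 2, ML = 4, AML = 6)
  sim <- simulate_vesicle_stack(vg(160), vesicle_scenario(counts), seed = 3)
  ps <- puncta_from_sim(sim)
  tab <- classify_puncta(ps$LC3, ps$LYSO, ps$MITO)
  expect_equal(stats::setNames(tab$count, tab$class),
               counts[tab$class])
  # class volumes match the ground-truth defining-channel volumes
  tru <- sim$truth$puncta
  for (cl in names(counts)) {
    expect_equal(tab$mean_volume_um3[tab$class == cl],
                 mean(tru$volume_um3[tru$class == cl]),
                 tolerance = 0.25, info = cl)
  }
  mm <- mito_morphometrics(ps$MITO)
  # MITO channel holds MITO + AM + ML + AML structures
  expect_equal(mm$count, sum(counts[c("MITO", "AM", "ML", "AML")]))
})

test_that("exclusive classification partitions the LC3 pool", {
  for (seed in c(4, 9)) {
    counts <- c(AP = 4, LYS = 4, AL = 5, MITO = 3, AM = 3, ML = 3, AML = 5)
    sim <- simulate_vesicle_stack(vg(160), vesicle_scenario(counts),
                                  seed = seed)
    ps <- puncta_from_sim(sim)
    tab <- classify_puncta(ps$LC3, ps$LYSO, ps$MITO)
    with_tab <- function(cl) tab$count[tab$class == cl]
    expect_equal(with_tab("AP") + with_tab("AL") + with_tab("AM") +
                   with_tab("AML"), ps$LC3$n)
    asg <- attr(tab, "assignments")
    expect_false(any(is.na(asg$LC3)))
  }
})

test_that("raising min_shared_voxels never increases colocalised counts", {
  counts <- c(AL = 6, AM = 4, AML = 4, AP = 3, LYS = 3, MITO = 3)
  sim <- simulate_vesicle_stack(vg(160), vesicle_scenario(counts), seed = 13)
  ps <- puncta_from_sim(sim)
  prev <- NULL
  for (m in c(1, 5, 20, 80)) {
    tab <- classify_puncta(ps$LC3, ps$LYSO, ps$MITO, coloc_rule(m))
    cc <- tab$count[tab$class %in% c("AL", "AM", "ML", "AML")]
    if (!is.null(prev)) expect_true(all(cc <= prev))
    prev <- cc
  }
})

test_that("overlap classification is symmetric in argument order", {
  counts <- c(AL = 5, AP = 3, LYS = 3)
  sim <- simulate_vesicle_stack(vg(), vesicle_scenario(counts), seed = 21)
  ps <- puncta_from_sim(sim)
  tab <- classify_puncta(ps$LC3, ps$LYSO, ps$MITO)
  # AL pairs seen from the LYSO side: lysosomes overlapping LC3 equal AL count
  n_lyso_touching_lc3 <- sum(is.na(attr(tab, "assignments")$LYSO))
  expect_equal(n_lyso_touching_lc3, tab$count[tab$class == "AL"])
})

test_that("inclusive mode counts pairwise classes irrespective of the third channel", {
  counts <- c(AML = 5, AM = 2, AL = 3)
  sim <- simulate_vesicle_stack(vg(160), vesicle_scenario(counts), seed = 8)
  ps <- puncta_from_sim(sim)
  inc <- classify_puncta(ps$LC3, ps$LYSO, ps$MITO,
                         coloc_rule(classes_exclusive = FALSE))
  expect_equal(inc$count[inc$class == "AM"], 7L)   # AM + AML
  expect_equal(inc$count[inc$class == "AL"], 8L)   # AL + AML
  expect_equal(inc$count[inc$class == "AML"], 5L)
})

test_that("geometry mismatch between channels is rejected", {
  sim <- simulate_vesicle_stack(vg(64), vesicle_scenario(c(AP = 2)), seed = 1)
  ps <- puncta_from_sim(sim)
  other <- detect_puncta(voxel_grid(array(0, c(12, 32, 32)), 0.35, 0.1),
                         "LYSO")
  expect_error(classify_puncta(ps$LC3, other, ps$MITO), "geometry")
})

test_that("mito morphometrics flag the empty channel and use voxel arithmetic", {
  zero <- detect_puncta(voxel_grid(array(0, c(6, 16, 16)), 0.35, 0.1), "MITO")
  mm <- mito_morphometrics(zero)
  expect_equal(mm$count, 0L)
  expect_equal(mm$mean_volume_um3, 0)
  expect_true(mm$empty)

  a <- array(0, c(8, 20, 20))
  a[2:4, 2:4, 2:4] <- 100
  a[5:7, 12:14, 12:14] <- 100
  ps <- detect_puncta(voxel_grid(a, 0.35, 0.1), "MITO",
                      preprocess_config(denoise = "none"))
  mm2 <- mito_morphometrics(ps)
  expect_equal(mm2$count, 2L)
  expect_equal(mm2$mean_volume_um3, 27 * 0.1 * 0.1 * 0.35)
})
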