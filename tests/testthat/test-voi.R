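test_that("isocontour VOI matches the brute-force graph oracle", {
  set.seed(101)
  for (trial in 1:20) {
    img <- random_activity_image(c(5, 5, 5))
    member <- which(img$values >= 0.5 * max(img$values))
    seed_lin <- sample(member, 1)
    seed_ijk <- drop(arrayInd(seed_lin, dim(img$values)))
    voi <- isocontour_voi(img, 0.5, seed_ijk)
    expect_identical(voi$voxels,
                     as.integer(oracle_isocontour(img$values, 0.5, seed_ijk)))
  }
})

test_that("uniform image yields the whole search region at any threshold", {
  img <- activity_image(array(3, dim = c(6, 6, 6)), c(2, 2, 2))
  reg <- array(FALSE, dim = c(6, 6, 6)); reg[2:5, 2:5, 2:5] <- TRUE
  for (t in c(0.1, 0.5, 1)) {
    voi <- isocontour_voi(img, t, c(3, 3, 3), search_region = reg)
    expect_setequal(voi$voxels, which(reg))
  }
})

test_that("threshold 1.0 keeps only the maximal component of the seed", {
  vals <- array(0, dim = c(7, 7, 7))
  vals[2, 2, 2] <- 5; vals[2, 3, 2] <- 5   # adjacent maxima
  vals[6, 6, 6] <- 5                       # distant maximum
  vals[4, 4, 4] <- 3
  img <- activity_image(vals, c(1, 1, 1))
  voi <- isocontour_voi(img, 1, c(2, 2, 2))
  expect_setequal(voi$voxels,
                  c(which(vals == 5 & slice.index(vals, 1) < 4)))
  expect_length(voi$voxels, 2)
})

test_that("a seed below the threshold raises an empty-VOI error", {
  vals <- array(1, dim = c(4, 4, 4)); vals[1, 1, 1] <- 10
  img <- activity_image(vals, c(1, 1, 1))
  expect_error(isocontour_voi(img, 0.8, c(4, 4, 4)), "80%")
  expect_error(isocontour_voi(img, 0.8, c(9, 4, 4)), "grid")
})

test_that("VOIs are nested as the threshold rises", {
  fx <- blurred_sphere_fixture(noise = TRUE, seed = 3)
  peak <- drop(arrayInd(which.max(fx$image$values), dim(fx$image$values)))
  prev <- NULL
  for (t in c(0.2, 0.35, 0.5, 0.65, 0.8, 0.95)) {
    voi <- isocontour_voi(fx$image, t, peak)
    if (!is.null(prev)) expect_true(all(voi$voxels %in% prev))
    prev <- voi$voxels
  }
})

test_that("volume and count measurement agree with direct arithmetic", {
  vals <- array(2, dim = c(10, 10, 10))
  img <- activity_image(vals, c(4, 4, 4))
  voi <- isocontour_voi(img, 0.5, c(5, 5, 5))  # uniform: all 1000 voxels
  expect_equal(measure_volume(voi, img), 64)
  expect_equal(measure_counts(voi, img), 2000)
  img2 <- random_activity_image(c(10, 10, 10), voxel_size = c(4, 4, 4))
  img2$values[5, 5, 5] <- max(img2$values) # make the seed the maximum
  voi2 <- isocontour_voi(img2, 0.3, c(5, 5, 5))
  expect_equal(measure_counts(voi2, img2), sum(img2$values[voi2$voxels]))
  other <- activity_image(img2$values, c(2, 2, 2))
  expect_error(measure_counts(voi2, other), "grid")
})

test_that("a VOI equal to a rasterized 473 mL cylinder measures 473 mL", {
  spec <- cylinder_phantom(473, 42.5, grid_shape = c(96L, 96L, 96L),
                           voxel_size = c(1, 1, 1))
  ras <- rasterize(spec)
  img <- activity_image(ras$image$values, c(1, 1, 1))
  voi <- isocontour_voi(img, 0.5, as.integer(dim(img$values) / 2))
  expect_equal(voi$voxels, which(ras$masks$cylinder$values))
  expect_lt(abs(percent_error(measure_volume(voi), 473)), 2)
})

test_that("anatomical fitting recovers a constructed superlevel fixed point", {
  fx <- blurred_sphere_fixture(noise = FALSE)
  reg <- maadose:::box_region(dim(fx$image$values), fx$image$voxel_size,
                              fx$center, 45)
  ref_max <- max(fx$image$values[reg])
  truth <- (fx$image$values >= 0.40 * ref_max) & reg
  fit <- fit_threshold_anatomical(fx$image,
                                  reference_mask(truth, fx$image$voxel_size,
                                                 "fixedpoint"),
                                  search_region = reg)
  expect_equal(fit$best_threshold, 0.40)
  expect_equal(fit$objective, 1.0)
})

test_that("anatomical fitting on clean rasterized objects is near-exact", {
  ras <- rasterize(jaszczak_phantom())
  img <- ras$image
  for (lab in c("sphere1", "sphere3")) {
    fit <- fit_threshold_anatomical(img, ras$masks[[lab]])
    expect_gte(fit$objective, 0.99)
    raster_mL <- sum(ras$masks[[lab]]$values) *
      voxel_volume_mL(img$voxel_size)
    expect_equal(measure_volume(fit$voi), raster_mL, tolerance = 1e-9)
  }
})

test_that("Dice ties resolve to the smallest threshold", {
  vals <- array(0, dim = c(12, 12, 12))
  vals[5:8, 5:8, 5:8] <- 7  # step object in empty background
  img <- activity_image(vals, c(1, 1, 1))
  mask <- vals > 0
  fit <- fit_threshold_anatomical(img, reference_mask(mask, c(1, 1, 1), "cube"),
                                  thresholds = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(fit$best_threshold, 0.2)  # every threshold gives the same VOI
  expect_equal(fit$objective, 1.0)
})

test_that("hot-spot fitting recovers a step-edge object exactly", {
  vals <- array(0, dim = c(24, 24, 24))
  vals[8:16, 8:16, 8:16] <- 5
  img <- activity_image(vals, c(2, 2, 2))
  fit <- fit_threshold_hotspot(img, c(12, 12, 12), display_gamma = 1)
  expect_equal(sort(fit$voi$voxels), which(vals == 5))
})

test_that("hot-spot fitting is deterministic and gamma-sensitive", {
  fx <- blurred_sphere_fixture(ratio = 6, noise = TRUE, seed = 11)
  f1 <- fit_threshold_hotspot(fx$image, fx$center, display_gamma = 0.7)
  f1b <- fit_threshold_hotspot(fx$image, fx$center, display_gamma = 0.7)
  f2 <- fit_threshold_hotspot(fx$image, fx$center, display_gamma = 1.6)
  expect_identical(f1$voi$voxels, f1b$voi$voxels)
  expect_false(isTRUE(all.equal(measure_volume(f1$voi),
                                measure_volume(f2$voi))))
})

test_that("hot-spot fitting fails cleanly on an edgeless image", {
  img <- activity_image(array(4, dim = c(10, 10, 10)), c(2, 2, 2))
  expect_error(fit_threshold_hotspot(img, c(5, 5, 5)), "edge")
})
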