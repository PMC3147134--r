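test_that("rasterized volumes converge to analytic volumes at 1 mm voxels", {
  # spheres of the phantom set, each alone on a fine grid
  for (v in c(55, 20.5, 16, 8)) {
    r <- (3 * v * 1000 / (4 * pi))^(1 / 3)
    ob <- geometric_object("sphere", c(32, 32, 32), r, 1, "s")
    ras <- rasterize(phantom_spec(list(ob), grid_shape = c(64L, 64L, 64L),
                                  voxel_size = c(1, 1, 1)))
    vol <- sum(ras$masks$s$values) / 1000
    expect_lt(abs(percent_error(vol, v)), 2)
  }
  # liver-like cylinders
  for (cfg in list(c(6716, 108), c(774, 50), c(473, 42.5))) {
    h <- cfg[1] * 1000 / (pi * cfg[2]^2)
    n <- as.integer(2 * cfg[2] + 8)
    nz <- as.integer(h + 8)
    ob <- geometric_object("cylinder", c(n / 2, n / 2, nz / 2),
                           c(cfg[2], h), 1, "c")
    ras <- rasterize(phantom_spec(list(ob), grid_shape = c(n, n, nz),
                                  voxel_size = c(1, 1, 1)))
    vol <- sum(ras$masks$c$values) / 1000
    expect_lt(abs(percent_error(vol, cfg[1])), 2)
  }
})

test_that("rasterize paints innermost objects and reproduces contrast ratios", {
  ras <- rasterize(jaszczak_phantom(sphere_ratios = c(2.8, 7.6, 9.6, 19.6)))
  img <- ras$image$values
  bg_only <- ras$masks$cylinder1$values
  for (s in paste0("sphere", 1:4)) bg_only <- bg_only & !ras$masks[[s]]$values
  expect_equal(max(img[ras$masks$sphere1$values]) / mean(img[bg_only]), 2.8)
  expect_equal(max(img[ras$masks$sphere4$values]) / mean(img[bg_only]), 19.6)
  # outside the phantom there is no activity
  expect_equal(img[1, 1, 1], 0)
})

test_that("empty phantom rasterizes to an all-zero image", {
  ras <- rasterize(phantom_spec(list(), background = 0,
                                grid_shape = c(8L, 8L, 8L)))
  expect_true(all(ras$image$values == 0))
  expect_length(ras$masks, 0)
})

test_that("objects protruding from the grid are rejected by name", {
  ob <- geometric_object("sphere", c(2, 32, 32), 10, 1, "runaway")
  expect_error(phantom_spec(list(ob), grid_shape = c(64L, 64L, 64L),
                            voxel_size = c(1, 1, 1)),
               "runaway")
})

test_that("degrade with zero PSF and no noise only rescales", {
  img <- random_activity_image(c(8, 8, 8), max_val = 5)
  out <- degrade(img, acquisition_model(0, 1000, noise = FALSE))
  expect_equal(sum(out$values), 1000)
  expect_equal(out$values, img$values * (1000 / sum(img$values)))
})

test_that("noise-free degradation is linear and conserves counts", {
  a <- random_activity_image(c(16, 16, 16))
  acq <- acquisition_model(10, 5e4, noise = FALSE)
  out <- degrade(a, acq)
  expect_lt(abs(sum(out$values) - 5e4) / 5e4, 1e-6)
  # blur itself (before rescaling) is linear: blur(x + y) = blur(x) + blur(y)
  b <- random_activity_image(c(16, 16, 16))
  ab <- activity_image(a$values + b$values, a$voxel_size)
  blur <- function(im) degrade(im, acquisition_model(10, sum(im$values),
                                                     noise = FALSE))$values
  expect_equal(blur(ab), blur(a) * 1 + blur(b), tolerance = 1e-8)
})

test_that("Poisson degradation is seed-reproducible and seed-sensitive", {
  img <- blurred_sphere_fixture(noise = FALSE)$clean
  acq1 <- acquisition_model(0, 1e5, noise = TRUE, seed = 42)
  n1 <- degrade(img, acq1)
  n2 <- degrade(img, acq1)
  n3 <- degrade(img, acquisition_model(0, 1e5, noise = TRUE, seed = 43))
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  # degradation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(degrade(img, acq1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("a point source blurred at 15 mm FWHM measures 15 +/- 1 mm", {
  vals <- array(0, dim = c(64, 64, 64))
  vals[32, 32, 32] <- 1
  img <- activity_image(vals, c(2, 2, 2))
  out <- degrade(img, acquisition_model(15, 1e6, noise = FALSE))
  prof <- out$values[, 32, 32]
  x <- (seq_len(64) - 0.5) * 2
  mu <- sum(prof * x) / sum(prof)
  sigma <- sqrt(sum(prof * (x - mu)^2) / sum(prof))
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_lt(abs(fwhm - 15), 1)
})

test_that("clinical phantom enforces the tumor count fraction exactly", {
  cp <- make_clinical_phantom(1829, 610, 0.691)
  tum <- sum(cp$image$values[cp$tumor_mask$values])
  liv <- sum(cp$image$values[cp$liver_mask$values])
  expect_equal(tum / liv, 0.691, tolerance = 1e-9)
  # tumor sits strictly inside the liver
  expect_true(all(cp$liver_mask$values[cp$tumor_mask$values]))
})

test_that("clinical phantom limit cases", {
  # fraction matching the volume fraction gives uniform concentrations
  cp <- make_clinical_phantom(1000, 400, 0.5, grid_shape = c(64L, 64L, 64L))
  nt <- sum(cp$tumor_mask$values); nl <- sum(cp$liver_mask$values)
  cp2 <- make_clinical_phantom(1000, 400, nt / nl,
                               grid_shape = c(64L, 64L, 64L))
  inside <- cp2$image$values[cp2$liver_mask$values]
  expect_equal(max(inside), min(inside), tolerance = 1e-9)
  # stated concentration contrast: f = 0.10 with V_t = 150 in 1500 mL gives
  # c_t / c_h = f V_h / ((1 - f) V_t), here exactly uniform (ratio 1)
  cp3 <- make_clinical_phantom(1500, 150, 0.10)
  c_t <- max(cp3$image$values[cp3$tumor_mask$values])
  healthy <- cp3$liver_mask$values & !cp3$tumor_mask$values
  c_h <- max(cp3$image$values[healthy])
  nt <- sum(cp3$tumor_mask$values); nh <- sum(healthy)
  expect_equal(c_t / c_h, (0.10 / 0.90) * nh / nt, tolerance = 1e-9)
  expect_equal((0.10 / 0.90) * 1350 / 150, 1.0)
  expect_error(make_clinical_phantom(1000, 1200, 0.5), "liver")
})
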