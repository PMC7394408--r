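test_that("zone partition of a disk has the analytic core area and tiles exactly", {
  disk <- mask_roi(oracle_disk_mask(c(64, 64), 20, c(128L, 128L)))
  part <- partition_zones(disk, fractions = c(0.5, 1.0))
  # inner half of the radius covers a quarter of the area
  expect_lt(abs(roi_size(part$core) - roi_size(disk) / 4) / (roi_size(disk) / 4), 0.10)
  expect_true(roi_equal(roi_union(part$core, part$middle), disk))
  expect_true(is_empty_roi(roi_intersect(part$core, part$middle)))
  expect_true(is_empty_roi(roi_intersect(part$middle, part$outer_ring)))
  # outer ring sits outside the inclusion
  expect_true(is_empty_roi(roi_intersect(part$outer_ring, disk)))
})

test_that("a vanishing core fraction collapses the core toward the centroid", {
  disk <- mask_roi(oracle_disk_mask(c(32, 32), 15, c(64L, 64L)))
  part <- partition_zones(disk, fractions = c(0.05, 1.0))
  expect_lte(roi_size(part$core), 9)
  ctr <- roi_centroid(disk)
  d <- sqrt((part$core$coords[, 1] - ctr[1])^2 + (part$core$coords[, 2] - ctr[2])^2)
  expect_true(all(d <= 0.05 * 15 + 1))
})

test_that("partition contract holds on irregular shapes (property)", {
  set.seed(81)
  for (i in 1:10) {
    roi <- largest_component(random_blob_roi(shape = c(64L, 64L)))
    if (roi_size(roi) < 9) next
    part <- partition_zones(roi)
    expect_true(roi_equal(roi_union(part$core, part$middle), roi))
    expect_true(is_empty_roi(roi_intersect(part$core, part$middle)))
  }
  expect_error(partition_zones(pixel_roi(rbind(c(2, 2)), c(8, 8))), "small")
})

test_that("uniform channels give identical zone means, shell channels enrich the ring", {
  sc <- render_scene(scene_spec(noise_sigma = 0, seed = 1,
                                channel_profiles = list(cerulean = profile_uniform(100, 0),
                                                        tmr = profile_uniform(50))))
  roi <- largest_component(auto_threshold(get_channel(sc$image, "cerulean")))
  zp <- zone_profile(get_channel(sc$image, "tmr"), partition_zones(roi), "tmr")
  expect_equal(diff(range(zp$mean_intensity)), 0)
  # shell enrichment detected across seeded noisy scenes
  hits <- vapply(1:30, function(seed) {
    s <- shell_scene(seed)
    r <- largest_component(auto_threshold(get_channel(s$image, "cerulean")))
    z <- zone_profile(get_channel(s$image, "tmr"), partition_zones(r), "tmr")
    z$mean_intensity[z$zone == "outer_ring"] > z$mean_intensity[z$zone == "core"]
  }, TRUE)
  expect_true(all(hits))
})

test_that("excluded profiles leave the core at background", {
  sc <- render_scene(scene_spec(noise_sigma = 0, seed = 2, background_level = 10,
                                channel_profiles = list(cerulean = profile_uniform(100, 0),
                                                        tmr = profile_excluded(60))))
  roi <- largest_component(auto_threshold(get_channel(sc$image, "cerulean")))
  zp <- zone_profile(get_channel(sc$image, "tmr"), partition_zones(roi), "tmr")
  expect_equal(zp$mean_intensity[zp$zone == "core"], 10)
})

test_that("compartment intensities subtract background and preserve ordering", {
  # plain arithmetic
  ch <- matrix(20, 32, 32); ch[10:12, 10:12] <- 30
  comp <- list(inclusion = mask_roi(ch == 30), cytoplasm = mask_roi(ch == 20))
  out <- compartment_intensity(ch, comp, background = 20)
  expect_equal(unname(out["inclusion"]), 10)
  expect_equal(unname(out["cytoplasm"]), 0)
  expect_error(compartment_intensity(ch, list(inclusion = comp$inclusion)),
               "cytoplasm")
  # RNA-style scene: background < inclusion < cytoplasm
  sc <- render_scene(scene_spec(noise_sigma = 2, seed = 3, background_level = 10,
                                channel_profiles = list(cerulean = profile_uniform(100, 0),
                                                        rna = profile_uniform(20, 60))))
  roi <- largest_component(auto_threshold(get_channel(sc$image, "cerulean")))
  cyto <- roi_subtract(sc$truth$cell_roi, scale_roi(roi, 1.2))
  rna <- get_channel(sc$image, "rna")
  bg_roi <- circular_roi(c(8, 8), 5, dim(rna))
  out2 <- compartment_intensity(rna, list(inclusion = roi, cytoplasm = cyto), bg_roi)
  expect_gt(out2["inclusion"], 0)
  expect_gt(out2["cytoplasm"], out2["inclusion"])
})

test_that("EU-free control scenes read ~zero after background subtraction", {
  sc <- render_scene(scene_spec(noise_sigma = 0, seed = 4, background_level = 10,
                                channel_profiles = list(cerulean = profile_uniform(100, 0),
                                                        rna = profile_uniform(0, 0))))
  roi <- largest_component(auto_threshold(get_channel(sc$image, "cerulean")))
  cyto <- roi_subtract(sc$truth$cell_roi, scale_roi(roi, 1.2))
  out <- compartment_intensity(get_channel(sc$image, "rna"),
                               list(inclusion = roi, cytoplasm = cyto),
                               background = 10)
  expect_equal(unname(out["inclusion"]), 0)
})

test_that("OLS regression is exact on a noiseless line and matches normal equations", {
  x <- c(1, 2, 3, 4, 5)
  # an exact line triggers R's perfect-fit note; the fit itself is the point
  fit <- suppressWarnings(fit_regression(x, 2 * x + 1))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_regression(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_regression(1:2, 1:2), "3")
  set.seed(91)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    xx <- stats::rnorm(n); yy <- stats::rnorm(n)
    fit <- fit_regression(xx, yy)
    oracle <- unname(oracle_ols(xx, yy))
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-9)
    expect_equal(fit$slope, oracle[2], tolerance = 1e-9)
  }
})

test_that("slope CI covers zero at nominal rate under a null generator", {
  set.seed(92)
  covered <- vapply(1:100, function(i) {
    x <- stats::rnorm(200)
    y <- stats::rnorm(200)  # independent of x
    ci <- fit_regression(x, y)$slope_ci95
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.90)
})

test_that("a negative association yields a negative fitted slope", {
  set.seed(93)
  ratio <- stats::runif(60, 0.1, 0.6)
  cyto_eu <- 100 - 80 * ratio + stats::rnorm(60, 0, 5)
  expect_lt(fit_regression(ratio, cyto_eu)$slope, 0)
})
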