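test_that("noiseless uniform inclusion reads exactly background + level", {
  sc <- render_scene(scene_spec(noise_sigma = 0, background_level = 10,
                                channel_profiles = list(cerulean = profile_uniform(100, 0))))
  ch <- get_channel(sc$image, "cerulean")
  vals <- ch[sc$truth$inclusion_roi$coords]
  expect_true(all(vals == 110))
  # outside the cell only background remains
  outside <- ch[1, 1]
  expect_identical(outside, 10)
})

test_that("coat profile confines signal to the analytic outer annulus", {
  shape <- c(128L, 128L)
  sc <- render_scene(scene_spec(
    image_shape = shape, inclusion_radius = 20, noise_sigma = 0,
    background_level = 0,
    channel_profiles = list(antibody = profile_coat(0, 200, 5))
  ))
  ab <- get_channel(sc$image, "antibody")
  disk <- oracle_disk_mask(c(64, 64), 20, shape)
  inner <- oracle_disk_mask(c(64, 64), 15, shape)
  annulus <- disk & !inner
  expect_true(all(ab[annulus] == 200))
  expect_true(all(ab[!annulus] == 0))
})

test_that("rendering is deterministic for a fixed seed", {
  spec <- scene_spec(noise_sigma = 8, seed = 42,
                     channel_profiles = list(cerulean = profile_uniform(100, 0),
                                             tmr = profile_uniform(50)))
  s1 <- render_scene(spec); s2 <- render_scene(spec)
  expect_identical(s1$image$channels, s2$image$channels)
  f1 <- simulate_frap(frap_spec(0.5, noise_sigma = 5, seed = 9))
  f2 <- simulate_frap(frap_spec(0.5, noise_sigma = 5, seed = 9))
  expect_identical(lapply(f1$frames, function(f) f$channels),
                   lapply(f2$frames, function(f) f$channels))
  p1 <- simulate_population(population_spec(500, seed = 3))
  p2 <- simulate_population(population_spec(500, seed = 3))
  expect_identical(p1, p2)
})

test_that("changing one channel's profile leaves other channels untouched", {
  base <- list(cerulean = profile_uniform(100, 0), tmr = profile_uniform(50))
  alt <- list(cerulean = profile_uniform(100, 0), tmr = profile_shell(5, 80, 0.8))
  s1 <- render_scene(scene_spec(channel_profiles = base, noise_sigma = 6, seed = 4))
  s2 <- render_scene(scene_spec(channel_profiles = alt, noise_sigma = 6, seed = 4))
  expect_identical(get_channel(s1$image, "cerulean"), get_channel(s2$image, "cerulean"))
  expect_false(identical(get_channel(s1$image, "tmr"), get_channel(s2$image, "tmr")))
})

test_that("rasterized disks are within 2% of their analytic area for r >= 10", {
  for (r in c(10, 15, 20, 30)) {
    sc <- render_scene(scene_spec(inclusion_radius = r, noise_sigma = 0))
    expect_lt(abs(roi_size(sc$truth$inclusion_roi) - pi * r^2) / (pi * r^2), 0.02)
  }
})

test_that("invalid geometry is rejected", {
  expect_error(scene_spec(cell_center = c(64, 64), cell_radius = 30,
                          inclusion_center = c(90, 90), inclusion_radius = 10),
               "geometry")
  expect_error(scene_spec(image_shape = c(64, 64), cell_center = c(32, 32),
                          cell_radius = 40), "geometry")
})

test_that("FRAP kinetics honor the immobile limit and the halftime definition", {
  # immobile, noiseless: the bleached-half mean never moves post-bleach
  fs0 <- simulate_frap(frap_spec(mobile_fraction = 0, noise_sigma = 0))
  tr <- fs0$truth$trace
  post <- tr$time >= 0
  expect_equal(diff(range(tr$bleached[post])), 0)
  expect_equal(sum(post), 21L)
  # fully mobile: at t = halftime exactly half of the bleached amount is back
  fs1 <- simulate_frap(frap_spec(mobile_fraction = 1, recovery_halftime = 5,
                                 noise_sigma = 0))
  tr1 <- fs1$truth$trace
  pre <- tr1$bleached[tr1$time < 0]
  at0 <- tr1$bleached[tr1$time == 0]
  ath <- tr1$bleached[tr1$time == 5]
  expect_equal((ath - at0) / (pre - at0), 0.5, tolerance = 1e-12)
  # the unbleached half is untouched
  expect_equal(diff(range(tr1$unbleached)), 0)
})

test_that("a null modifier leaves the inclusion fraction flat across TMR (chi-square)", {
  ev <- simulate_population(population_spec(50000, logistic_beta_modifier = 0,
                                            seed = 101))
  q <- cut(log(ev$tmr_area), breaks = stats::quantile(log(ev$tmr_area),
                                                      0:4 / 4),
           include.lowest = TRUE)
  tab <- table(q, ev$true_inclusion)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("stall-reporter ratios recover the specified efficiency", {
  # no stall: median ratio near 1 (small multiplicative noise only)
  ev0 <- simulate_population(population_spec(20000, stall_efficiency = 0, seed = 7))
  expect_lt(abs(stats::median(ev0$mcherry_area / ev0$gfp_area) - 1), 0.02)
  # 50% stall at n = 50,000: median within 2% of 0.5
  ev5 <- simulate_population(population_spec(50000, stall_efficiency = 0.5, seed = 8))
  expect_lt(abs(stats::median(ev5$mcherry_area / ev5$gfp_area) - 0.5), 0.01)
  # logistic probabilities are proper probabilities
  p <- attr(ev5, "inclusion_prob")
  expect_true(all(p > 0 & p < 1))
})

test_that("scene and FRAP series survive a TIFF round trip", {
  sc <- render_scene(scene_spec(noise_sigma = 3, seed = 11,
                                channel_profiles = list(cerulean = profile_uniform(100, 0),
                                                        flash = profile_uniform(40, 0))))
  tf <- tempfile(fileext = ".tiff")
  write_scene(sc, tf)
  back <- read_image_tiff(tf)
  expect_identical(names(back$channels), c("cerulean", "flash"))
  # 16-bit quantization: intensities agree to the scale step
  expect_lt(max(abs(back$channels$cerulean - get_channel(sc$image, "cerulean"))), 1)
  fs <- simulate_frap(frap_spec(0.3, noise_sigma = 2, seed = 12))
  tf2 <- tempfile(fileext = ".tiff")
  write_frap_series(fs, tf2)
  back2 <- read_frap_series(tf2)
  expect_equal(back2$times, fs$times)
  expect_equal(length(back2$frames), length(fs$frames))
  expect_lt(max(abs(get_channel(back2$frames[[5]], "fusion") -
                    get_channel(fs$frames[[5]], "fusion"))), 1)
})
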