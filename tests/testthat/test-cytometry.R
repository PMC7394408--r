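gate_calibration <- function(n = 4000, seed_neg = 201, seed_pos = 202, ...) {
  neg <- simulate_population(population_spec(n, seed = seed_neg, ...))
  pos <- simulate_population(population_spec(n, seed = seed_pos, ...))
  list(negative = neg[!neg$true_inclusion, ][1:1000, ],
       positive = pos[pos$true_inclusion, ][1:1000, ])
}

test_that("the pulse-shape gate separates shifted populations and is deterministic", {
  ev <- simulate_population(population_spec(10000, seed = 200))
  calib <- gate_calibration()
  f1 <- pulsa_gate(ev, calib)
  expect_gte(mean(f1 == ev$true_inclusion), 0.95)
  f2 <- pulsa_gate(ev, calib)
  expect_identical(as.logical(f1), as.logical(f2))
  expect_gt(attr(f1, "separation"), 1)
})

test_that("a null pulse-shape difference gives chance accuracy and a warning", {
  ev <- simulate_population(population_spec(5000, pulse_width_shift = 0,
                                            pulse_height_shift = 0, seed = 210))
  calib <- gate_calibration(pulse_width_shift = 0, pulse_height_shift = 0,
                            seed_neg = 211, seed_pos = 212)
  expect_warning(flags <- pulsa_gate(ev, calib), "separable")
  expect_lt(abs(mean(flags == ev$true_inclusion) - 0.5), 0.1)
})

test_that("identical calibration populations are rejected", {
  ev <- simulate_population(population_spec(500, seed = 220))
  same <- simulate_population(population_spec(500, seed = 221))
  expect_error(pulsa_gate(ev, list(negative = same, positive = same)),
               "degenerate")
  expect_error(pulsa_gate(ev, list(negative = same[1:50, ], positive = same)),
               "100")
})

test_that("log bin edges follow the closed form over a known range", {
  ev <- data.frame(event_id = 1:2, construct = "c",
                   cerulean_area = c(1, 1e4), cerulean_height = 1,
                   cerulean_width = 1, tmr_area = c(0, 0))
  grid <- make_bins(ev, tmr_floor = 1)
  ratios <- grid$cerulean_edges[-1] / grid$cerulean_edges[-21]
  expect_equal(ratios, rep(10^0.2, 20), tolerance = 1e-9)
})

test_that("TMR categories honor the floor, including the all-none case", {
  ev <- data.frame(event_id = 1:100, construct = "c",
                   cerulean_area = exp(seq(log(10), log(1e4), length.out = 100)),
                   cerulean_height = 1, cerulean_width = 1,
                   tmr_area = rep(0.5, 100))
  grid <- make_bins(ev, tmr_floor = 10)
  expect_null(grid$tmr$c$edges)
  bg <- inclusion_fraction(ev, rep(FALSE, 100), grid)
  expect_equal(sum(bg$c$counts[, "none"]), 100L)
  expect_equal(sum(bg$c$counts[, c("low", "medium", "high")]), 0L)
})

test_that("an event exactly on an interior edge lands in the higher bin", {
  base <- data.frame(event_id = 1:2, construct = "c",
                     cerulean_area = c(1, 1e4), cerulean_height = 1,
                     cerulean_width = 1, tmr_area = 0)
  grid <- make_bins(base, tmr_floor = 1)
  probe <- data.frame(event_id = 1L, construct = "c",
                      cerulean_area = grid$cerulean_edges[3],
                      cerulean_height = 1, cerulean_width = 1, tmr_area = 0)
  bg <- inclusion_fraction(probe, TRUE, grid)
  expect_equal(unname(bg$c$counts[3, "none"]), 1L)
  expect_equal(sum(bg$c$counts), 1L)
})

test_that("binning conserves events and is invariant to row permutation", {
  ev <- simulate_population(population_spec(20000, seed = 230))
  grid <- make_bins(ev)
  bg <- inclusion_fraction(ev, ev$true_inclusion, grid)
  expect_equal(sum(bg[[1]]$counts), nrow(ev))
  set.seed(231)
  perm <- sample(nrow(ev))
  bg2 <- inclusion_fraction(ev[perm, ], ev$true_inclusion[perm], grid)
  expect_identical(bg[[1]]$counts, bg2[[1]]$counts)
  expect_identical(bg[[1]]$n_inclusion, bg2[[1]]$n_inclusion)
  # fraction arithmetic
  expect_equal(bg[[1]]$fraction[!is.na(bg[[1]]$fraction)],
               (bg[[1]]$n_inclusion / bg[[1]]$counts)[!is.na(bg[[1]]$fraction)])
})

test_that("non-positive intensities are excluded and reported in QC", {
  ev <- simulate_population(population_spec(500, seed = 232))
  ev$cerulean_area[1:5] <- 0
  grid <- make_bins(ev)
  bg <- inclusion_fraction(ev, ev$true_inclusion, grid)
  expect_equal(attr(bg, "qc")$n_excluded_nonpositive, 5L)
  expect_equal(sum(bg[[1]]$counts), 495L)
})

test_that("a suppressing modifier yields non-increasing fractions across TMR", {
  ev <- simulate_population(population_spec(50000, logistic_beta_modifier = -0.8,
                                            seed = 240))
  grid <- make_bins(ev)
  bg <- inclusion_fraction(ev, ev$true_inclusion, grid)
  fr <- bg[[1]]$fraction; n <- bg[[1]]$counts; ni <- bg[[1]]$n_inclusion
  for (b in seq_len(nrow(fr))) {
    for (k in 1:3) {
      n1 <- n[b, k]; n2 <- n[b, k + 1]
      if (n1 < 20 || n2 < 20) next
      pool <- (ni[b, k] + ni[b, k + 1]) / (n1 + n2)
      se <- sqrt(max(pool * (1 - pool), 1e-12) * (1 / n1 + 1 / n2))
      expect_lte(fr[b, k + 1] - fr[b, k], 3 * se + 1e-12)
    }
  }
})

test_that("stall ratios summarize per construct with the expected ordering", {
  evs <- do.call(rbind, lapply(list(
    list(eff = 0.9, name = "20K"), list(eff = 0, name = "control"),
    list(eff = 0.02, name = "25Q"), list(eff = 0.05, name = "97Q")
  ), function(p) {
    simulate_population(population_spec(5000, stall_efficiency = p$eff,
                                        construct = p$name,
                                        seed = 300 + round(100 * p$eff)))
  }))
  ss <- stall_ratios(evs)
  med <- setNames(ss$summary$median_ratio, ss$summary$construct)
  expect_lt(med["20K"], 0.2)
  expect_gt(min(med[c("control", "25Q", "97Q")]), 0.9)
  expect_lt(max(abs(med[c("25Q", "97Q")] - med["control"])), 0.1)
  # mcherry == gfp gives median exactly 1
  eq <- data.frame(event_id = 1:10, construct = "eq", cerulean_area = 1,
                   cerulean_height = 1, cerulean_width = 1, tmr_area = 0,
                   gfp_area = 2:11, mcherry_area = 2:11)
  expect_equal(stall_ratios(eq)$summary$median_ratio, 1)
  # floor exclusion
  fl <- eq; fl$gfp_area <- c(rep(0.5, 4), 2:7)
  out <- stall_ratios(fl, gfp_floor = 1)
  expect_equal(out$summary$n, 6L)
  expect_equal(out$summary$n_excluded, 4L)
  expect_error(stall_ratios(fl, gfp_floor = 100), "floor")
})
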