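test_that("peak_height is max-in-region minus min-in-clockwise-flank", {
  pr <- profile_from_loess(c(0, 0, 0.5, 0.8, 0.5, 0, 0))
  # region covers the middle three windows, flank the last two
  reg <- peak_region(200, 500, flank_width = 2)
  expect_equal(peak_height(pr, reg), 0.8)

  flat <- profile_from_loess(rep(0, 7))
  expect_equal(peak_height(flat, reg), 0)

  # invariant to adding a constant to the whole curve
  shifted <- profile_from_loess(c(0, 0, 0.5, 0.8, 0.5, 0, 0) + 2.3)
  expect_equal(peak_height(shifted, reg), 0.8)

  expect_error(peak_region(500, 200), "left < right")
})

test_that("ter_peak_increase subtracts pre from post and is antisymmetric", {
  pre <- profile_from_loess(c(0, 0, 0.3, 0.5, 0.3, 0, 0))
  post <- profile_from_loess(c(0, 0, 0.5, 0.8, 0.5, 0, 0))
  reg <- peak_region(200, 500, flank_width = 2)
  expect_equal(ter_peak_increase(pre, post, reg), 0.3)
  expect_equal(ter_peak_increase(pre, pre, reg), 0)
  expect_equal(ter_peak_increase(post, pre, reg),
               -ter_peak_increase(pre, post, reg))
  bad <- profile_from_loess(rep(0, 9))
  expect_error(ter_peak_increase(pre, bad, reg), "different grids")
})

test_that("peak height grows with the re-replication gain", {
  m <- default_map()
  reg <- default_region(m, flank_width = 100)
  grid <- build_grid(m$length, 1000)
  heights <- sapply(c(0, 1, 3), function(gain) {
    mean(vapply(1:20, function(rep) {
      cfg <- sim_config(c_over_tau = 1, rldr_rate = 10, spc = TRUE,
                        rereplication_prob = 0.5, rereplication_gain = gain,
                        n_cells = 1500, seed = 5000 + 37 * rep + gain)
      p <- expected_copy_profile(cfg, m, 1000)
      ctl <- sample_counts(rep(1, 1000), 100, grid, seed = 6000 + rep + gain,
                           condition = "stationary_control")
      s <- sample_counts(p, 100, grid, seed = 7000 + rep + gain)
      peak_height(assemble_profile(s, ctl), reg)
    }, numeric(1)))
  })
  expect_true(all(diff(heights) > 0))
})

test_that("marker_ratio estimates locus copy ratios from counts or loess", {
  m <- default_map()
  grid_n <- 2000
  grid <- build_grid(m$length, grid_n)
  # flat profile: null ratio ~ 1
  tr <- sample_counts(rep(1, grid_n), 500, grid, seed = 11)
  expect_equal(marker_ratio(tr, "ydcM", "lepA", map = m, w = 2), 1,
               tolerance = 0.05)

  # injected ground-truth copy ratio 2.5 recovered within 10% (50 replicates)
  centers <- (grid$start + grid$end) / 2
  # plateau wider than the loess bandwidth so the smoothed variant is
  # comparable to the raw-count estimate
  expected <- rep(1, grid_n)
  expected[abs(centers - m$loci$ydcM$position) < 2.5e5] <- 2.5
  est <- vapply(1:50, function(s) {
    trs <- sample_counts(expected, 500, grid, seed = 800 + s)
    marker_ratio(trs, "ydcM", "lepA", map = m, w = 2)
  }, numeric(1))
  expect_lt(abs(mean(est) - 2.5) / 2.5, 0.03)
  expect_gt(mean(abs(est - 2.5) / 2.5 < 0.10), 0.9)

  expect_error(marker_ratio(tr, "ydcM", "nosuch", map = m), "not found")
  expect_error(marker_ratio(tr, "ydcM", "lepA"), "map is required")

  # profile-based variant works on 2^loess
  ctl <- sample_counts(rep(1, grid_n), 500, grid, seed = 12,
                       condition = "stationary_control")
  pr <- assemble_profile(sample_counts(expected, 500, grid, seed = 13), ctl)
  expect_equal(marker_ratio(pr, "ydcM", "lepA", map = m), 2.5,
               tolerance = 0.15)
})

test_that("region_copy_ratio recovers injected amplification folds", {
  m <- default_map()
  grid_n <- 2000
  grid <- build_grid(m$length, grid_n)
  amp <- c(2990000, 3240000)

  tr0 <- sample_counts(rep(1, grid_n), 500, grid, seed = 21)
  expect_equal(region_copy_ratio(tr0, amp, "lepA", map = m, w = 2), 1,
               tolerance = 0.05)

  for (fold in c(1.3, 4.9)) {
    cfg <- sim_config(spc = TRUE, rldr_rate = 0,
                      amplification = list(region = amp, fold = fold))
    p <- expected_copy_profile(cfg, m, grid_n)
    tr <- sample_counts(p, 500, grid, seed = round(100 * fold))
    expect_equal(region_copy_ratio(tr, amp, "lepA", map = m, w = 2), fold,
                 tolerance = 0.1 * fold)
  }
})

test_that("flatness_test separates tus-null from trap-proficient profiles", {
  reg <- default_region(flank_width = 100)
  tus <- sim_scenario_pair("topA_topB_tus", seed = 301, grid_n = 1000,
                           n_cells = 2000)
  expect_true(flatness_test(tus$post, reg, control = tus$pre)$flat)

  tt <- sim_scenario_pair("topA_topB", seed = 302, grid_n = 1000,
                          n_cells = 2000)
  expect_false(flatness_test(tt$post, reg)$flat)

  zero <- profile_from_loess(rep(0, 500))
  z <- flatness_test(zero, peak_region(100, 200, flank_width = 10),
                     threshold = 0.05)
  expect_true(z$flat)
  expect_equal(z$score, 0)
})
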