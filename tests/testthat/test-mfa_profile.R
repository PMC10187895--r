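test_that("normalize_to_control computes library-size-scaled log2 ratios", {
  grid <- build_grid(300, 3)
  s <- coverage_track(c(10, 20, 30), grid)
  ctl <- coverage_track(c(10, 10, 10), grid, condition = "stationary_control")
  r <- normalize_to_control(s, ctl, pseudocount = 0)
  # (10/60)*(30/10) = 0.5, (20/60)*(30/10) = 1, (30/60)*(30/10) = 1.5
  expect_equal(r, log2(c(0.5, 1, 1.5)), tolerance = 1e-12)
  expect_equal(round(r, 3), c(-1, 0, 0.585))

  # identity: any track against itself is exactly zero
  set.seed(1)
  tr <- coverage_track(rpois(3, 20), grid)
  expect_equal(normalize_to_control(tr, tr), rep(0, 3))

  # pseudocount guards zero-count control windows
  ctl0 <- coverage_track(c(0, 10, 10), grid, condition = "stationary_control")
  expect_true(all(is.finite(normalize_to_control(s, ctl0, pseudocount = 0.5))))

  bad <- coverage_track(rep(1, 4), build_grid(300, 4))
  expect_error(normalize_to_control(s, bad), "different window grids")
})

test_that("library-size scaling removes global depth factors", {
  grid <- build_grid(5000, 50)
  set.seed(8)
  ctl <- coverage_track(rpois(50, 100), grid, condition = "stationary_control")
  s <- coverage_track(rpois(50, 80), grid)
  s3 <- coverage_track(s$counts * 3, grid)
  expect_equal(normalize_to_control(s, ctl, pseudocount = 0),
               normalize_to_control(s3, ctl, pseudocount = 0) -
                 0 * log2(3),  # ratios identical, no global shift
               tolerance = 1e-12)
})

test_that("loess_smooth reproduces constants and lines exactly", {
  x <- sort(runif(100, 0, 1000))
  expect_equal(loess_smooth(x, rep(3.5, 100), span = 0.3), rep(3.5, 100),
               tolerance = 1e-10)
  y <- 2 + 0.01 * x
  expect_equal(loess_smooth(x, y, span = 0.4), y, tolerance = 1e-8)
  expect_error(loess_smooth(x[1:5], y[1:5]), "too few points")
  expect_error(loess_smooth(x, y, span = 0.01), "span")
})

test_that("loess_smooth recovers a noisy sine wave", {
  set.seed(21)
  n <- 2000
  L <- 1e6
  x <- (seq_len(n) - 0.5) * (L / n)
  truth <- sin(2 * pi * x / L)
  y <- truth + rnorm(n, 0, 0.3)
  sm <- loess_smooth(x, y, span = 0.1, circular = TRUE, period = L)
  expect_lt(sqrt(mean((sm - truth)^2)), 0.1)
})

test_that("loess_smooth matches the brute-force weighted-least-squares oracle", {
  set.seed(4)
  n <- 150
  x <- sort(runif(n, 0, 1000))
  y <- cos(x / 100) + rnorm(n, 0, 0.2)
  for (span in c(0.3, 0.5, 1.0)) {
    expect_lt(max(abs(loess_smooth(x, y, span = span) -
                        loess_bruteforce(x, y, span = span))), 1e-6)
    expect_lt(max(abs(
      loess_smooth(x, y, span = span, circular = TRUE, period = 1000) -
        loess_bruteforce(x, y, span = span, circular = TRUE, period = 1000)
    )), 1e-6)
  }
})

test_that("circular smoothing leaves no edge artifact at the origin", {
  m <- default_map()
  grid_n <- 1000
  grid <- build_grid(m$length, grid_n)
  ctl <- sample_counts(rep(1, grid_n), 200, grid, seed = 61,
                       condition = "stationary_control")
  s <- sample_counts(rep(1, grid_n), 200, grid, seed = 62)
  pr <- assemble_profile(s, ctl)
  edge_jump <- abs(pr$loess[1] - pr$loess[grid_n])
  interior <- max(abs(diff(pr$loess)))
  expect_lte(edge_jump, 3 * interior)
})

test_that("assemble_profile places the curve maximum where replication says", {
  m <- default_map()
  # wild type: maximum at oriC
  wt <- sim_scenario_pair("wild_type", seed = 201, grid_n = 2000,
                          n_cells = 200)
  amax <- wt$pre$window_centers[which.max(wt$pre$loess)]
  expect_lt(abs(amax - m$oriC), 1.5e5)

  # topA topB under spectinomycin: maximum inside the innermost Ter interval
  tt <- sim_scenario_pair("topA_topB", seed = 202, grid_n = 2000,
                          n_cells = 4000)
  iv <- innermost_ter_interval(m)
  amax2 <- tt$post$window_centers[which.max(tt$post$loess)]
  expect_gt(amax2, iv["left"])
  expect_lt(amax2, iv["right"])

  # sample == control: flat zero profile
  grid <- build_grid(m$length, 500)
  tr <- sample_counts(rep(1, 500), 100, grid, seed = 9)
  ctl <- coverage_track(tr$counts, grid, condition = "stationary_control")
  pr <- assemble_profile(tr, ctl)
  expect_equal(pr$log2_ratio, rep(0, 500))
  expect_equal(pr$loess, rep(0, 500), tolerance = 1e-10)
})
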