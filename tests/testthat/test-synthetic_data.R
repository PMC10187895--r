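test_that("oriC component follows the exponential-culture marker-frequency form", {
  m <- toy_map()
  cfg <- sim_config(c_over_tau = 1, rldr_rate = 0)
  p <- expected_copy_profile(cfg, m, 1000)
  expect_equal(mean(p), 1, tolerance = 1e-9)
  # copy(oriC) / copy(antipodal terminus) = 2^(C/tau) = 2
  expect_equal(p[1] / min(p), 2, tolerance = 0.01)
  # terminus (fork meeting point) is antipodal to oriC on this symmetric map
  expect_equal(which.min(p), 500, tolerance = 2)

  # spectinomycin run-off: all oriC rounds completed, flat profile
  cfg_spc <- sim_config(c_over_tau = 1, rldr_rate = 0, spc = TRUE)
  expect_equal(expected_copy_profile(cfg_spc, m, 1000), rep(1, 1000))
})

test_that("tus deletion with dispersed RLDR yields a flattened profile", {
  cfg <- sim_config(c_over_tau = 0, rldr_rate = 5, tus = FALSE,
                    n_cells = 10000, seed = 99)
  p <- expected_copy_profile(cfg, default_map(), 1000)
  expect_lt(max(p) / min(p), 1.2)
})

test_that("RLDR forks are trapped only at barriers in blocking orientation", {
  m <- toy_map()
  # near-unbounded runs: every fork reaches a barrier if one can stop it
  cfg <- sim_config(rldr_rate = 3, rldr_run_mean = 1e9, n_cells = 300,
                    rereplication_prob = 1, rereplication_gain = 2, seed = 5)
  ev <- simulate_rldr_events(cfg, m)
  expect_gt(nrow(ev), 0)
  inside <- ev$origin > 4e5 & ev$origin < 6e5
  # origins inside [TerA, TerB] with efficiency-1 barriers: both forks trapped
  expect_true(all(ev$trapped_left[inside] == "TerA"))
  expect_true(all(ev$trapped_right[inside] == "TerB"))
  expect_equal(ev$left_end[inside], rep(4e5, sum(inside)))
  expect_equal(ev$right_end[inside], rep(6e5, sum(inside)))

  cfg_tus <- sim_config(rldr_rate = 3, rldr_run_mean = 1e9, n_cells = 300,
                        tus = FALSE, seed = 5)
  ev2 <- simulate_rldr_events(cfg_tus, m)
  expect_true(all(is.na(ev2$trapped_left)))
  expect_true(all(is.na(ev2$trapped_right)))
  expect_true(all(ev2$extra_copies == 0))

  cfg0 <- sim_config(rldr_rate = 0)
  expect_equal(nrow(simulate_rldr_events(cfg0, m)), 0L)
})

test_that("sample_counts draws Poisson read counts reproducibly", {
  grid <- build_grid(1e6, 10000)
  tr <- sample_counts(rep(1, 10000), depth = 100, grid, seed = 31)
  expect_gt(mean(tr$counts), 97)
  expect_lt(mean(tr$counts), 103)
  disp <- var(tr$counts) / mean(tr$counts)
  expect_gt(disp, 0.9)
  expect_lt(disp, 1.1)

  tr2 <- sample_counts(rep(1, 10000), depth = 100, grid, seed = 31)
  expect_identical(tr$counts, tr2$counts)

  exp0 <- c(0, 1, 0, 2, rep(1, 6))
  g10 <- build_grid(1000, 10)
  for (s in 1:5)
    expect_equal(sample_counts(exp0, 50, g10, seed = s)$counts[c(1, 3)],
                 c(0, 0))
  expect_error(sample_counts(rep(1, 10), -5, g10), "non-negative")
})

test_that("trapped re-replication elevates the innermost Ter interval", {
  m <- default_map()
  iv <- innermost_ter_interval(m)
  grid_n <- 1000
  grid <- build_grid(m$length, grid_n)
  centers <- (grid$start + grid$end) / 2
  in_ter <- centers >= iv["left"] & centers <= iv["right"]
  iw <- which(in_ter)
  flanks <- c(min(iw) - seq_len(100), max(iw) + seq_len(100))
  flanks <- (flanks - 1) %% grid_n + 1

  cfg <- sim_config(c_over_tau = 0, rldr_rate = 3, rereplication_prob = 0.5,
                    rereplication_gain = 70, n_cells = 4000, seed = 17)
  p <- expected_copy_profile(cfg, m, grid_n)
  expect_gt(mean(p[iw]), mean(p[flanks]))

  # without Tus the contrast vanishes (within Monte-Carlo error)
  diffs <- vapply(1:8, function(s) {
    cfgt <- sim_config(c_over_tau = 0, rldr_rate = 3, rereplication_prob = 0.5,
                       rereplication_gain = 70, tus = FALSE, n_cells = 2000,
                       seed = 1000 + s)
    pt <- expected_copy_profile(cfgt, m, grid_n)
    mean(pt[iw]) - mean(pt[flanks])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("spectinomycin removes the oriC gradient outside Ter", {
  m <- default_map()
  grid_n <- 2000
  centers <- (build_grid(m$length, grid_n)$start +
                build_grid(m$length, grid_n)$end) / 2
  iv <- innermost_ter_interval(m)
  # exclude the trap interval plus a run-length margin on each side
  excl <- centers >= iv["left"] - 5e5 & centers <= 2380000 + 5e5
  d_ori <- pmin((centers - m$oriC) %% m$length,
                (m$oriC - centers) %% m$length)

  # bursts are confined to the (excluded) trap interval; turn them off so
  # the regression sees only the dispersed-fork background. Fork runs are
  # kept short relative to the exclusion margin, otherwise the trap casts a
  # coverage shadow several run-lengths beyond Ter that tilts the fit.
  slope_of <- function(spc, seed) {
    cfg <- sim_config(c_over_tau = 1, rldr_rate = 3, rldr_run_mean = 1e5,
                      rereplication_prob = 0, rereplication_gain = 0,
                      spc = spc, n_cells = 40000, seed = seed)
    p <- expected_copy_profile(cfg, m, grid_n)
    unname(coef(lm(log2(p[!excl]) ~ d_ori[!excl]))[2])
  }
  s_log <- slope_of(FALSE, 11)
  s_spc <- slope_of(TRUE, 11)
  # log-phase gradient ~ -C/tau per replichore length; spc at least 10x flatter
  expect_lt(s_log, -2e-7)
  expect_lt(abs(s_spc), abs(s_log) / 10)
})

test_that("the inversion scenario relocates the expected-copy maximum", {
  m <- default_map()
  cfg <- make_scenario("topA_topB_inv", spc = TRUE, seed = 3, n_cells = 5000)
  p <- expected_copy_profile(cfg, m, 2000)
  centers <- (build_grid(m$length, 2000)$start +
                build_grid(m$length, 2000)$end) / 2
  minv <- apply_inversion(m, cfg$inversion[1], cfg$inversion[2])
  iv <- innermost_ter_interval(minv)
  amax <- centers[which.max(p)]
  expect_gt(amax, iv["left"])
  expect_lt(amax, iv["right"])
  # not in the original TerA-TerB interval
  iv0 <- innermost_ter_interval(m)
  expect_false(amax >= iv0["left"] && amax <= iv0["right"])
})

test_that("the generator is fully deterministic under a fixed seed", {
  m <- default_map()
  cfg <- make_scenario("topA_topB", seed = 123, n_cells = 500)
  p1 <- expected_copy_profile(cfg, m, 500)
  p2 <- expected_copy_profile(cfg, m, 500)
  expect_identical(p1, p2)
  grid <- build_grid(m$length, 500)
  t1 <- sample_counts(p1, 50, grid, seed = 77)
  t2 <- sample_counts(p2, 50, grid, seed = 77)
  expect_identical(t1, t2)
})

test_that("scenario presets encode the strain contrasts", {
  wt <- make_scenario("wild_type")
  expect_equal(wt$rldr_rate, 0)
  expect_null(wt$amplification)

  tt <- make_scenario("topA_topB")
  expect_gt(tt$rldr_rate, 0)
  expect_gt(tt$rereplication_gain, 0)
  expect_false(is.null(tt$amplification))

  tus <- make_scenario("topA_topB_tus")
  expect_false(tus$tus)
  tus$tus <- TRUE
  expect_equal(tus, tt)

  spc <- make_scenario("topA_topB", spc = TRUE)
  expect_true(spc$spc)
  expect_equal(spc$rldr_rate, 2 * tt$rldr_rate)

  expect_error(make_scenario("nonsense"), "unknown scenario")
})

test_that("fixtures and configs serialize losslessly", {
  grid <- build_grid(300, 3)
  tr <- coverage_track(c(2, 0, 1), grid)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_fixture(tr, sam, format = "sam_lite")
  expect_equal(sum(!startsWith(readLines(sam), "@")), 3L)
  expect_identical(bin_reads(filter_mapq(read_sam(sam), 10), grid)$counts,
                   tr$counts)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fixture(tr, tsv, format = "tsv")
  expect_equal(read_counts_tsv(tsv)$counts, tr$counts)

  cfg <- make_scenario("topA_topB_inv", spc = TRUE, seed = 42)
  js <- withr::local_tempfile(fileext = ".json")
  write_config_json(cfg, js)
  expect_equal(read_config_json(js), cfg)
})
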