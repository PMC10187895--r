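# Shared fixtures: all tests run on toy maps built in code.

# 1 Mb toy chromosome: oriC at 0, innermost trap [TerA 400k, TerB 600k]
toy_map <- function() {
  build_map(
    1e6, oriC = 0,
    ter_sites = list(ter_site("TerA", 4e5, "cw"), ter_site("TerB", 6e5, "ccw")),
    loci = list(locus("ydcM", 5.2e5), locus("lepA", 8e5))
  )
}

# Brute-force local-linear tricube fit, written independently of
# loess_smooth: per-point distance sort, explicit neighbour pick, lm() with
# weights. Used as the oracle for smoothing equivalence.
loess_bruteforce <- function(x, y, span, circular = FALSE, period = NULL) {
  n <- length(x)
  k <- ceiling(span * n)
  if (circular) {
    npad <- ceiling(k / 2)
    xp <- c(x[(n - npad + 1):n] - period, x, x[1:npad] + period)
    yp <- c(y[(n - npad + 1):n], y, y[1:npad])
  } else {
    xp <- x
    yp <- y
  }
  vapply(seq_len(n), function(i) {
    d <- abs(xp - x[i])
    nb <- order(d)[seq_len(k)]
    dmax <- max(d[nb])
    w <- if (dmax == 0) rep(1, k) else (1 - pmin(d[nb] / dmax, 1)^3)^3
    df <- data.frame(xx = xp[nb], yy = yp[nb])
    fit <- stats::lm(yy ~ xx, data = df, weights = w)
    unname(stats::predict(fit, data.frame(xx = x[i])))
  }, numeric(1))
}

# Simulate a matched (sample, control, profiles) set for a scenario on a
# reduced grid; seeds derived deterministically from `seed`.
sim_scenario_pair <- function(name, seed, grid_n = 2000, n_cells = 2000,
                              depth = 100, map = default_map()) {
  grid <- build_grid(map$length, grid_n)
  cfg_pre <- make_scenario(name, spc = FALSE, seed = seed, n_cells = n_cells,
                           depth = depth)
  cfg_post <- make_scenario(name, spc = TRUE, seed = seed + 100L,
                            n_cells = n_cells, depth = depth)
  ctl <- sample_counts(rep(1, grid_n), depth, grid, seed = seed + 200L,
                       condition = "stationary_control", sample_id = "ctl")
  pre <- sample_counts(expected_copy_profile(cfg_pre, map, grid_n), depth,
                       grid, seed = seed + 300L)
  post <- sample_counts(expected_copy_profile(cfg_post, map, grid_n), depth,
                        grid, seed = seed + 400L, condition = "spc")
  list(pre = assemble_profile(pre, ctl), post = assemble_profile(post, ctl),
       track_pre = pre, track_post = post, control = ctl)
}

default_region <- function(map = default_map(), flank_width = 200) {
  iv <- innermost_ter_interval(map)
  peak_region(iv["left"], iv["right"], flank_width = flank_width)
}

# Minimal mfa_profile constructed directly from a loess vector (for the
# closed-form peak statistic tests).
profile_from_loess <- function(loess_vals, window_bp = 100) {
  n <- length(loess_vals)
  grid <- build_grid(n * window_bp, n)
  structure(
    list(window_centers = (grid$start + grid$end) / 2,
         log2_ratio = loess_vals, loess = loess_vals, span = 0.1,
         grid = grid, length = n * window_bp, sample_id = "constructed"),
    class = "mfa_profile"
  )
}
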