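#' Simulation configuration for bacterial replication profiles
#'
#' Collects every generative knob of the simulator. The expected copy-number
#' profile of an exponentially growing culture is composed of (i) an oriC
#' component `2^(c_over_tau * (1 - m(x)))`, where `m(x)` is the fraction of
#' the replication period at which position `x` is replicated by the fork
#' serving it (flat when `spc = TRUE`, since after spectinomycin run-off all
#' oriC rounds have completed); (ii) an R-loop-dependent replication (RLDR)
#' component: stochastic unidirectional fork pairs fired from weak origins
#' uniformly distributed on the chromosome, trapped at polar Ter/Tus
#' barriers, with re-replication bursts of the trapped interval; and (iii) a
#' multiplicative gene-amplification block.
#'
#' @param c_over_tau Replication period over doubling time (C/tau, >= 0);
#'   sets the origin-to-terminus copy gradient `2^(C/tau)`.
#' @param rldr_rate Expected RLDR initiation events per cell per (observed)
#'   cell cycle.
#' @param rldr_run_mean Mean unidirectional fork run length in bp when not
#'   arrested (exponentially distributed).
#' @param rereplication_prob Probability that a fully Tus-trapped fork pair
#'   triggers a re-replication burst.
#' @param rereplication_gain Mean number of extra copies of the trapped
#'   interval per burst (geometric).
#' @param spc Spectinomycin run-off mode: oriC gradient removed, RLDR still
#'   active.
#' @param tus Is Tus present? `FALSE` removes all fork barriers.
#' @param inversion Optional `c(a, b)` bp interval to invert (see
#'   [apply_inversion()]).
#' @param amplification Optional `list(region = c(a, b), fold = f)` gene
#'   amplification block.
#' @param n_cells Number of simulated cells in the Monte-Carlo average.
#' @param depth Mean reads per window in the stationary-phase control.
#' @param seed RNG seed for all stochastic stages.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(c_over_tau = 1, rldr_rate = 0, rldr_run_mean = 5e5,
                       rereplication_prob = 0.5, rereplication_gain = 3,
                       spc = FALSE, tus = TRUE, inversion = NULL,
                       amplification = NULL, n_cells = 2000, depth = 100,
                       seed = 1L) {
  if (c_over_tau < 0 || rldr_rate < 0 || rldr_run_mean < 0 ||
      rereplication_gain < 0)
    stop("rates and means must be >= 0")
  if (rereplication_prob < 0 || rereplication_prob > 1)
    stop("rereplication_prob must be in [0, 1]")
  if (depth <= 0) stop("depth must be > 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(inversion) &&
      (length(inversion) != 2L || inversion[1] >= inversion[2]))
    stop("inversion must be c(a, b) with a < b")
  if (!is.null(amplification)) {
    if (!is.list(amplification) ||
        !all(c("region", "fold") %in% names(amplification)) ||
        length(amplification$region) != 2L || amplification$fold <= 0)
      stop("amplification must be list(region = c(a, b), fold > 0)")
  }
  structure(
    list(c_over_tau = c_over_tau, rldr_rate = rldr_rate,
         rldr_run_mean = rldr_run_mean,
         rereplication_prob = rereplication_prob,
         rereplication_gain = rereplication_gain, spc = spc, tus = tus,
         inversion = inversion, amplification = amplification,
         n_cells = as.integer(n_cells), depth = depth,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> C/tau=%.2f rldr_rate=%.2f run=%.0fkb burst(p=%.2f, gain=%.1f)\n",
    x$c_over_tau, x$rldr_rate, x$rldr_run_mean / 1e3,
    x$rereplication_prob, x$rereplication_gain))
  cat(sprintf("  spc=%s tus=%s inversion=%s amp=%s n_cells=%d depth=%g seed=%d\n",
              x$spc, x$tus,
              if (is.null(x$inversion)) "none" else
                paste0("[", x$inversion[1], ",", x$inversion[2], ")"),
              if (is.null(x$amplification)) "none" else
                sprintf("%.2fx", x$amplification$fold),
              x$n_cells, x$depth, x$seed))
  invisible(x)
}

#' Preset simulation scenarios
#'
#' Named parameter sets mirroring the strain classes a topoisomerase-mutant
#' MFA study contrasts: `wild_type` (oriC replication only), `topA` (modest
#' RLDR and a weak parC-parE amplification), `topA_topB` (strong RLDR with
#' Tus-trapping re-replication bursts and a strong parC-parE amplification),
#' `topA_topB_tus` (same but Tus absent: no trapping, flattened profile) and
#' `topA_topB_inv` (same as `topA_topB` with the IN(1.52-1.84)-like inversion
#' that repositions TerB and relocates the trap to the TerB-TerG interval).
#'
#' With `spc = TRUE` the preset doubles `rldr_rate`: the two-hour
#' spectinomycin run-off lets R-loop-dependent synthesis continue while oriC
#' initiations stop, and that extra accumulation is absorbed into the rate
#' knob rather than modeled in time.
#'
#' @param name One of `wild_type`, `topA`, `topA_topB`, `topA_topB_tus`,
#'   `topA_topB_inv`.
#' @param spc Spectinomycin run-off mode.
#' @param seed RNG seed.
#' @param n_cells,depth Override the preset Monte-Carlo size / sequencing
#'   depth.
#' @return A [sim_config()].
#' @export
make_scenario <- function(name, spc = FALSE, seed = 1L, n_cells = 2000,
                          depth = 100) {
  amp_region <- c(2990000, 3240000)
  base <- switch(
    name,
    wild_type = list(rldr_rate = 0, prob = 0, gain = 0, tus = TRUE,
                     inv = NULL, amp = NULL),
    topA = list(rldr_rate = 0.5, prob = 0.5, gain = 70, tus = TRUE,
                inv = NULL,
                amp = list(region = amp_region, fold = 1.15)),
    topA_topB = list(rldr_rate = 3, prob = 0.5, gain = 70, tus = TRUE,
                     inv = NULL,
                     amp = list(region = amp_region, fold = 2)),
    topA_topB_tus = list(rldr_rate = 3, prob = 0.5, gain = 70, tus = FALSE,
                         inv = NULL,
                         amp = list(region = amp_region, fold = 2)),
    topA_topB_inv = list(rldr_rate = 3, prob = 0.5, gain = 70, tus = TRUE,
                         inv = c(1520000, 1840000),
                         amp = list(region = amp_region, fold = 2)),
    stop("unknown scenario: '", name, "'")
  )
  sim_config(
    c_over_tau = 1,
    rldr_rate = base$rldr_rate * if (spc) 2 else 1,
    rldr_run_mean = 5e5,
    rereplication_prob = base$prob,
    rereplication_gain = base$gain,
    spc = spc, tus = base$tus, inversion = base$inv, amplification = base$amp,
    n_cells = n_cells, depth = depth, seed = seed
  )
}

# Replication time (in fork-travel bp) of each position for the two oriC
# forks on a circular chromosome with polar barriers. Barriers are applied
# deterministically at full efficiency only; partial-efficiency sites matter
# for the stochastic RLDR forks, not for the mean oriC component.
ori_fork_times <- function(map, x, tus = TRUE) {
  L <- map$length
  d_cw <- (x - map$oriC) %% L
  d_ccw <- (map$oriC - x) %% L
  a_cw <- Inf
  a_ccw <- Inf
  if (tus && length(map$ter_sites)) {
    pos <- vapply(map$ter_sites, `[[`, numeric(1), "position")
    blk <- vapply(map$ter_sites, `[[`, character(1), "blocks")
    eff <- vapply(map$ter_sites, `[[`, numeric(1), "efficiency")
    stop_cw <- pos[blk == "ccw" & eff >= 1]  # arrest clockwise-moving forks
    stop_ccw <- pos[blk == "cw" & eff >= 1]
    if (length(stop_cw)) a_cw <- min((stop_cw - map$oriC) %% L)
    if (length(stop_ccw)) a_ccw <- min((map$oriC - stop_ccw) %% L)
  }
  t_cw <- ifelse(d_cw <= a_cw, d_cw, Inf)
  t_ccw <- ifelse(d_ccw <= a_ccw, d_ccw, Inf)
  t <- pmin(t_cw, t_ccw)
  if (any(!is.finite(t))) {
    # both forks arrested before meeting: the residual gap is completed last
    t[!is.finite(t)] <- max(t[is.finite(t)])
  }
  t
}

#' Simulate R-loop-dependent replication events
#'
#' Draws `Poisson(rldr_rate * n_cells)` initiation events from origins
#' uniform on the chromosome. Each event fires two unidirectional forks that
#' run an exponential distance (mean `rldr_run_mean`) or stop earlier at the
#' first Ter/Tus barrier in blocking orientation, each encountered barrier
#' arresting with probability equal to its efficiency. When both forks are
#' trapped and Tus is present, the event triggers, with probability
#' `rereplication_prob`, a re-replication burst adding a geometric number
#' (mean `rereplication_gain`) of extra copies of the trapped interval.
#'
#' @param config A [sim_config()].
#' @param map A `chromosome_map` (any `config$inversion` should already have
#'   been applied by the caller; [expected_copy_profile()] does this).
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A data.frame with one row per event: `origin`, `left_end`,
#'   `right_end` (bp, `left_end` may be negative / `right_end` beyond the
#'   chromosome length to denote wrap-around on the circle), `trapped_left`,
#'   `trapped_right` (site names or `NA`), `extra_copies`.
#' @export
simulate_rldr_events <- function(config, map, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(map, "chromosome_map"))
  if (!is.null(seed)) set.seed(seed)
  L <- map$length
  n <- stats::rpois(1, config$rldr_rate * config$n_cells)
  empty <- data.frame(origin = numeric(0), left_end = numeric(0),
                      right_end = numeric(0), trapped_left = character(0),
                      trapped_right = character(0), extra_copies = integer(0))
  if (n == 0) return(empty)
  u <- stats::runif(n, 0, L)
  run_r <- stats::rexp(n, 1 / config$rldr_run_mean)
  run_l <- stats::rexp(n, 1 / config$rldr_run_mean)

  # distance to the first successful arrest in one direction, Inf if none
  arrest_dist <- function(u, run, site_pos, site_eff, dist_fun) {
    d <- rep(Inf, length(u))
    who <- rep(NA_integer_, length(u))
    for (j in seq_along(site_pos)) {
      dj <- dist_fun(site_pos[j])
      hit <- dj <= run & stats::runif(length(u)) < site_eff[j] & dj < d
      d[hit] <- dj[hit]
      who[hit] <- j
    }
    list(d = d, who = who)
  }

  trapped_left <- rep(NA_character_, n)
  trapped_right <- rep(NA_character_, n)
  d_right <- run_r
  d_left <- run_l
  if (config$tus && length(map$ter_sites)) {
    pos <- vapply(map$ter_sites, `[[`, numeric(1), "position")
    blk <- vapply(map$ter_sites, `[[`, character(1), "blocks")
    eff <- vapply(map$ter_sites, `[[`, numeric(1), "efficiency")
    nm <- vapply(map$ter_sites, `[[`, character(1), "name")
    r_idx <- which(blk == "ccw")  # arrest rightward (clockwise) forks
    l_idx <- which(blk == "cw")
    if (length(r_idx)) {
      ar <- arrest_dist(u, run_r, pos[r_idx], eff[r_idx],
                        function(p) (p - u) %% L)
      stopped <- is.finite(ar$d)
      d_right[stopped] <- ar$d[stopped]
      trapped_right[stopped] <- nm[r_idx][ar$who[stopped]]
    }
    if (length(l_idx)) {
      al <- arrest_dist(u, run_l, pos[l_idx], eff[l_idx],
                        function(p) (u - p) %% L)
      stopped <- is.finite(al$d)
      d_left[stopped] <- al$d[stopped]
      trapped_left[stopped] <- nm[l_idx][al$who[stopped]]
    }
  }
  # cap so a single event never covers the circle more than once
  over <- (d_left + d_right) > L
  if (any(over)) {
    scl <- L / (d_left[over] + d_right[over])
    d_left[over] <- d_left[over] * scl
    d_right[over] <- d_right[over] * scl
  }
  extra <- integer(n)
  both <- config$tus & !is.na(trapped_left) & !is.na(trapped_right)
  if (any(both) && config$rereplication_prob > 0 &&
      config$rereplication_gain > 0) {
    burst <- both & stats::runif(n) < config$rereplication_prob
    if (any(burst)) {
      p <- 1 / (1 + config$rereplication_gain)
      extra[burst] <- stats::rgeom(sum(burst), p)
    }
  }
  data.frame(origin = u, left_end = u - d_left, right_end = u + d_right,
             trapped_left = trapped_left, trapped_right = trapped_right,
             extra_copies = extra, stringsAsFactors = FALSE)
}

# Accumulate per-window coverage (weight per event) for circular bp
# intervals [s, e] given as possibly out-of-range coordinates around origin.
accumulate_coverage <- function(events, weights, grid_n, L) {
  cov <- numeric(grid_n)
  if (!nrow(events)) return(cov)
  s <- events$left_end %% L
  e <- events$right_end %% L
  full <- (events$right_end - events$left_end) >= L - 1e-9
  ws <- locate_window(grid_n, L, s)
  we <- locate_window(grid_n, L, pmin(e, L - 1e-9))
  diffacc <- numeric(grid_n + 1)
  add <- function(i1, i2, w) {
    # weighted interval add via difference array
    if (!length(i1)) return()
    up <- rowsum(w, i1)
    diffacc[as.integer(rownames(up))] <<-
      diffacc[as.integer(rownames(up))] + up[, 1]
    dn <- rowsum(w, i2 + 1L)
    diffacc[as.integer(rownames(dn))] <<-
      diffacc[as.integer(rownames(dn))] + -dn[, 1]
  }
  wrap <- ws > we & !full
  plain <- !wrap & !full
  add(ws[plain], we[plain], weights[plain])
  add(ws[wrap], rep(grid_n, sum(wrap)), weights[wrap])
  add(rep(1L, sum(wrap)), we[wrap], weights[wrap])
  cov <- cumsum(diffacc[seq_len(grid_n)])
  cov + sum(weights[full])
}

#' Expected relative copy-number profile
#'
#' Composes the oriC gradient, the Monte-Carlo RLDR component and the
#' amplification block (see [sim_config()]) into a strictly positive
#' per-window relative copy-number vector normalized to genome-wide mean 1.
#' Any `config$inversion` is applied to the map before simulating.
#'
#' @param config A [sim_config()].
#' @param map A `chromosome_map`.
#' @param grid_n Number of windows (default 10,000).
#' @param events Optional pre-simulated [simulate_rldr_events()] table used
#'   instead of drawing new events. Useful for coupled Monte-Carlo designs
#'   (e.g. comparing rates on nested, binomially thinned event sets, a
#'   standard variance-reduction technique); the events must have been
#'   generated on the same (post-inversion) map.
#' @return Numeric vector of length `grid_n`, mean 1.
#' @export
expected_copy_profile <- function(config, map, grid_n = 10000, events = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(map, "chromosome_map"))
  if (!is.null(config$inversion))
    map <- apply_inversion(map, config$inversion[1], config$inversion[2])
  L <- map$length
  grid <- build_grid(L, grid_n)
  centers <- (grid$start + grid$end) / 2

  if (config$spc || config$c_over_tau == 0) {
    prof <- rep(1, grid_n)
  } else {
    t <- ori_fork_times(map, centers, tus = config$tus)
    m <- t / max(t)
    prof <- 2^(config$c_over_tau * (1 - m))
  }
  if (is.null(events) && config$rldr_rate > 0)
    events <- simulate_rldr_events(config, map, seed = config$seed)
  if (!is.null(events) && nrow(events)) {
    cov <- accumulate_coverage(events, 1 + events$extra_copies, grid_n, L)
    prof <- prof + cov / config$n_cells
  }
  if (!is.null(config$amplification)) {
    reg <- config$amplification$region
    inside <- centers >= reg[1] & centers < reg[2]
    prof[inside] <- prof[inside] * config$amplification$fold
  }
  prof / mean(prof)
}

#' Poisson-sample read counts from an expected profile
#'
#' `counts[i] ~ Poisson(depth * expected[i])`, independently per window.
#'
#' @param expected Positive per-window expected relative copy numbers.
#' @param depth Mean reads per window at expected copy number 1.
#' @param grid A [build_grid()] data.frame matching `expected`.
#' @param seed Optional RNG seed for reproducibility.
#' @param condition,sample_id Metadata for the returned track.
#' @return A `coverage_track`.
#' @export
sample_counts <- function(expected, depth, grid, seed = NULL,
                          condition = "log", sample_id = "sim") {
  if (depth < 0) stop("depth must be non-negative")
  if (any(expected < 0)) stop("expected profile must be non-negative")
  stopifnot(length(expected) == nrow(grid))
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(length(expected), depth * expected)
  coverage_track(counts, grid, condition = condition, sample_id = sample_id)
}

#' Write a coverage track as a test fixture
#'
#' `format = "tsv"` writes the per-window count table ([write_counts_tsv()]).
#' `format = "sam_lite"` expands each window count into that many single-end
#' reads (leftmost position = window start, MAPQ 60, FLAG 0) under an
#' `@HD`/`@SQ` header, so the coverage module's SAM path can be round-trip
#' tested.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param format `"tsv"` or `"sam_lite"`.
#' @param chrom Reference name for SAM output.
#' @param read_len Read length reported in the CIGAR.
#' @export
write_fixture <- function(track, path, format = c("tsv", "sam_lite"),
                          chrom = "chr", read_len = 50) {
  format <- match.arg(format)
  stopifnot(inherits(track, "coverage_track"))
  if (format == "tsv") return(write_counts_tsv(track, path))
  counts <- as.integer(track$counts)
  win <- rep.int(seq_along(counts), counts)
  pos1 <- track$grid$start[win] + 1L  # SAM is 1-based
  k <- stats::ave(win, win, FUN = seq_along)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(track$length)),
    if (length(win)) sprintf("r%d_%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                             win, k, chrom, pos1, as.integer(read_len))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / deserialize a simulation config as JSON
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  amp <- x$amplification
  if (!is.null(amp)) amp <- list(region = as.numeric(amp$region),
                                 fold = as.numeric(amp$fold))
  sim_config(c_over_tau = x$c_over_tau, rldr_rate = x$rldr_rate,
             rldr_run_mean = x$rldr_run_mean,
             rereplication_prob = x$rereplication_prob,
             rereplication_gain = x$rereplication_gain, spc = x$spc,
             tus = x$tus, inversion = if (length(x$inversion)) x$inversion,
             amplification = amp, n_cells = x$n_cells, depth = x$depth,
             seed = x$seed)
}
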