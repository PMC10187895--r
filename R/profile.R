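#' Normalize a sample track against the stationary-phase control
#'
#' Computes the per-window log2 ratio of library-size-scaled counts,
#' `r[i] = log2( (s[i]+p)/S * C/(c[i]+p) )`, where `S` and `C` are the total
#' read counts of the sample and the stationary-phase control. The control
#' corrects window-specific depth biases (mappability, copy number of the
#' non-replicating genome); the library-size scaling removes global depth
#' differences, so multiplying all sample counts by a constant changes no
#' ratio, and a sample normalized against itself gives all zeros.
#'
#' @param sample A `coverage_track` (condition `log` or `spc`).
#' @param control A `coverage_track` with condition `stationary_control`.
#' @param pseudocount Added to both numerator and denominator counts to keep
#'   zero-count windows finite (default 0.5).
#' @return Numeric vector of per-window log2 ratios.
#' @export
normalize_to_control <- function(sample, control, pseudocount = 0.5) {
  stopifnot(inherits(sample, "coverage_track"),
            inherits(control, "coverage_track"))
  if (sample$grid_n != control$grid_n ||
      !isTRUE(all.equal(sample$grid, control$grid)))
    stop("sample and control are on different window grids")
  s_tot <- sum(sample$counts)
  c_tot <- sum(control$counts)
  if (s_tot <= 0 || c_tot <= 0) stop("empty track: total count is zero")
  log2(((sample$counts + pseudocount) / s_tot) *
         (c_tot / (control$counts + pseudocount)))
}

# contiguous k-nearest-neighbour window of xi in sorted x: returns c(j1, j2)
knn_window <- function(x, xi, k) {
  n <- length(x)
  if (k >= n) return(c(1L, n))
  pos <- findInterval(xi, x)
  j_lo <- max(1L, min(pos - k + 1L, n - k + 1L))
  j_hi <- min(pos + 1L, n - k + 1L)
  js <- j_lo:j_hi
  cost <- pmax(abs(x[js] - xi), abs(x[js + k - 1L] - xi))
  j <- js[which.min(cost)]
  c(j, j + k - 1L)
}

#' Locally weighted (loess-style) smoothing on a genome axis
#'
#' Degree-1 local regression with tricube weights over the
#' `ceiling(span * n)` nearest neighbours of each point — the canonical
#' loess default, without robustness iterations. For circular chromosomes,
#' `span/2` of the data is wrapped from each end (shifted by the period)
#' before fitting and the fit is cropped back, so the smoothed curve has no
#' edge artifact at the origin of the coordinate system.
#'
#' @param x Sorted positions (window centers).
#' @param y Values at `x`.
#' @param span Fraction of points in each local fit, in (0, 1] (default 0.1).
#' @param circular Wrap the data around the chromosome before fitting?
#' @param period Chromosome length in bp (required when `circular = TRUE`).
#' @return Smoothed values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.1, circular = FALSE, period = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 10) stop("too few points for loess smoothing (need >= 10)")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  k <- ceiling(span * n)
  if (k < 3) stop("span * n must be >= 3")
  if (is.unsorted(x)) stop("x must be sorted increasing")

  if (circular) {
    if (is.null(period)) stop("circular smoothing needs the period (genome length)")
    npad <- ceiling(k / 2)
    idx_pre <- (n - npad + 1):n
    idx_post <- 1:npad
    xp <- c(x[idx_pre] - period, x, x[idx_post] + period)
    yp <- c(y[idx_pre], y, y[idx_post])
    offset <- npad
  } else {
    xp <- x
    yp <- y
    offset <- 0L
  }

  out <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    jw <- knn_window(xp, xi, k)
    xs <- xp[jw[1]:jw[2]]
    ys <- yp[jw[1]:jw[2]]
    d <- abs(xs - xi)
    dmax <- max(d)
    w <- if (dmax == 0) rep(1, length(d)) else (1 - pmin(d / dmax, 1)^3)^3
    sw <- sum(w)
    swx <- sum(w * xs)
    swy <- sum(w * ys)
    swxx <- sum(w * xs * xs)
    swxy <- sum(w * xs * ys)
    den <- sw * swxx - swx^2
    if (abs(den) < 1e-10 * max(1, swxx) * max(1, sw)) {
      out[i] <- swy / sw  # degenerate spread: weighted mean
    } else {
      beta <- (sw * swxy - swx * swy) / den
      alpha <- (swy - beta * swx) / sw
      out[i] <- alpha + beta * xi
    }
  }
  out
}

#' Assemble an MFA profile
#'
#' Normalizes a sample coverage track against the stationary-phase control
#' ([normalize_to_control()]) and overlays the circular loess curve
#' ([loess_smooth()]) at the published defaults (span 0.1).
#'
#' @param sample,control `coverage_track`s on the same grid.
#' @param span Loess span (default 0.1).
#' @param pseudocount See [normalize_to_control()].
#' @return An object of class `mfa_profile` with fields `window_centers`,
#'   `log2_ratio`, `loess`, `span`, `grid`, `length`, `sample_id`.
#' @export
assemble_profile <- function(sample, control, span = 0.1, pseudocount = 0.5) {
  r <- normalize_to_control(sample, control, pseudocount = pseudocount)
  centers <- (sample$grid$start + sample$grid$end) / 2
  sm <- loess_smooth(centers, r, span = span, circular = TRUE,
                     period = sample$length)
  structure(
    list(window_centers = centers, log2_ratio = r, loess = sm, span = span,
         grid = sample$grid, length = sample$length,
         sample_id = sample$sample_id),
    class = "mfa_profile"
  )
}

#' @export
print.mfa_profile <- function(x, ...) {
  cat(sprintf(
    "<mfa_profile> '%s': %d windows over %.2f Mb, span %.2f, loess range [%.3f, %.3f]\n",
    x$sample_id, length(x$log2_ratio), x$length / 1e6, x$span,
    min(x$loess), max(x$loess)))
  invisible(x)
}

#' Write an MFA profile as TSV (and optionally bedGraph)
#'
#' TSV columns: `center`, `log2_ratio`, `loess`.
#'
#' @param profile An `mfa_profile`.
#' @param path Output TSV path.
#' @param bedgraph Optional path for a bedGraph of the raw log2 ratios.
#' @param chrom Chromosome name for the bedGraph.
#' @export
write_profile_tsv <- function(profile, path, bedgraph = NULL, chrom = "chr") {
  stopifnot(inherits(profile, "mfa_profile"))
  tab <- data.frame(center = profile$window_centers,
                    log2_ratio = profile$log2_ratio,
                    loess = profile$loess)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedgraph))
    write_bedgraph(profile$grid, profile$log2_ratio, bedgraph, chrom = chrom)
  invisible(path)
}
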