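#' Candidate Ter peak region
#'
#' @param left,right bp bounds of the candidate over-replicated interval
#'   (typically the innermost Ter/Tus pair, e.g. from
#'   [innermost_ter_interval()]); `left < right`.
#' @param flank_width Number of windows immediately clockwise of `right` in
#'   which the reference minimum is searched (default 200).
#' @return An object of class `peak_region`.
#' @export
peak_region <- function(left, right, flank_width = 200) {
  if (!(left < right)) stop("peak_region needs left < right")
  if (flank_width < 1) stop("flank_width must be >= 1")
  structure(list(left = left, right = right,
                 flank_width = as.integer(flank_width)),
            class = "peak_region")
}

region_window_idx <- function(profile, region) {
  which(profile$window_centers >= region$left &
          profile$window_centers <= region$right)
}

flank_window_idx <- function(profile, region) {
  n <- length(profile$window_centers)
  idx <- region_window_idx(profile, region)
  if (!length(idx)) stop("peak region contains no windows")
  start <- max(idx) + 1L
  ((start - 1L) + seq_len(min(region$flank_width, n - length(idx))) - 1L) %% n + 1L
}

#' Ter peak height of an MFA profile
#'
#' The difference between the highest loess value inside the candidate
#' region and the lowest loess value in the `flank_width` windows
#' immediately clockwise of the region. Adding a constant to the whole curve
#' leaves the statistic unchanged.
#'
#' @param profile An `mfa_profile`.
#' @param region A [peak_region()].
#' @return The peak height (log2 units).
#' @export
peak_height <- function(profile, region) {
  stopifnot(inherits(profile, "mfa_profile"), inherits(region, "peak_region"))
  idx <- region_window_idx(profile, region)
  if (!length(idx)) stop("peak region contains no windows")
  fidx <- flank_window_idx(profile, region)
  if (!length(fidx)) stop("empty flank")
  max(profile$loess[idx]) - min(profile$loess[fidx])
}

#' Spectinomycin Ter-peak-increase statistic
#'
#' Quantifies continued replication in the Ter region during protein
#' synthesis inhibition: the peak height after the spectinomycin run-off
#' minus the peak height before it. Positive values indicate synthesis in
#' Ter that does not depend on new oriC initiations (R-loop-dependent
#' replication trapped at Ter/Tus).
#'
#' @param profile_pre MFA profile before spectinomycin (log phase).
#' @param profile_post MFA profile after the run-off.
#' @param region A [peak_region()].
#' @return `peak_height(post) - peak_height(pre)`.
#' @export
ter_peak_increase <- function(profile_pre, profile_post, region) {
  if (length(profile_pre$window_centers) != length(profile_post$window_centers) ||
      !isTRUE(all.equal(profile_pre$window_centers,
                        profile_post$window_centers)))
    stop("pre and post profiles are on different grids")
  peak_height(profile_post, region) - peak_height(profile_pre, region)
}

resolve_locus <- function(locus, map, what = "locus") {
  if (inherits(locus, "locus")) return(locus)
  if (is.character(locus)) {
    if (is.null(map)) stop("a map is required to look up locus '", locus, "'")
    lc <- map$loci[[locus]]
    if (is.null(lc)) stop(what, " '", locus, "' not found in map")
    return(lc)
  }
  stop(what, " must be a locus object or a name")
}

locus_window_idx <- function(n, length, pos, w) {
  center <- locate_window(n, length, pos)
  ((center - 1L) + (-w:w)) %% n + 1L
}

#' Marker-locus copy ratio
#'
#' The in-silico analogue of the qPCR marker ratio (e.g. ydcM/lepA, which
#' tracks the Ter peak height): mean raw counts (or `2^loess` for a
#' profile) over the `2w+1` windows centered at locus A divided by the same
#' at locus B.
#'
#' @param x A `coverage_track` (raw-count ratio, the qPCR analogue) or an
#'   `mfa_profile` (ratio of `2^loess`).
#' @param locus_a,locus_b [locus()] objects or names to look up in `map`.
#' @param map Optional `chromosome_map` for name lookup.
#' @param w Window half-width (default 1, i.e. 3 windows per locus).
#' @param pseudocount Guard for zero-count denominators (default 0).
#' @return The ratio A/B.
#' @export
marker_ratio <- function(x, locus_a, locus_b, map = NULL, w = 1,
                         pseudocount = 0) {
  la <- resolve_locus(locus_a, map, "locus A")
  lb <- resolve_locus(locus_b, map, "locus B")
  if (inherits(x, "coverage_track")) {
    n <- x$grid_n
    vals <- x$counts
    L <- x$length
  } else if (inherits(x, "mfa_profile")) {
    n <- length(x$loess)
    vals <- 2^x$loess
    L <- x$length
  } else stop("x must be a coverage_track or mfa_profile")
  num <- mean(vals[locus_window_idx(n, L, la$position, w)]) + pseudocount
  den <- mean(vals[locus_window_idx(n, L, lb$position, w)]) + pseudocount
  if (den == 0) stop("zero denominator at locus '", lb$name,
                     "'; use a pseudocount")
  num / den
}

#' Region-to-reference copy ratio (amplification fold estimate)
#'
#' Mean window count inside a region divided by the mean count around a
#' reference locus: the sequencing analogue of estimating a gene
#' amplification (e.g. the parC-parE block) by a qPCR ratio against a locus
#' just outside it.
#'
#' @param track A `coverage_track`.
#' @param region Numeric `c(left, right)` bp interval.
#' @param reference_locus A [locus()] or name (with `map`).
#' @param map Optional `chromosome_map` for name lookup.
#' @param w Reference window half-width (default 1).
#' @param pseudocount Guard for zero denominators.
#' @return Estimated fold.
#' @export
region_copy_ratio <- function(track, region, reference_locus, map = NULL,
                              w = 1, pseudocount = 0) {
  stopifnot(inherits(track, "coverage_track"), length(region) == 2L,
            region[1] < region[2])
  ref <- resolve_locus(reference_locus, map, "reference locus")
  centers <- (track$grid$start + track$grid$end) / 2
  inside <- centers >= region[1] & centers <= region[2]
  if (!any(inside)) stop("region contains no windows")
  num <- mean(track$counts[inside]) + pseudocount
  den <- mean(track$counts[locus_window_idx(track$grid_n, track$length,
                                            ref$position, w)]) + pseudocount
  if (den == 0) stop("zero denominator at reference locus; use a pseudocount")
  num / den
}

#' Flatness test for an MFA profile
#'
#' Scores the candidate region with [peak_height()] and calls the profile
#' flat when the score falls below a threshold. Deleting tus flattens the
#' profile (no Ter peaks); this test formalizes that call. The default
#' threshold is 3x the loess standard deviation of a control profile when
#' one is supplied, otherwise 3x the loess SD of this profile outside the
#' region and its flank.
#'
#' @param profile An `mfa_profile`.
#' @param region A [peak_region()].
#' @param threshold Explicit threshold in log2 units (overrides the default).
#' @param control Optional control `mfa_profile` used to set the threshold.
#' @return A list with `flat` (logical), `score`, `threshold`.
#' @export
flatness_test <- function(profile, region, threshold = NULL, control = NULL) {
  score <- peak_height(profile, region)
  if (is.null(threshold)) {
    if (!is.null(control)) {
      threshold <- 3 * stats::sd(control$loess)
    } else {
      excl <- union(region_window_idx(profile, region),
                    flank_window_idx(profile, region))
      threshold <- 3 * stats::sd(profile$loess[-excl])
    }
  }
  list(flat = score < threshold, score = score, threshold = threshold)
}

#' One-row Ter over-replication report
#'
#' Convenience summary used by the pipeline: peak heights pre/post
#' spectinomycin, the Ter-peak-increase statistic, marker ratios and the
#' flatness verdict.
#'
#' @param profile_pre,profile_post MFA profiles before/after spectinomycin.
#' @param region A [peak_region()].
#' @param map A `chromosome_map` carrying `ydcM`, `lepA` and `qseC` loci (any
#'   missing locus yields `NA` ratios).
#' @return A one-row data.frame.
#' @export
peak_report <- function(profile_pre, profile_post, region, map) {
  ratio_or_na <- function(p, a, b) {
    tryCatch(marker_ratio(p, a, b, map = map), error = function(e) NA_real_)
  }
  fl <- flatness_test(profile_post, region)
  data.frame(
    region_left = region$left, region_right = region$right,
    peak_height_pre = peak_height(profile_pre, region),
    peak_height_post = peak_height(profile_post, region),
    ter_peak_increase = ter_peak_increase(profile_pre, profile_post, region),
    ydcM_lepA_pre = ratio_or_na(profile_pre, "ydcM", "lepA"),
    ydcM_lepA_post = ratio_or_na(profile_post, "ydcM", "lepA"),
    qseC_lepA_pre = ratio_or_na(profile_pre, "qseC", "lepA"),
    flat_post = fl$flat, flat_score = fl$score,
    flat_threshold = fl$threshold
  )
}
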