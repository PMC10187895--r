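#' Relative quantification by the 2^-dCt formula
#'
#' `ratio = 2^-(ct_target - ct_reference)`: one threshold cycle earlier for
#' the target means twice as much template, assuming 100% amplification
#' efficiency. Vectorized.
#'
#' @param ct_target,ct_reference Threshold cycles.
#' @return Fold ratio(s).
#' @export
#' @examples
#' ddct_ratio(20, 20)   # 1
#' ddct_ratio(19, 20)   # 2
ddct_ratio <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^(-(ct_target - ct_reference))
}

#' Aggregate replicate qPCR ratios
#'
#' Computes per-replicate ratios with [ddct_ratio()], then the arithmetic
#' mean and sample standard deviation over replicates for each
#' sample/target/reference combination (ratios first, statistics on the
#' ratios — not ratios of mean Cts).
#'
#' @param measurements A data.frame with columns `target`, `reference`,
#'   `ct_target`, `ct_reference` and optionally `sample_id` and `replicate`.
#' @return A data.frame with one row per sample/pair: `sample_id`, `pair`,
#'   `mean_ratio`, `sd`, `n`, `sd_defined` (FALSE when n = 1, where the SD
#'   is reported as 0).
#' @export
aggregate_ratios <- function(measurements) {
  need <- c("target", "reference", "ct_target", "ct_reference")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (!nrow(measurements)) stop("no measurements")
  m <- measurements
  if (is.null(m$sample_id)) m$sample_id <- "sample"
  m$ratio <- ddct_ratio(m$ct_target, m$ct_reference)
  m$pair <- paste0(m$target, "/", m$reference)
  key <- interaction(m$sample_id, m$pair, drop = TRUE)
  out <- do.call(rbind, lapply(split(m, key), function(g) {
    n <- nrow(g)
    data.frame(sample_id = g$sample_id[1], pair = g$pair[1],
               mean_ratio = mean(g$ratio),
               sd = if (n > 1) stats::sd(g$ratio) else 0,
               n = n, sd_defined = n > 1, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a qPCR Ct table
#'
#' TSV columns: `sample_id`, `target`, `reference`, `ct_target`,
#' `ct_reference`, `replicate`.
#'
#' @param path File path.
#' @return A data.frame suitable for [aggregate_ratios()].
#' @export
read_ct_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "reference", "ct_target", "ct_reference")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Adjusted activity for a partially active fusion enzyme
#'
#' When an overexpressed enzyme is a fusion protein k-fold less active than
#' the native one, the effective activity fold is the strain's baseline fold
#' plus the fusion-derived remainder reduced k-fold:
#' `baseline_fold + (raw_fold - baseline_fold) / k`. `k` may be a vector
#' (e.g. `c(5, 10)`) to obtain the interval endpoints for a 5- to 10-fold
#' activity reduction.
#'
#' @param baseline_fold Expression fold without the fusion construct.
#' @param raw_fold Measured expression fold with the construct
#'   (`>= baseline_fold`).
#' @param k Activity divisor(s); values outside `[5, 10]` are allowed with a
#'   warning.
#' @return Adjusted fold(s), one per element of `k`.
#' @export
#' @examples
#' adjusted_activity(2, 12, k = c(5, 10))  # c(4, 3)
adjusted_activity <- function(baseline_fold, raw_fold, k = c(5, 10)) {
  if (baseline_fold < 0) stop("baseline_fold must be >= 0")
  if (raw_fold < baseline_fold)
    stop("raw_fold (", raw_fold, ") below baseline_fold (", baseline_fold, ")")
  if (any(k <= 0)) stop("k must be positive")
  if (any(k < 5 | k > 10))
    warning("k outside the published 5-10 fold activity-reduction range")
  baseline_fold + (raw_fold - baseline_fold) / k
}
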