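#' Build the genome window grid
#'
#' Divides the circular chromosome `[0, length)` into `grid_n` contiguous
#' windows. The base window width is `floor(length / grid_n)` and the first
#' `length %% grid_n` windows are one bp wider, so the windows exactly
#' partition the chromosome. For an E. coli-scale genome the default 10,000
#' windows are ~465-500 bp each ("500 bp windows on average").
#'
#' @param length Chromosome length in bp.
#' @param grid_n Number of windows (default 10,000); must not exceed `length`.
#' @return A data.frame with columns `start`, `end` (0-based, half-open).
#' @export
#' @examples
#' build_grid(1000, 10)    # ten 100 bp windows
#' head(build_grid(1001, 10))  # first window is 101 bp
build_grid <- function(length, grid_n = 10000) {
  if (grid_n > length) stop("grid_n (", grid_n, ") exceeds length (", length, ")")
  if (grid_n < 1) stop("grid_n must be >= 1")
  w <- length %/% grid_n
  r <- length %% grid_n
  widths <- rep(w, grid_n)
  if (r > 0) widths[seq_len(r)] <- w + 1
  end <- cumsum(widths)
  data.frame(start = c(0, end[-grid_n]), end = end)
}

#' Per-window read-count track
#'
#' @param counts Non-negative integer counts, one per window.
#' @param grid A [build_grid()] data.frame.
#' @param condition `"log"`, `"spc"` or `"stationary_control"` — the growth/
#'   treatment state the sample was taken in.
#' @param sample_id Free-text sample label.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(counts, grid,
                           condition = c("log", "spc", "stationary_control"),
                           sample_id = "sample") {
  condition <- match.arg(condition)
  if (length(counts) != nrow(grid))
    stop("counts length (", length(counts), ") != number of windows (",
         nrow(grid), ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(
    list(counts = as.numeric(counts), grid = grid, grid_n = nrow(grid),
         length = grid$end[nrow(grid)], condition = condition,
         sample_id = sample_id),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> '%s' (%s): %d windows over %.2f Mb, %s reads\n",
              x$sample_id, x$condition, x$grid_n, x$length / 1e6,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read a SAM file into a table of aligned reads
#'
#' Parses the minimal single-end SAM dialect the pipeline consumes (header
#' lines starting with `@` are skipped; each alignment line must have at
#' least 11 tab-separated fields). Only the fields MFA needs are retained:
#' the 1-based leftmost position, the mapping quality and the mapped flag
#' (SAM FLAG bit 0x4 unset).
#'
#' @param path Path to a SAM file.
#' @return A data.frame with columns `position` (1-based), `mapq`, `mapped`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  is_aln <- !startsWith(lines, "@") & nzchar(lines)
  ln <- which(is_aln)
  if (!length(ln))
    return(data.frame(position = integer(0), mapq = integer(0),
                      mapped = logical(0)))
  fields <- strsplit(lines[ln], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("SAM parse error at line ", ln[which(nf < 11)[1]],
         ": fewer than 11 tab-separated fields")
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  bad <- which(is.na(flag) | is.na(pos) | is.na(mapq))
  if (length(bad))
    stop("SAM parse error at line ", ln[bad[1]],
         ": non-integer FLAG/POS/MAPQ field")
  data.frame(position = pos, mapq = mapq,
             mapped = bitwAnd(flag, 4L) == 0L)
}

#' Filter reads on mapping quality
#'
#' Keeps mapped reads whose MAPQ is at least `min_mapq` (inclusive; the
#' standard threshold of 10 discards multi-mapping reads).
#'
#' @param reads A [read_sam()] data.frame.
#' @param min_mapq Minimum mapping quality to keep a read (default 10).
#' @return The filtered data.frame.
#' @export
filter_mapq <- function(reads, min_mapq = 10) {
  reads[reads$mapped & reads$mapq >= min_mapq, , drop = FALSE]
}

#' Bin reads into genome windows
#'
#' Assigns each read to exactly one window by its 0-based leftmost mapped
#' coordinate (the CIGAR/length of the read is ignored: depth here is a read
#' start count, which is deterministic and conserving). The total of the
#' returned counts equals the number of input reads.
#'
#' @param reads A data.frame with a 1-based `position` column (e.g. from
#'   [read_sam()] after [filter_mapq()]).
#' @param grid A [build_grid()] data.frame.
#' @param condition,sample_id Passed to [coverage_track()].
#' @return A `coverage_track`.
#' @export
bin_reads <- function(reads, grid, condition = "log", sample_id = "sample") {
  grid_n <- nrow(grid)
  length <- grid$end[grid_n]
  pos0 <- reads$position - 1
  if (any(pos0 < 0 | pos0 >= length))
    stop("read position outside chromosome [1, ", length, "]")
  idx <- locate_window(grid_n, length, pos0)
  counts <- tabulate(idx, nbins = grid_n)
  coverage_track(counts, grid, condition = condition, sample_id = sample_id)
}

#' Read / write per-window count tables as TSV
#'
#' The TSV has a header and columns `window_start`, `window_end` (0-based,
#' half-open) and `count`.
#'
#' @param path File path.
#' @param condition,sample_id Metadata attached on read (not stored in the
#'   file).
#' @return For `read_counts_tsv`, a `coverage_track`.
#' @export
read_counts_tsv <- function(path, condition = "log", sample_id = "sample") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("window_start", "window_end", "count")
  if (!all(need %in% names(tab)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  grid <- data.frame(start = tab$window_start, end = tab$window_end)
  coverage_track(tab$count, grid, condition = condition, sample_id = sample_id)
}

#' @rdname read_counts_tsv
#' @param track A `coverage_track`.
#' @export
write_counts_tsv <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  tab <- data.frame(window_start = track$grid$start,
                    window_end = track$grid$end,
                    count = track$counts)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-window value vector as bedGraph
#'
#' 0-based, half-open intervals, one line per window.
#'
#' @param grid A [build_grid()] data.frame.
#' @param values Numeric vector, one value per window.
#' @param path Output path.
#' @param chrom Chromosome name used in column 1.
#' @export
write_bedgraph <- function(grid, values, path, chrom = "chr") {
  stopifnot(length(values) == nrow(grid))
  tab <- data.frame(chrom = chrom, start = grid$start, end = grid$end,
                    value = values)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
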