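#' Polar replication fork barrier (Ter/Tus site)
#'
#' A *Ter* site bound by Tus arrests replication forks arriving from one side
#' of the site only. `blocks` names that side: a site with `blocks = "cw"`
#' arrests forks approaching from the clockwise side (i.e. forks moving toward
#' decreasing coordinates), while `blocks = "ccw"` arrests forks approaching
#' from the counterclockwise side (forks moving toward increasing
#' coordinates). Clockwise is the direction of increasing coordinate, with
#' wrap-around at the chromosome length. Under this convention the left edge
#' of the terminus trap (TerA-like sites) blocks "cw" and the right edge
#' (TerB-like sites) blocks "ccw", so forks entering the trap from either
#' replichore pass the near barrier and are arrested at the far one.
#'
#' @param name Short unique label, e.g. `"TerA"`.
#' @param position 0-based bp offset on the chromosome.
#' @param blocks `"cw"` or `"ccw"` (see Description).
#' @param efficiency Arrest probability in `[0, 1]`; weak barriers such as
#'   TerG arrest only a fraction of arriving forks.
#' @return An object of class `ter_site`.
#' @export
#' @examples
#' ter_site("TerA", 4e5, "cw")
#' ter_site("TerG", 2.38e6, "ccw", efficiency = 0.5)
ter_site <- function(name, position, blocks = c("cw", "ccw"), efficiency = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  blocks <- match.arg(blocks)
  if (!is.numeric(position) || length(position) != 1L || position < 0)
    stop("ter_site '", name, "': position must be a single non-negative number")
  if (!is.numeric(efficiency) || efficiency < 0 || efficiency > 1)
    stop("ter_site '", name, "': efficiency must be in [0, 1]")
  structure(
    list(name = name, position = as.numeric(position), blocks = blocks,
         efficiency = as.numeric(efficiency)),
    class = "ter_site"
  )
}

#' Named marker locus
#'
#' @param name Marker label (e.g. `"ydcM"`, `"lepA"`, `"qseC"`).
#' @param position 0-based bp offset.
#' @return An object of class `locus`.
#' @export
locus <- function(name, position) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(position) || length(position) != 1L || position < 0)
    stop("locus '", name, "': position must be a single non-negative number")
  structure(list(name = name, position = as.numeric(position)), class = "locus")
}

#' Build a circular chromosome map
#'
#' Validates and assembles the coordinate frame every other computation uses:
#' a circular chromosome of `length` bp with the origin of bidirectional
#' replication `oriC`, a set of polar Ter/Tus barriers and named marker loci.
#' All coordinates are 0-based, half-open internally; positions must lie in
#' `[0, length)`.
#'
#' @param length Chromosome length in bp (> 0).
#' @param oriC 0-based position of oriC.
#' @param ter_sites List of [ter_site()] objects (names must be unique).
#' @param loci List of [locus()] objects.
#' @param dif Optional position of the dif site.
#' @return An object of class `chromosome_map`.
#' @export
#' @examples
#' m <- build_map(1e6, oriC = 0,
#'   ter_sites = list(ter_site("TerA", 4e5, "cw"), ter_site("TerB", 6e5, "ccw")),
#'   loci = list(locus("ydcM", 5.2e5), locus("lepA", 8e5)))
build_map <- function(length, oriC, ter_sites = list(), loci = list(), dif = NULL) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0)
    stop("chromosome length must be a single positive number")
  chk_pos <- function(p, what) {
    if (p < 0 || p >= length)
      stop(what, " position ", p, " outside [0, ", length, ")")
  }
  chk_pos(oriC, "oriC")
  if (!is.null(dif)) chk_pos(dif, "dif")
  for (ts in ter_sites) {
    if (!inherits(ts, "ter_site")) stop("ter_sites must be ter_site objects")
    chk_pos(ts$position, paste0("Ter site '", ts$name, "'"))
  }
  for (lc in loci) {
    if (!inherits(lc, "locus")) stop("loci must be locus objects")
    chk_pos(lc$position, paste0("locus '", lc$name, "'"))
  }
  ter_names <- vapply(ter_sites, `[[`, character(1), "name")
  if (anyDuplicated(ter_names))
    stop("duplicate Ter site name: ",
         paste(unique(ter_names[duplicated(ter_names)]), collapse = ", "))
  names(ter_sites) <- ter_names
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  structure(
    list(length = as.numeric(length), oriC = as.numeric(oriC),
         dif = if (is.null(dif)) NULL else as.numeric(dif),
         ter_sites = ter_sites, loci = loci, circular = TRUE),
    class = "chromosome_map"
  )
}

#' @export
print.chromosome_map <- function(x, ...) {
  cat(sprintf("<chromosome_map> circular, %.2f Mb, oriC at %.2f Mb\n",
              x$length / 1e6, x$oriC / 1e6))
  for (ts in x$ter_sites)
    cat(sprintf("  Ter %-6s %8.2f Mb  blocks %-3s  eff %.2f\n",
                ts$name, ts$position / 1e6, ts$blocks, ts$efficiency))
  for (lc in x$loci)
    cat(sprintf("  locus %-6s %6.2f Mb\n", lc$name, lc$position / 1e6))
  invisible(x)
}

#' Apply a chromosomal inversion to a map
#'
#' Rearranges the segment `[a, b)`: every feature at position `p` inside the
#' segment moves to `a + b - 1 - p`, and Ter sites inside flip the side they
#' block (a barrier arresting forks from the counterclockwise side arrests
#' forks from the clockwise side after inversion). Features outside `[a, b)`
#' are unchanged. Applying the same inversion twice restores the original map.
#'
#' This models rearrangements such as the naturally occurring inversion that
#' repositions the TerB barrier so that the fork trap, and with it the
#' over-replicated interval, relocates between the inverted TerB and TerG.
#'
#' @param map A [build_map()] result.
#' @param a,b Segment bounds in bp, `0 <= a < b <= length`.
#' @return A new `chromosome_map`.
#' @export
apply_inversion <- function(map, a, b) {
  stopifnot(inherits(map, "chromosome_map"))
  if (!(a >= 0 && a < b && b <= map$length))
    stop("invalid inversion bounds: need 0 <= a < b <= length, got [",
         a, ", ", b, "]")
  flip_pos <- function(p) if (p >= a && p < b) a + b - 1 - p else p
  ter <- lapply(map$ter_sites, function(ts) {
    if (ts$position >= a && ts$position < b) {
      ts$position <- a + b - 1 - ts$position
      ts$blocks <- if (ts$blocks == "cw") "ccw" else "cw"
    }
    ts
  })
  loci <- lapply(map$loci, function(lc) {
    lc$position <- flip_pos(lc$position)
    lc
  })
  build_map(map$length, flip_pos(map$oriC), ter_sites = unname(ter),
            loci = unname(loci),
            dif = if (is.null(map$dif)) NULL else flip_pos(map$dif))
}

#' Window index of a bp position on the standard grid
#'
#' The grid divides `[0, length)` into `grid_n` contiguous windows of base
#' width `floor(length / grid_n)`; the first `length %% grid_n` windows are
#' one bp wider so the windows exactly partition the chromosome (see
#' [build_grid()]).
#'
#' @param grid_n Number of windows.
#' @param length Chromosome length in bp.
#' @param pos bp position(s), 0-based, in `[0, length)`. Vectorized.
#' @return Integer window indices in `[1, grid_n]` (1-based, R convention).
#' @export
locate_window <- function(grid_n, length, pos) {
  if (any(pos < 0 | pos >= length))
    stop("position out of range [0, ", length, ")")
  w <- length %/% grid_n
  r <- length %% grid_n
  wide_span <- r * (w + 1)
  idx <- ifelse(pos < wide_span,
                pos %/% (w + 1),
                r + (pos - wide_span) %/% w)
  as.integer(idx) + 1L
}

# Innermost trapped interval: the first barrier each oriC fork would be
# arrested at (clockwise fork at the nearest "ccw"-blocking site along its
# path, counterclockwise fork at the nearest "cw"-blocking site). Returns the
# arc between them that does not contain oriC.

#' Innermost Ter/Tus trap interval of a map
#'
#' @param map A `chromosome_map` with at least one barrier of each polarity.
#' @return Named numeric `c(left, right)` in bp; the interval is the arc from
#'   `left` to `right` in the clockwise direction (it may wrap past 0).
#' @export
innermost_ter_interval <- function(map) {
  stopifnot(inherits(map, "chromosome_map"))
  L <- map$length
  pos <- vapply(map$ter_sites, `[[`, numeric(1), "position")
  blk <- vapply(map$ter_sites, `[[`, character(1), "blocks")
  cw_block <- pos[blk == "ccw"]   # arrest clockwise-moving forks
  ccw_block <- pos[blk == "cw"]   # arrest counterclockwise-moving forks
  if (!length(cw_block) || !length(ccw_block))
    stop("map needs at least one barrier of each polarity")
  d_cw <- (cw_block - map$oriC) %% L
  d_ccw <- (map$oriC - ccw_block) %% L
  right <- cw_block[which.min(d_cw)]   # first stop of the clockwise fork
  left <- ccw_block[which.min(d_ccw)]  # first stop of the counterclockwise fork
  c(left = unname(left), right = unname(right))
}

#' Read / write a chromosome map as TSV
#'
#' Columns: `feature_type` (`ter`, `locus`, `oriC` or `dif`), `name`,
#' `position_bp`, `blocks` (`cw`, `ccw` or `.`), `efficiency` (`.` for
#' non-Ter rows). A header comment line `# length=<bp>` carries the
#' chromosome length.
#'
#' @param path File path.
#' @return For `read_map_tsv`, a `chromosome_map`.
#' @export
read_map_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*length=", lines, value = TRUE)
  if (!length(hdr)) stop("map file lacks '# length=<bp>' header: ", path)
  len <- as.numeric(sub("^#\\s*length=", "", hdr[1]))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           stringsAsFactors = FALSE)
  need <- c("feature_type", "name", "position_bp", "blocks", "efficiency")
  if (!all(need %in% names(tab)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  ori <- tab$position_bp[tab$feature_type == "oriC"]
  if (length(ori) != 1L) stop("map file must contain exactly one oriC row")
  dif <- tab$position_bp[tab$feature_type == "dif"]
  ters <- lapply(which(tab$feature_type == "ter"), function(i)
    ter_site(tab$name[i], tab$position_bp[i], tab$blocks[i],
             as.numeric(tab$efficiency[i])))
  locs <- lapply(which(tab$feature_type == "locus"), function(i)
    locus(tab$name[i], tab$position_bp[i]))
  build_map(len, ori, ter_sites = ters, loci = locs,
            dif = if (length(dif)) dif[1] else NULL)
}

#' @rdname read_map_tsv
#' @param map A `chromosome_map` to serialize.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "chromosome_map"))
  rows <- data.frame(
    feature_type = "oriC", name = "oriC", position_bp = map$oriC,
    blocks = ".", efficiency = ".", stringsAsFactors = FALSE)
  if (!is.null(map$dif))
    rows <- rbind(rows, data.frame(feature_type = "dif", name = "dif",
                                   position_bp = map$dif, blocks = ".",
                                   efficiency = "."))
  for (ts in map$ter_sites)
    rows <- rbind(rows, data.frame(feature_type = "ter", name = ts$name,
                                   position_bp = ts$position, blocks = ts$blocks,
                                   efficiency = format(ts$efficiency)))
  for (lc in map$loci)
    rows <- rbind(rows, data.frame(feature_type = "locus", name = lc$name,
                                   position_bp = lc$position, blocks = ".",
                                   efficiency = "."))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# length=%d", as.integer(map$length)), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default E. coli-like chromosome map (synthetic coordinates)
#'
#' A 4.64 Mb circular chromosome with oriC, the TerA/TerB innermost trap,
#' the weak TerG barrier and the qPCR marker loci ydcM (near the top of the
#' Ter peak), lepA (outside Ter and outside the parC-parE amplified region)
#' and qseC (inside the amplified region). Positions are approximate,
#' synthetic stand-ins at the right genomic scale; edit or replace via
#' [read_map_tsv()] for real coordinates.
#'
#' @return A `chromosome_map`.
#' @export
default_map <- function() {
  build_map(
    length = 4640000, oriC = 3925000, dif = 1590000,
    ter_sites = list(
      ter_site("TerA", 1340000, "cw", 1.0),
      ter_site("TerB", 1685000, "ccw", 1.0),
      ter_site("TerG", 2380000, "ccw", 0.5)
    ),
    loci = list(
      locus("ydcM", 1525000),
      locus("lepA", 2730000),
      locus("qseC", 3170000)
    )
  )
}
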