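#' Expand vertex positions to per-nucleotide coordinates
#'
#' Maps a (typically converged) vertex layout back onto the nucleotides,
#' honouring the drawing conventions the compressed graph was designed for:
#' the two bases of each pair sit symmetrically about their vertex,
#' perpendicular to the local stem axis and `config$pair_width` apart, so
#' pair midpoints coincide with the (equally spaced) vertex positions;
#' unpaired loop nucleotides sit on their loop's circle, at the angular
#' slots of the loop's perimeter walk, in sequence order between the
#' flanking stem anchors.
#'
#' The stem axis at a base-pair vertex is the direction between its two
#' stem-side neighbours' positions (single-neighbour direction at a lone
#' pair's free end). The y axis follows the SVG convention (downwards) when
#' rendered; coordinates themselves are plain Cartesian.
#'
#' @param graph a `compressed_graph` built from a structure.
#' @param state a [layout_state()].
#' @param config a [sim_config()].
#' @return a list of class `nucleotide_layout`: `coordinates` (N x 2
#'   matrix, rows in sequence order) and `n`.
#' @export
place_nucleotides <- function(graph, state, config) {
  if (is.null(graph$structure))
    stop("placement requires a graph built from a structure")
  P <- state$positions
  n <- graph$n
  coords <- matrix(NA_real_, n, 2L)
  w <- config$pair_width

  for (v in seq_along(graph$kind)) {
    if (graph$is_loop[v]) next
    pr <- graph$pair[[v]]
    a <- graph$bp_outer[v]; b <- graph$bp_inner[v]
    dir <- if (!is.na(a) && !is.na(b)) P[b, ] - P[a, ]
           else if (!is.na(b)) P[b, ] - P[v, ]
           else P[v, ] - P[a, ]
    nrm <- sqrt(sum(dir^2))
    dir <- if (nrm < .DIST_TOL) c(1, 0) else dir / nrm
    perp <- c(-dir[2L], dir[1L])
    coords[pr[1L], ] <- P[v, ] + (w / 2) * perp
    coords[pr[2L], ] <- P[v, ] - (w / 2) * perp
  }

  for (v in graph$loop_ids) {
    nt_slot <- graph$loop_nt_slot[[v]]
    if (base::length(nt_slot) == 0L) next
    m <- graph$loop_slots[v]
    radius <- loop_radius(graph, v, config)
    stems <- graph$loop_stem_slot[[v]]
    if (base::length(stems) > 0L) {
      theta0 <- .loop_orientation(P, graph, v)
      ref_slot <- stems[1L]
    } else {
      theta0 <- 0
      ref_slot <- 0
    }
    ang <- theta0 + 2 * pi * (nt_slot - ref_slot) / m
    idx <- as.integer(names(nt_slot))
    coords[idx, 1L] <- P[v, 1L] + radius * cos(ang)
    coords[idx, 2L] <- P[v, 2L] + radius * sin(ang)
  }

  structure(list(coordinates = coords, n = n), class = "nucleotide_layout")
}

#' Render a nucleotide layout to SVG
#'
#' Writes a standalone SVG: the backbone as a polyline in sequence order,
#' one tick line per base pair, and one glyph (circle plus base letter) per
#' nucleotide. The canvas is fitted to the layout with a fixed margin; the
#' SVG y axis points down. Output is byte-deterministic for identical
#' layouts.
#'
#' @param layout a `nucleotide_layout`.
#' @param structure the originating [secondary_structure()] (for base
#'   letters and pair ticks).
#' @param path output file path.
#' @param scale pixels per layout unit.
#' @return `path`, invisibly.
#' @export
render_svg <- function(layout, structure, path, scale = 30) {
  xy <- layout$coordinates
  margin <- 2
  xmin <- min(xy[, 1L]) - margin; xmax <- max(xy[, 1L]) + margin
  ymin <- min(xy[, 2L]) - margin; ymax <- max(xy[, 2L]) + margin
  px <- function(x) sprintf("%.3f", (x - xmin) * scale)
  py <- function(y) sprintf("%.3f", (y - ymin) * scale)
  wpx <- sprintf("%.3f", (xmax - xmin) * scale)
  hpx <- sprintf("%.3f", (ymax - ymin) * scale)
  r_glyph <- sprintf("%.3f", 0.3 * scale)
  fs <- sprintf("%.3f", 0.4 * scale)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            wpx, hpx, wpx, hpx))
  if (layout$n > 1L) {
    pts <- paste(sprintf("%s,%s", px(xy[, 1L]), py(xy[, 2L])), collapse = " ")
    lines <- c(lines, sprintf(paste0("<polyline class=\"backbone\" ",
                                     "points=\"%s\" fill=\"none\" ",
                                     "stroke=\"#888888\" stroke-width=\"1\"/>"),
                              pts))
  }
  if (nrow(structure$pairs) > 0L) {
    for (r in seq_len(nrow(structure$pairs))) {
      i <- structure$pairs[r, 1L]; j <- structure$pairs[r, 2L]
      lines <- c(lines, sprintf(paste0("<line class=\"pair\" x1=\"%s\" ",
                                       "y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
                                       "stroke=\"#cc3333\" stroke-width=\"1\"/>"),
                                px(xy[i, 1L]), py(xy[i, 2L]),
                                px(xy[j, 1L]), py(xy[j, 2L])))
    }
  }
  bases <- strsplit(structure$sequence, "")[[1]]
  for (i in seq_len(layout$n)) {
    lines <- c(lines,
      sprintf(paste0("<circle class=\"nt\" cx=\"%s\" cy=\"%s\" r=\"%s\" ",
                     "fill=\"#ffffff\" stroke=\"#333333\" stroke-width=\"1\"/>"),
              px(xy[i, 1L]), py(xy[i, 2L]), r_glyph),
      sprintf(paste0("<text x=\"%s\" y=\"%s\" font-size=\"%s\" ",
                     "font-family=\"monospace\" text-anchor=\"middle\" ",
                     "dominant-baseline=\"central\">%s</text>"),
              px(xy[i, 1L]), py(xy[i, 2L]), fs, bases[i]))
  }
  lines <- c(lines, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# proper segment-segment intersection (shared endpoints excluded by caller);
# vectorised over rows of the two endpoint matrices
.segments_intersect <- function(a1, a2, b1, b2) {
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(b1[, 1L], b1[, 2L], b2[, 1L], b2[, 2L], a1[, 1L], a1[, 2L])
  d2 <- cross(b1[, 1L], b1[, 2L], b2[, 1L], b2[, 2L], a2[, 1L], a2[, 2L])
  d3 <- cross(a1[, 1L], a1[, 2L], a2[, 1L], a2[, 2L], b1[, 1L], b1[, 2L])
  d4 <- cross(a1[, 1L], a1[, 2L], a2[, 1L], a2[, 2L], b2[, 1L], b2[, 2L])
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  # collinear overlap: all cross products ~0 and projections overlap
  eps <- 1e-12
  col <- abs(d1) < eps & abs(d2) < eps & abs(d3) < eps & abs(d4) < eps
  if (any(col)) {
    olap <- function(p, q, r, s) pmax(pmin(p, q), pmin(r, s)) <
      pmin(pmax(p, q), pmax(r, s))
    col <- col & (olap(a1[, 1L], a2[, 1L], b1[, 1L], b2[, 1L]) |
                  olap(a1[, 2L], a2[, 2L], b1[, 2L], b2[, 2L]))
  }
  proper | col
}

#' Count crossings between drawn elements
#'
#' Treats the drawing as a set of segments — the N-1 backbone segments plus
#' one segment per base pair — and counts pairs of segments that intersect
#' while not sharing a nucleotide endpoint. 0 means an untangled layout;
#' the score is invariant under rigid motions of the whole layout.
#'
#' @param layout a `nucleotide_layout`.
#' @param structure the originating [secondary_structure()].
#' @return a non-negative integer crossing count.
#' @export
overlap_score <- function(layout, structure) {
  xy <- layout$coordinates
  n <- layout$n
  ends <- rbind(
    if (n > 1L) cbind(seq_len(n - 1L), 2:n) else matrix(integer(0), ncol = 2L),
    structure$pairs)
  m <- nrow(ends)
  if (m < 2L) return(0L)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  a <- idx[, 1L]; b <- idx[, 2L]
  shared <- ends[a, 1L] == ends[b, 1L] | ends[a, 1L] == ends[b, 2L] |
            ends[a, 2L] == ends[b, 1L] | ends[a, 2L] == ends[b, 2L]
  a <- a[!shared]; b <- b[!shared]
  if (base::length(a) == 0L) return(0L)
  hits <- .segments_intersect(xy[ends[a, 1L], , drop = FALSE],
                              xy[ends[a, 2L], , drop = FALSE],
                              xy[ends[b, 1L], , drop = FALSE],
                              xy[ends[b, 2L], , drop = FALSE])
  sum(hits)
}
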