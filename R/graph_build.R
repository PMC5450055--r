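#' Decompose a secondary structure into loops and base pairs
#'
#' Splits a pseudoknot-free structure into its structural elements: one
#' element per base pair, plus the loops that the stems delimit. Loops are
#' classified by the number of stems on their boundary: hairpin (1), bulge
#' (2, unpaired on one side only), internal (2, unpaired on both sides),
#' multiloop (>= 3). The exterior region is always materialised as a loop
#' element, even when it has no unpaired nucleotides, so the outermost stems
#' have an anchoring hub.
#'
#' Every nucleotide belongs to exactly one element: paired bases to their
#' `base_pair` element, unpaired bases to the surrounding loop. Loop elements
#' additionally record their *anchors* — the base pairs adjacent to the loop
#' on each incident stem — and an ordered *boundary* walk used to allocate
#' perimeter slots (one slot per unpaired base, two per incident stem) when
#' the loop is drawn as a circle.
#'
#' @param structure a [secondary_structure()].
#' @return a list of elements; each element is a list with fields `kind`,
#'   `members` and, for base pairs, `pair`, or, for loops, `anchors`
#'   (matrix of adjacent pairs) and `boundary` (ordered perimeter items).
#' @export
decompose_elements <- function(structure) {
  if (!validate_pseudoknot_free(structure))
    stop("pseudoknot: cannot decompose a structure with crossing pairs")
  pt <- structure$pair_table
  n <- structure$length
  elements <- list()

  if (nrow(structure$pairs) > 0L) {
    for (r in seq_len(nrow(structure$pairs))) {
      i <- structure$pairs[r, 1L]; j <- structure$pairs[r, 2L]
      elements[[base::length(elements) + 1L]] <-
        list(kind = "base_pair", members = c(i, j), pair = c(i, j))
    }
  }

  # walk the region strictly inside (i, j); i = j = 0 walks the exterior
  walk_region <- function(i, j) {
    members <- integer(0)
    children <- matrix(integer(0), ncol = 2L)
    boundary <- list()
    k <- if (i == 0L) 1L else i + 1L
    end <- if (i == 0L) n else j - 1L
    while (k <= end) {
      if (pt[k] == 0L) {
        members <- c(members, k)
        boundary[[base::length(boundary) + 1L]] <- list(type = "nt", index = k)
        k <- k + 1L
      } else {
        child <- c(k, pt[k])
        children <- rbind(children, child)
        boundary[[base::length(boundary) + 1L]] <-
          list(type = "stem", pair = child, closing = FALSE)
        k <- pt[k] + 1L
      }
    }
    list(members = members, children = children, boundary = boundary)
  }

  # loops closed by the innermost pair of each stem
  if (nrow(structure$pairs) > 0L) {
    for (r in seq_len(nrow(structure$pairs))) {
      i <- structure$pairs[r, 1L]; j <- structure$pairs[r, 2L]
      if (i + 1L < j && pt[i + 1L] == j - 1L) next  # stacked: no loop here
      reg <- walk_region(i, j)
      nstems <- 1L + nrow(reg$children)
      kind <- if (nstems == 1L) {
        "hairpin_loop"
      } else if (nstems == 2L) {
        k <- reg$children[1L, 1L]; l <- reg$children[1L, 2L]
        left <- k - i - 1L; right <- j - l - 1L
        if (left > 0L && right > 0L) "internal_loop" else "bulge_loop"
      } else {
        "multi_loop"
      }
      boundary <- c(list(list(type = "stem", pair = c(i, j), closing = TRUE)),
                    reg$boundary)
      anchors <- rbind(c(i, j), reg$children)
      dimnames(anchors) <- NULL
      elements[[base::length(elements) + 1L]] <-
        list(kind = kind, members = reg$members,
             anchors = anchors, boundary = boundary)
    }
  }

  # exterior region, always present
  reg <- walk_region(0L, 0L)
  anchors <- reg$children
  dimnames(anchors) <- NULL
  elements[[base::length(elements) + 1L]] <-
    list(kind = "exterior_loop", members = reg$members,
         anchors = anchors, boundary = reg$boundary)

  # deterministic order: minimal involved nucleotide, loops before base pairs
  key <- vapply(elements, function(e) {
    idx <- c(e$members, e$pair, as.vector(e$anchors))
    if (base::length(idx) == 0L) 0L else min(idx)
  }, integer(1))
  is_loop <- vapply(elements, function(e) e$kind != "base_pair", logical(1))
  elements[order(key, !is_loop)]
}

#' Build the compressed graph of a secondary structure
#'
#' Maps every loop and every stem base pair to a vertex and connects them
#' along the stems: consecutive base pairs within a stem share an edge, the
#' outer pair of each stem connects to the enclosing (parent) loop and the
#' inner pair to the loop it closes. For pseudoknot-free input the result is
#' a tree.
#'
#' @param structure a [secondary_structure()].
#' @return an object of class `compressed_graph`: fields `kind`, `is_loop`,
#'   `members`, `pair` (per vertex), `edges` (m x 2), `adjacency` (list of
#'   neighbour id vectors), `loop_ids`, `loop_slots` (perimeter slot count
#'   per loop vertex), per-loop boundary bookkeeping, `n` (nucleotide count)
#'   and the originating `structure`.
#' @examples
#' g <- build_compressed_graph(parse_dotbracket("((((....))))"))
#' g$kind
#' @export
build_compressed_graph <- function(structure) {
  elements <- decompose_elements(structure)
  nv <- base::length(elements)
  kind <- vapply(elements, `[[`, character(1), "kind")
  is_loop <- kind != "base_pair"

  # vertex lookup: base pair by its 5' index; loop by closing pair 5' index
  bp_of <- integer(structure$length)       # 5' index -> bp vertex id
  loop_of_closing <- integer(structure$length)  # closing 5' index -> loop id
  exterior_id <- NA_integer_
  for (v in seq_len(nv)) {
    e <- elements[[v]]
    if (e$kind == "base_pair") {
      bp_of[e$pair[1L]] <- v
    } else if (e$kind == "exterior_loop") {
      exterior_id <- v
    } else {
      closing <- e$boundary[[1L]]$pair
      loop_of_closing[closing[1L]] <- v
    }
  }

  edges <- matrix(integer(0), ncol = 2L)
  add_edge <- function(a, b) edges <<- rbind(edges, c(min(a, b), max(a, b)))

  pt <- structure$pair_table
  n <- structure$length
  if (nrow(structure$pairs) > 0L) {
    for (r in seq_len(nrow(structure$pairs))) {
      i <- structure$pairs[r, 1L]; j <- structure$pairs[r, 2L]
      # stacked neighbour inward
      if (i + 1L < j && pt[i + 1L] == j - 1L)
        add_edge(bp_of[i], bp_of[i + 1L])
      # innermost pair of a stem -> the loop it closes
      if (!(i + 1L < j && pt[i + 1L] == j - 1L))
        add_edge(bp_of[i], loop_of_closing[i])
    }
  }
  # outer pair of each stem -> parent loop (via loop boundaries)
  parent_loop <- rep(NA_integer_, nv)
  for (v in seq_len(nv)) {
    e <- elements[[v]]
    if (e$kind == "base_pair") next
    for (item in e$boundary) {
      if (item$type == "stem" && !isTRUE(item$closing)) {
        add_edge(v, bp_of[item$pair[1L]])
        parent_loop[bp_of[item$pair[1L]]] <- v
      }
    }
  }

  # stem-axis neighbours of each base-pair vertex: the vertex on its
  # exterior-facing side and the one on its loop-closing side
  bp_outer <- rep(NA_integer_, nv)
  bp_inner <- rep(NA_integer_, nv)
  if (nrow(structure$pairs) > 0L) {
    for (r in seq_len(nrow(structure$pairs))) {
      i <- structure$pairs[r, 1L]; j <- structure$pairs[r, 2L]
      v <- bp_of[i]
      bp_inner[v] <- if (i + 1L < j && pt[i + 1L] == j - 1L) bp_of[i + 1L]
                     else loop_of_closing[i]
      bp_outer[v] <- if (i > 1L && j < n && pt[i - 1L] == j + 1L) bp_of[i - 1L]
                     else parent_loop[v]
    }
  }
  if (nrow(edges) > 1L)
    edges <- unique(edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE])

  adjacency <- rep(list(integer(0)), nv)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adjacency[[a]] <- c(adjacency[[a]], b)
      adjacency[[b]] <- c(adjacency[[b]], a)
    }
    adjacency <- lapply(adjacency, sort)
  }

  # per-loop perimeter bookkeeping: slot count, stem slot centres (in units
  # of slots), unpaired-member slot centres, neighbour ids per stem
  loop_slots <- rep(NA_real_, nv)
  loop_stem_nbr <- vector("list", nv)
  loop_stem_slot <- vector("list", nv)
  loop_nt_slot <- vector("list", nv)
  for (v in seq_len(nv)) {
    e <- elements[[v]]
    if (e$kind == "base_pair") next
    slot <- 0
    stem_nbr <- integer(0); stem_slot <- numeric(0)
    nt_idx <- integer(0); nt_slot <- numeric(0)
    for (item in e$boundary) {
      if (item$type == "stem") {
        nbr <- if (isTRUE(item$closing)) bp_of[item$pair[1L]]
               else bp_of[item$pair[1L]]
        stem_nbr <- c(stem_nbr, nbr)
        stem_slot <- c(stem_slot, slot + 0.5)  # centre of its two slots
        slot <- slot + 2
      } else {
        nt_idx <- c(nt_idx, item$index)
        nt_slot <- c(nt_slot, slot)
        slot <- slot + 1
      }
    }
    loop_slots[v] <- slot
    loop_stem_nbr[[v]] <- stem_nbr
    loop_stem_slot[[v]] <- stem_slot
    loop_nt_slot[[v]] <- stats::setNames(nt_slot, nt_idx)
  }

  structure(list(
    kind = kind,
    is_loop = is_loop,
    members = lapply(elements, `[[`, "members"),
    pair = lapply(elements, function(e) e$pair),
    anchors = lapply(elements, function(e) e$anchors),
    edges = edges,
    adjacency = adjacency,
    loop_ids = which(is_loop),
    loop_slots = loop_slots,
    loop_stem_nbr = loop_stem_nbr,
    loop_stem_slot = loop_stem_slot,
    loop_nt_slot = loop_nt_slot,
    bp_outer = bp_outer,
    bp_inner = bp_inner,
    edge_r_ideal = rep(NA_real_, nrow(edges)),
    fixed = integer(0),
    n = structure$length,
    structure = structure
  ), class = "compressed_graph")
}

#' @export
print.compressed_graph <- function(x, ...) {
  cat(sprintf(
    "compressed_graph: %d vertexes (%d loops, %d base pairs), %d edges, %d nt\n",
    base::length(x$kind), sum(x$is_loop), sum(!x$is_loop), nrow(x$edges), x$n))
  invisible(x)
}

#' Build the detailed (nucleotide-per-vertex) graph
#'
#' Baseline representation: one vertex per nucleotide, one edge per covalent
#' backbone bond plus one per base pair. Kept for comparison with the
#' compressed graph; the layout engine operates on compressed graphs.
#'
#' @param structure a [secondary_structure()].
#' @return a list with `n_vertexes` and `edges` (m x 2 matrix).
#' @export
build_detailed_graph <- function(structure) {
  n <- structure$length
  backbone <- if (n > 1L) cbind(seq_len(n - 1L), 2:n)
              else matrix(integer(0), ncol = 2L)
  edges <- rbind(backbone, structure$pairs)
  list(n_vertexes = n, edges = edges)
}

#' Compression ratio of the compressed graph
#'
#' Ratio of compressed-graph vertex count to nucleotide count; below 1 for
#' any structure with a stem of stacked pairs, and `1/N` for a pairless
#' strand (a single exterior vertex).
#'
#' @param structure a [secondary_structure()].
#' @return a number in (0, 1].
#' @export
compression_ratio <- function(structure) {
  g <- build_compressed_graph(structure)
  base::length(g$kind) / structure$length
}

#' Export a compressed graph as an edge-list text table
#'
#' Debug helper: one line per vertex (`id kind members`) followed by one
#' line per edge (`a -- b`).
#'
#' @param graph a `compressed_graph`.
#' @return a character vector of lines.
#' @export
graph_edge_list <- function(graph) {
  vlines <- vapply(seq_along(graph$kind), function(v) {
    sprintf("vertex %d %s [%s]", v, graph$kind[v],
            paste(graph$members[[v]], collapse = ","))
  }, character(1))
  elines <- if (nrow(graph$edges) > 0L)
    sprintf("edge %d -- %d", graph$edges[, 1L], graph$edges[, 2L])
  else character(0)
  c(vlines, elines)
}

# internal: hand-assembled graph for synthetic test systems
.graph_from_parts <- function(kind, edges, edge_r_ideal = NULL,
                              loop_slots = NULL, fixed = integer(0)) {
  nv <- base::length(kind)
  is_loop <- kind != "base_pair"
  edges <- matrix(as.integer(edges), ncol = 2L)
  adjacency <- rep(list(integer(0)), nv)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adjacency[[a]] <- c(adjacency[[a]], b)
      adjacency[[b]] <- c(adjacency[[b]], a)
    }
  }
  if (is.null(edge_r_ideal)) edge_r_ideal <- rep(NA_real_, nrow(edges))
  if (is.null(loop_slots)) loop_slots <- ifelse(is_loop, 3, NA_real_)
  structure(list(
    kind = kind, is_loop = is_loop,
    members = rep(list(integer(0)), nv),
    pair = rep(list(NULL), nv),
    anchors = rep(list(NULL), nv),
    edges = edges, adjacency = adjacency,
    loop_ids = which(is_loop),
    loop_slots = loop_slots,
    loop_stem_nbr = rep(list(integer(0)), nv),
    loop_stem_slot = rep(list(numeric(0)), nv),
    loop_nt_slot = rep(list(numeric(0)), nv),
    bp_outer = rep(NA_integer_, nv),
    bp_inner = rep(NA_integer_, nv),
    edge_r_ideal = edge_r_ideal,
    fixed = as.integer(fixed),
    n = nv, structure = NULL
  ), class = "compressed_graph")
}
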