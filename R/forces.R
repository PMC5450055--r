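#' Simulation configuration
#'
#' Bundles every tunable of the force model and the integrators. `K` scales
#' the spring-like attraction along graph edges, `G` the inverse-square
#' repulsion acting between loop vertexes only (base pairs never repel).
#' `dt` is the integration time-step and `epsilon` the equilibrium
#' threshold: the simulation stops once every free vertex's net force
#' magnitude is at most `epsilon`.
#'
#' Distances are expressed in layout units of one `nucleotide_spacing`: the
#' rest length between consecutive base pairs of a stem is
#' `r_ideal_bp = nucleotide_spacing`, and a loop whose perimeter carries `m`
#' slots (one per unpaired base, two per incident stem) is drawn with radius
#' `s / (2 sin(pi / max(m, 3)))` so that adjacent slots sit one spacing
#' apart on its circle; that radius is also the rest length of the loop's
#' edges to its stems.
#'
#' @param integrator `"forward"` (explicit) or `"backward"` (implicit).
#' @param K attraction coefficient (> 0).
#' @param G repulsion coefficient (>= 0).
#' @param dt time-step (> 0).
#' @param epsilon stopping threshold on the net-force magnitude (>= 0).
#' @param newton_iterations Newton iteration cap per vertex and step
#'   (backward integrator only).
#' @param nucleotide_spacing layout unit; target arc spacing on loops.
#' @param r_ideal_bp rest length between consecutive stem base pairs.
#' @param pair_width distance between the two bases of a drawn pair.
#' @param max_iterations cap on time-steps.
#' @param use_ideal_positions if `TRUE`, base-pair vertexes are attracted to
#'   their stem's anchor point on the parent loop's circumference instead of
#'   the loop centre, fixing stem orientation.
#' @return an object of class `sim_config`.
#' @seealso [preset_config()] for the two shipped configurations.
#' @export
sim_config <- function(integrator = c("backward", "forward"),
                       K = 10, G = 0.01, dt = 3, epsilon = 0.3,
                       newton_iterations = 5L,
                       nucleotide_spacing = 1,
                       r_ideal_bp = nucleotide_spacing,
                       pair_width = nucleotide_spacing,
                       max_iterations = if (match.arg(integrator) == "forward")
                         200000L else 2000L,
                       use_ideal_positions = TRUE) {
  integrator <- match.arg(integrator)
  stopifnot(K > 0, G >= 0, dt > 0, epsilon >= 0,
            newton_iterations >= 0, nucleotide_spacing > 0,
            max_iterations >= 1)
  structure(list(
    integrator = integrator, K = K, G = G, dt = dt, epsilon = epsilon,
    newton_iterations = as.integer(newton_iterations),
    nucleotide_spacing = nucleotide_spacing,
    r_ideal_bp = r_ideal_bp, pair_width = pair_width,
    max_iterations = as.integer(max_iterations),
    use_ideal_positions = use_ideal_positions
  ), class = "sim_config")
}

#' The two shipped configurations
#'
#' Configuration 1 is the explicit (Forward Euler) setup at the largest
#' time-step it supports without losing stability; configuration 2 the
#' implicit (Backward Euler) setup, whose time-step is 300 times larger and
#' whose per-vertex Newton solve is capped at 5 iterations.
#'
#' @param which 1 (explicit) or 2 (implicit).
#' @return a [sim_config()].
#' @examples
#' preset_config(2)$dt / preset_config(1)$dt
#' @export
preset_config <- function(which) {
  if (!(base::length(which) == 1L && which %in% c(1, 2)))
    stop("'which' must be 1 or 2")
  if (which == 1) {
    sim_config(integrator = "forward", K = 10.0, G = 0.01, dt = 0.01,
               epsilon = 0.0001, newton_iterations = 0L,
               max_iterations = 200000L)
  } else {
    sim_config(integrator = "backward", K = 10.0, G = 0.01, dt = 3.0,
               epsilon = 0.3, newton_iterations = 5L,
               max_iterations = 2000L)
  }
}

# degenerate-geometry signal: raised when interacting points coincide;
# the engine catches it and applies a deterministic jitter
.degenerate <- function(ids) {
  cond <- structure(
    class = c("rnaspring_degenerate", "error", "condition"),
    list(message = sprintf("coincident vertexes: %s",
                           paste(unique(ids), collapse = ",")),
         call = NULL, ids = unique(ids)))
  stop(cond)
}

.DIST_TOL <- 1e-12

#' Unit vector between two points
#'
#' Returns the unit vector pointing from `p_j` toward `p_i`.
#'
#' @param p_i,p_j numeric length-2 positions.
#' @return numeric length-2 vector of norm 1.
#' @export
unit_vector <- function(p_i, p_j) {
  d <- p_i - p_j
  nrm <- sqrt(sum(d^2))
  if (nrm < .DIST_TOL) .degenerate(NA_integer_)
  d / nrm
}

#' Inverse-square repulsion force
#'
#' Force exerted on the vertex at `p_i` by the vertex at `p_j`:
#' magnitude `G / |p_i - p_j|^2`, directed away from `p_j`. In the layout
#' model only loop vertexes exchange repulsion.
#'
#' @param p_i,p_j numeric length-2 positions.
#' @param G repulsion coefficient.
#' @return numeric length-2 force vector.
#' @export
repulsion <- function(p_i, p_j, G) {
  d2 <- sum((p_i - p_j)^2)
  if (d2 < .DIST_TOL^2) .degenerate(NA_integer_)
  (G / d2) * unit_vector(p_i, p_j)
}

#' Spring-like attraction force
#'
#' Force on the vertex at `p_i` pulling it toward (or pushing it away from)
#' `p_j` so that their separation relaxes to `r_ideal`:
#' `K * ((p_j - p_i) + r_ideal * U(p_i, p_j))`. Vanishes exactly at the
#' ideal separation.
#'
#' @param p_i,p_j numeric length-2 positions.
#' @param K attraction coefficient.
#' @param r_ideal rest length.
#' @return numeric length-2 force vector.
#' @export
attraction <- function(p_i, p_j, K, r_ideal) {
  K * ((p_j - p_i) + r_ideal * unit_vector(p_i, p_j))
}

#' Drawing radius of a loop vertex
#'
#' @param graph a `compressed_graph`.
#' @param vertex a loop vertex id.
#' @param config a [sim_config()].
#' @return the loop's circle radius in layout units.
#' @export
loop_radius <- function(graph, vertex, config) {
  if (!graph$is_loop[vertex]) stop("vertex is not a loop")
  m <- graph$loop_slots[vertex]
  config$nucleotide_spacing / (2 * sin(pi / max(m, 3)))
}

# rest length of each undirected edge under the centre-attraction rule:
# loop radius when one endpoint is a loop, r_ideal_bp for stacked pairs;
# explicit per-edge overrides (synthetic systems) win
.edge_rest_lengths <- function(graph, config) {
  m <- nrow(graph$edges)
  if (m == 0L) return(numeric(0))
  rest <- graph$edge_r_ideal
  for (e in seq_len(m)) {
    if (!is.na(rest[e])) next
    a <- graph$edges[e, 1L]; b <- graph$edges[e, 2L]
    rest[e] <- if (graph$is_loop[a]) loop_radius(graph, a, config)
               else if (graph$is_loop[b]) loop_radius(graph, b, config)
               else config$r_ideal_bp
  }
  rest
}

# orientation angle of a loop's anchor frame: the rotation that best fits
# (least-squares on the circle) the designed anchor directions to the
# current directions of all incident stems. For a single-stem loop this is
# exactly the direction to that stem's base-pair vertex; with several stems
# it is the circular mean of the per-stem estimates, so the anchor forces
# exert no net torque about the loop and cannot lock onto one reference
# stem. NA when the loop has no incident stem.
.loop_orientation <- function(positions, graph, v) {
  nbr <- graph$loop_stem_nbr[[v]]
  if (base::length(nbr) == 0L) return(NA_real_)
  dx <- positions[nbr, 1L] - positions[v, 1L]
  dy <- positions[nbr, 2L] - positions[v, 2L]
  if (any(dx * dx + dy * dy < .DIST_TOL^2)) {
    bad <- which(dx * dx + dy * dy < .DIST_TOL^2)[1L]
    .degenerate(c(v, nbr[bad]))
  }
  slots <- graph$loop_stem_slot[[v]]
  delta <- 2 * pi * (slots - slots[1L]) / graph$loop_slots[v]
  theta_s <- atan2(dy, dx) - delta
  sx <- sum(cos(theta_s)); sy <- sum(sin(theta_s))
  if (sx * sx + sy * sy < 1e-18)  # perfectly antagonistic: fall back
    return(atan2(dy[1L], dx[1L]))
  atan2(sy, sx)
}

#' Ideal anchor positions of the stems protruding from a loop
#'
#' Each stem incident to a loop has an ideal position: a point on the loop's
#' circle at the angular slot the stem occupies in the loop's perimeter walk.
#' Anchors rotate rigidly with the loop's current orientation, taken as the
#' direction from the loop centre to its first boundary stem's base-pair
#' vertex. With ideal-position attraction enabled, terminal base-pair
#' vertexes are attracted to these anchors rather than to the loop centre,
#' which fixes each stem's orientation relative to its parent loop.
#'
#' @param loop_vertex loop vertex id.
#' @param state a `layout_state`.
#' @param graph a `compressed_graph`.
#' @param config a [sim_config()].
#' @return a matrix with one row per incident stem (rownames = neighbouring
#'   base-pair vertex id) and columns `x`, `y`; zero rows when the loop has
#'   no incident stems.
#' @export
compute_ideal_positions <- function(loop_vertex, state, graph, config) {
  positions <- state$positions
  nbr <- graph$loop_stem_nbr[[loop_vertex]]
  out <- matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y")))
  if (base::length(nbr) == 0L) return(out)
  theta0 <- .loop_orientation(positions, graph, loop_vertex)
  slots <- graph$loop_stem_slot[[loop_vertex]]
  m <- graph$loop_slots[loop_vertex]
  radius <- loop_radius(graph, loop_vertex, config)
  ang <- theta0 + 2 * pi * (slots - slots[1L]) / m
  out <- cbind(x = positions[loop_vertex, 1L] + radius * cos(ang),
               y = positions[loop_vertex, 2L] + radius * sin(ang))
  rownames(out) <- as.character(nbr)
  out
}

#' Layout state
#'
#' Positions of every graph vertex at one time-step.
#'
#' @param positions numeric matrix, one row per vertex, columns x and y.
#' @param time simulation time.
#' @param step_index time-step counter.
#' @return an object of class `layout_state`.
#' @export
layout_state <- function(positions, time = 0, step_index = 0L) {
  positions <- matrix(as.numeric(positions), ncol = 2L)
  structure(list(positions = positions, time = time,
                 step_index = as.integer(step_index)),
            class = "layout_state")
}

# --- vectorised force core ------------------------------------------------
#
# Sums, for every vertex i evaluated at its row of Q, the repulsion from all
# loop vertexes (frozen at Pfix) and the attraction along incident edges
# toward neighbours frozen at Pfix (or toward precomputed anchor targets).
# Returns the force matrix S (nv x 2) and, on request, the per-vertex 2x2
# blocks of partial derivatives with respect to the vertex's own
# coordinates, as columns (dSx/dx, dSx/dy, dSy/dx, dSy/dy).
#
# Q = Pfix gives the explicit forces of the forward step and the Eq-4 test;
# Q = a Newton iterate gives the implicit residual's force part.
.force_sums <- function(Q, Pfix, graph, config, targets = NULL,
                        jacobian = FALSE) {
  nv <- nrow(Q)
  S <- matrix(0, nv, 2L)
  J <- if (jacobian) matrix(0, nv, 4L) else NULL
  K <- config$K; G <- config$G

  L <- graph$loop_ids
  if (G > 0 && base::length(L) > 1L) {
    dx <- outer(Q[L, 1L], Pfix[L, 1L], "-")
    dy <- outer(Q[L, 2L], Pfix[L, 2L], "-")
    d2 <- dx * dx + dy * dy
    diag(d2) <- Inf
    if (any(d2 < .DIST_TOL^2)) {
      bad <- which(d2 < .DIST_TOL^2, arr.ind = TRUE)[1L, ]
      .degenerate(L[bad])
    }
    d3 <- d2^1.5
    S[L, 1L] <- S[L, 1L] + G * rowSums(dx / d3)
    S[L, 2L] <- S[L, 2L] + G * rowSums(dy / d3)
    if (jacobian) {
      d5 <- d2^2.5
      J[L, 1L] <- J[L, 1L] + G * rowSums((dy * dy - 2 * dx * dx) / d5)
      J[L, 2L] <- J[L, 2L] + G * rowSums(-3 * dx * dy / d5)
      J[L, 3L] <- J[L, 3L] + G * rowSums(-3 * dx * dy / d5)
      J[L, 4L] <- J[L, 4L] + G * rowSums((dx * dx - 2 * dy * dy) / d5)
    }
  }

  if (nrow(graph$edges) > 0L) {
    if (is.null(targets)) targets <- .edge_targets(Pfix, graph, config)
    from <- targets$from
    tx <- targets$x; ty <- targets$y; rest <- targets$rest
    dx <- Q[from, 1L] - tx
    dy <- Q[from, 2L] - ty
    d2 <- dx * dx + dy * dy
    pos_rest <- rest > 0
    if (any(pos_rest & d2 < .DIST_TOL^2)) {
      bad <- which(pos_rest & d2 < .DIST_TOL^2)[1L]
      .degenerate(c(from[bad], targets$to[bad]))
    }
    d <- sqrt(d2)
    ux <- ifelse(pos_rest, dx / d, 0)
    uy <- ifelse(pos_rest, dy / d, 0)
    ax <- K * (-dx + rest * ux)
    ay <- K * (-dy + rest * uy)
    grp <- sort(unique(from))
    S[grp, 1L] <- S[grp, 1L] + rowsum(ax, from)[, 1L]
    S[grp, 2L] <- S[grp, 2L] + rowsum(ay, from)[, 1L]
    if (jacobian) {
      d3 <- ifelse(pos_rest, d2 * d, 1)
      jxx <- K * (-1 + rest * ifelse(pos_rest, dy * dy / d3, 0))
      jxy <- K * rest * ifelse(pos_rest, -dx * dy / d3, 0)
      jyy <- K * (-1 + rest * ifelse(pos_rest, dx * dx / d3, 0))
      J[grp, 1L] <- J[grp, 1L] + rowsum(jxx, from)[, 1L]
      J[grp, 2L] <- J[grp, 2L] + rowsum(jxy, from)[, 1L]
      J[grp, 3L] <- J[grp, 3L] + rowsum(jxy, from)[, 1L]
      J[grp, 4L] <- J[grp, 4L] + rowsum(jyy, from)[, 1L]
    }
  }
  list(S = S, J = J)
}

# directed-edge attraction targets at the frozen positions Pfix: for each
# directed edge (from -> to) the target point, its rest length, and ids.
# Base-pair -> loop edges use the loop's anchor for that stem (rest 0) when
# ideal positions are enabled; every other edge targets the neighbour's
# centre with the centre-rule rest length.
.edge_targets <- function(Pfix, graph, config) {
  e <- graph$edges
  m <- nrow(e)
  rest_und <- .edge_rest_lengths(graph, config)
  from <- c(e[, 1L], e[, 2L])
  to <- c(e[, 2L], e[, 1L])
  rest <- c(rest_und, rest_und)
  tx <- Pfix[to, 1L]
  ty <- Pfix[to, 2L]
  if (config$use_ideal_positions) {
    anchor_mode <- graph$is_loop[to] & !graph$is_loop[from]
    reaction_mode <- graph$is_loop[from] & !graph$is_loop[to]
    if (any(anchor_mode)) {
      for (v in unique(to[anchor_mode])) {
        nbr <- graph$loop_stem_nbr[[v]]
        if (base::length(nbr) == 0L) next
        theta0 <- .loop_orientation(Pfix, graph, v)
        slots <- graph$loop_stem_slot[[v]]
        ang <- theta0 + 2 * pi * (slots - slots[1L]) / graph$loop_slots[v]
        radius <- loop_radius(graph, v, config)
        offx <- radius * cos(ang)
        offy <- radius * sin(ang)
        # base pair -> anchor point on the loop circle (rest 0)
        sel <- which(anchor_mode & to == v)
        match_idx <- match(from[sel], nbr)
        ok <- !is.na(match_idx)
        tx[sel[ok]] <- Pfix[v, 1L] + offx[match_idx[ok]]
        ty[sel[ok]] <- Pfix[v, 2L] + offy[match_idx[ok]]
        rest[sel[ok]] <- 0
        # action-reaction: the loop is pulled so that its anchor meets the
        # base pair, i.e. toward P_bp - anchor_offset (rest 0); without the
        # reaction the anchor springs exert a net thrust on the molecule
        # and the layout drifts indefinitely instead of equilibrating
        sel2 <- which(reaction_mode & from == v)
        match_idx2 <- match(to[sel2], nbr)
        ok2 <- !is.na(match_idx2)
        tx[sel2[ok2]] <- Pfix[to[sel2[ok2]], 1L] - offx[match_idx2[ok2]]
        ty[sel2[ok2]] <- Pfix[to[sel2[ok2]], 2L] - offy[match_idx2[ok2]]
        rest[sel2[ok2]] <- 0
      }
    }
  }
  list(from = from, to = to, x = tx, y = ty, rest = rest)
}

#' Net force on one vertex
#'
#' Reference per-vertex implementation of the force sums: a loop vertex
#' receives repulsion from every other loop plus attraction along each of
#' its edges; a base-pair vertex receives the attraction terms only. With
#' ideal positions enabled, a base-pair vertex's attraction toward a loop
#' neighbour targets that loop's anchor for the stem (rest length 0) rather
#' than the loop centre.
#'
#' @param vertex_id vertex id.
#' @param state a [layout_state()].
#' @param graph a `compressed_graph`.
#' @param config a [sim_config()].
#' @return numeric length-2 force vector.
#' @export
net_force <- function(vertex_id, state, graph, config) {
  P <- state$positions
  f <- c(0, 0)
  if (graph$is_loop[vertex_id] && config$G > 0) {
    for (j in setdiff(graph$loop_ids, vertex_id))
      f <- f + repulsion(P[vertex_id, ], P[j, ], config$G)
  }
  rest_und <- .edge_rest_lengths(graph, config)
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges[e, 1L]; b <- graph$edges[e, 2L]
    j <- if (a == vertex_id) b else if (b == vertex_id) a else next
    if (config$use_ideal_positions && graph$is_loop[j] &&
        !graph$is_loop[vertex_id]) {
      anchors <- compute_ideal_positions(j, state, graph, config)
      row <- match(as.character(vertex_id), rownames(anchors))
      if (!is.na(row)) {
        f <- f + config$K * (anchors[row, ] - P[vertex_id, ])
        next
      }
    }
    if (config$use_ideal_positions && graph$is_loop[vertex_id] &&
        !graph$is_loop[j]) {
      anchors <- compute_ideal_positions(vertex_id, state, graph, config)
      row <- match(as.character(j), rownames(anchors))
      if (!is.na(row)) {
        # reaction of the anchor spring acting on the base-pair neighbour
        f <- f + config$K * (P[j, ] - anchors[row, ])
        next
      }
    }
    f <- f + attraction(P[vertex_id, ], P[j, ], config$K, rest_und[e])
  }
  unname(f)
}

# all net forces at once (vectorised); rows of fixed vertexes still computed
.net_forces <- function(positions, graph, config, targets = NULL) {
  .force_sums(positions, positions, graph, config, targets = targets)$S
}

#' Equilibrium test
#'
#' `TRUE` iff every free vertex's net force magnitude is at most
#' `config$epsilon` (pinned vertexes are excluded: their reaction force is
#' external).
#'
#' @inheritParams net_force
#' @return logical.
#' @export
is_equilibrium <- function(state, graph, config) {
  S <- .net_forces(state$positions, graph, config)
  free <- setdiff(seq_len(nrow(S)), graph$fixed)
  all(sqrt(rowSums(S[free, , drop = FALSE]^2)) <= config$epsilon)
}
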