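# Independent oracles used across the test files. These deliberately do NOT
# share code with the package internals they check.

# Brute-force recursive interval decomposition over the pair table:
# descends each stem pair-by-pair and classifies the loop each innermost
# pair closes. Returns loop elements as list(kind, members sorted).
oracle_loops <- function(structure) {
  pt <- structure$pair_table
  n <- structure$length
  out <- list()
  classify <- function(closing, members, stems) {
    if (is.null(closing)) return("exterior_loop")
    if (length(stems) == 0L) return("hairpin_loop")
    if (length(stems) >= 2L) return("multi_loop")
    st <- stems[[1L]]
    left <- st[1L] - closing[1L] - 1L
    right <- closing[2L] - st[2L] - 1L
    if (left > 0L && right > 0L) "internal_loop" else "bulge_loop"
  }
  walk <- function(i, j, closing) {
    members <- integer(0)
    stems <- list()
    k <- i
    while (k <= j) {
      if (pt[k] == 0L) {
        members <- c(members, k)
        k <- k + 1L
      } else {
        stems[[length(stems) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      }
    }
    out[[length(out) + 1L]] <<-
      list(kind = classify(closing, members, stems),
           members = sort(members))
    for (st in stems) {
      a <- st[1L]; b <- st[2L]
      while (a + 1L < b - 1L && pt[a + 1L] == b - 1L) {
        a <- a + 1L; b <- b - 1L
      }
      walk(a + 1L, b - 1L, c(a, b))
    }
  }
  walk(1L, n, NULL)
  out
}

# canonical sortable fingerprint of a loop element set
loop_fingerprint <- function(loops) {
  sort(vapply(loops, function(e)
    paste0(e$kind, ":", paste(sort(e$members), collapse = ",")),
    character(1)))
}

# literal term-by-term force sums (centre attraction only): repulsion over
# all other loops for a loop vertex, attraction along every incident edge
# with the rest-length rule recomputed here from first principles
oracle_net_force <- function(v, positions, graph, config) {
  spacing <- config$nucleotide_spacing
  radius_of <- function(u)
    spacing / (2 * sin(pi / max(graph$loop_slots[u], 3)))
  f <- c(0, 0)
  if (graph$is_loop[v]) {
    for (j in setdiff(graph$loop_ids, v)) {
      d <- positions[v, ] - positions[j, ]
      nd <- sqrt(sum(d^2))
      f <- f + (config$G / nd^2) * (d / nd)
    }
  }
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges[e, 1L]; b <- graph$edges[e, 2L]
    j <- if (a == v) b else if (b == v) a else next
    r <- graph$edge_r_ideal[e]
    if (is.na(r)) {
      r <- if (graph$is_loop[a]) radius_of(a)
           else if (graph$is_loop[b]) radius_of(b)
           else config$r_ideal_bp
    }
    d <- positions[v, ] - positions[j, ]
    nd <- sqrt(sum(d^2))
    f <- f + config$K * ((positions[j, ] - positions[v, ]) + r * d / nd)
  }
  f
}

# central finite differences of the implicit residual
fd_jacobian <- function(q, v, state, graph, config, h = 1e-6) {
  fd <- matrix(0, 2, 2)
  for (c in 1:2) {
    e <- c(0, 0); e[c] <- h
    fd[, c] <- (backward_residual(q + e, v, state, graph, config) -
                backward_residual(q - e, v, state, graph, config)) / (2 * h)
  }
  fd
}

# single free particle attached to a fixed neighbour: the scalar spring
scalar_spring <- function(x0 = 2, r_ideal = 1) {
  g <- rnaspring:::.graph_from_parts(
    kind = c("hairpin_loop", "base_pair"),
    edges = cbind(1L, 2L), edge_r_ideal = r_ideal, fixed = 1L)
  list(graph = g, state = layout_state(rbind(c(0, 0), c(x0, 0))))
}

spring_config <- function(integrator = "backward", dt = 3, K = 10, G = 0,
                          epsilon = 1e-4, max_iterations = 5000L) {
  sim_config(integrator = integrator, K = K, G = G, dt = dt,
             epsilon = epsilon, newton_iterations = 5L,
             max_iterations = max_iterations, use_ideal_positions = FALSE)
}
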