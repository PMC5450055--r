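# --- jitter wrapper -------------------------------------------------------
#
# The unit vector is undefined for coincident points. When a force
# evaluation raises the degenerate-geometry signal, the offending vertex is
# nudged by 1e-6 layout units in a fixed direction derived from its id, and
# the evaluation retried; deterministic, so layouts stay reproducible.
.with_jitter <- function(positions, graph, fn, max_retry = 8L) {
  nv <- nrow(positions)
  for (try in seq_len(max_retry)) {
    res <- tryCatch(list(ok = TRUE, value = fn(positions)),
                    rnaspring_degenerate = function(c)
                      list(ok = FALSE, ids = c$ids))
    if (res$ok) return(list(value = res$value, positions = positions))
    id <- max(res$ids, na.rm = TRUE)
    ang <- 2 * pi * id / nv
    positions[id, ] <- positions[id, ] +
      try * 1e-6 * c(cos(ang), sin(ang))
  }
  stop("coincident vertexes persist after jitter retries")
}

#' Advance one explicit (Forward Euler) time-step
#'
#' All vertexes move simultaneously by `dt` times their net force evaluated
#' at the current step; pinned vertexes stay put. Conditionally stable: on a
#' linearised spring of stiffness `K` the displacement error is multiplied
#' by `1 - dt*K` each step, so the scheme diverges once `|1 - dt*K| > 1`.
#'
#' @param state a [layout_state()].
#' @param graph a `compressed_graph`.
#' @param config a [sim_config()].
#' @return the updated `layout_state`.
#' @export
forward_euler_step <- function(state, graph, config) {
  P <- state$positions
  res <- .with_jitter(P, graph, function(pos)
    .net_forces(pos, graph, config))
  P <- res$positions
  S <- res$value
  free <- setdiff(seq_len(nrow(P)), graph$fixed)
  P[free, ] <- P[free, ] + config$dt * S[free, , drop = FALSE]
  layout_state(P, time = state$time + config$dt,
               step_index = state$step_index + 1L)
}

#' Residual of the implicit (Backward Euler) update for one vertex
#'
#' The implicit update requires the new position to satisfy
#' `P_new = P_old + dt * f(P_new)` with the neighbours and repelling loops
#' frozen at the old step; the residual
#' `F(q) = -q + P_old + dt * f(q)` is zero exactly at the solution.
#'
#' @param p_guess numeric length-2 candidate position.
#' @param vertex_id vertex id.
#' @param state the `layout_state` at the *old* step.
#' @param graph a `compressed_graph`.
#' @param config a [sim_config()].
#' @return numeric length-2 residual.
#' @export
backward_residual <- function(p_guess, vertex_id, state, graph, config) {
  P <- state$positions
  Q <- P
  Q[vertex_id, ] <- p_guess
  S <- .force_sums(Q, P, graph, config)$S
  unname(-p_guess + P[vertex_id, ] + config$dt * S[vertex_id, ])
}

#' Analytic Jacobian of the implicit residual
#'
#' The 2x2 matrix of partial derivatives of the residual with respect to the
#' candidate position's coordinates, assembled from the closed-form partials
#' of the repulsion, attraction and unit-vector terms.
#'
#' @inheritParams backward_residual
#' @return a 2x2 numeric matrix `D` with rows (dFx/dx, dFx/dy) and
#'   (dFy/dx, dFy/dy); `attr(,"det")` carries its determinant.
#' @export
compute_jacobian <- function(p_guess, vertex_id, state, graph, config) {
  P <- state$positions
  Q <- P
  Q[vertex_id, ] <- p_guess
  J <- .force_sums(Q, P, graph, config, jacobian = TRUE)$J[vertex_id, ]
  dt <- config$dt
  D <- matrix(c(-1 + dt * J[1L], dt * J[3L],
                dt * J[2L], -1 + dt * J[4L]), 2L, 2L)
  attr(D, "det") <- D[1L, 1L] * D[2L, 2L] - D[1L, 2L] * D[2L, 1L]
  D
}

#' One Newton update of an implicit-step iterate
#'
#' Solves the 2x2 linear system `D delta = F` in closed form and returns
#' `p_k - delta`. Signals a condition of class `rnaspring_singular` when
#' `|det D|` falls below 1e-12; the implicit step then falls back to the
#' explicit seed for that vertex.
#'
#' @param p_k current iterate (length-2).
#' @param residual residual `F(p_k)` (length-2).
#' @param jacobian 2x2 Jacobian matrix at `p_k`.
#' @return the next iterate (length-2).
#' @export
newton_step <- function(p_k, residual, jacobian) {
  det <- jacobian[1L, 1L] * jacobian[2L, 2L] -
         jacobian[1L, 2L] * jacobian[2L, 1L]
  if (abs(det) < 1e-12) {
    cond <- structure(class = c("rnaspring_singular", "error", "condition"),
                      list(message = "singular Jacobian in Newton step",
                           call = NULL))
    stop(cond)
  }
  dx <- (jacobian[2L, 2L] * residual[1L] - jacobian[1L, 2L] * residual[2L]) / det
  dy <- (jacobian[1L, 1L] * residual[2L] - jacobian[2L, 1L] * residual[1L]) / det
  unname(p_k - c(dx, dy))
}

# vectorised residuals for all vertexes: rows of Q are per-vertex guesses,
# everything else frozen at P (targets precomputed at P)
.residuals_all <- function(Q, P, graph, config, targets, jacobian = FALSE) {
  fs <- .force_sums(Q, P, graph, config, targets = targets,
                    jacobian = jacobian)
  R <- -Q + P + config$dt * fs$S
  J <- NULL
  if (jacobian) {
    dt <- config$dt
    J <- cbind(-1 + dt * fs$J[, 1L], dt * fs$J[, 2L],
               dt * fs$J[, 3L], -1 + dt * fs$J[, 4L])
  }
  list(R = R, J = J)
}

#' Advance one implicit (Backward Euler) time-step
#'
#' Each vertex solves its own two-dimensional implicit equation with
#' neighbours frozen at the old step, and all solutions are committed
#' simultaneously (a Jacobi sweep, so results are independent of vertex
#' order). Per vertex the root is found by Newton's method with the analytic
#' Jacobian: at most `config$newton_iterations` iterations, with early exit
#' once the residual norm falls below 1e-9. The Newton seed is the explicit
#' (Forward Euler) guess unless the unmodified current position has a
#' smaller residual — which happens when the explicit guess overshoots past
#' a neighbour onto the wrong branch of the residual — in which case the
#' current position seeds the solve. A vertex whose Jacobian turns singular
#' keeps its explicit seed for the step.
#'
#' On a linearised spring the implicit update multiplies the displacement
#' error by `1 / (1 + dt*K)` per step, below 1 for every positive `dt`:
#' unconditionally stable.
#'
#' @inheritParams forward_euler_step
#' @return the updated `layout_state`; `attr(,"newton_trace")` is a list
#'   with `residual_norms` (matrix, row `k` = per-vertex residual norm after
#'   `k` Newton iterations, row 0 = at the seed), `seed` (per-vertex,
#'   `"explicit"` or `"current"`) and `singular_fallback` (logical per
#'   vertex).
#' @export
backward_euler_step <- function(state, graph, config) {
  P0 <- state$positions
  nv <- nrow(P0)
  free <- setdiff(seq_len(nv), graph$fixed)

  res <- .with_jitter(P0, graph, function(pos) {
    targets <- .edge_targets(pos, graph, config)
    S0 <- .force_sums(pos, pos, graph, config, targets = targets)$S
    list(targets = targets, S0 = S0)
  })
  P <- res$positions
  targets <- res$value$targets
  S0 <- res$value$S0

  seed_fe <- P
  seed_fe[free, ] <- P[free, , drop = FALSE] +
    config$dt * S0[free, , drop = FALSE]

  # residual at the explicit seed vs at the current position; keep the
  # smaller as the Newton seed (overshoot guard, see Details)
  r_fe <- .residuals_all(seed_fe, P, graph, config, targets)$R
  r_cur <- config$dt * S0  # residual at Q = P collapses to dt * f(P)
  n_fe <- sqrt(rowSums(r_fe^2))
  n_cur <- sqrt(rowSums(r_cur^2))
  use_fe <- n_fe <= n_cur

  Q <- P
  Q[use_fe, ] <- seed_fe[use_fe, , drop = FALSE]
  Rcur <- r_cur
  Rcur[use_fe, ] <- r_fe[use_fe, , drop = FALSE]

  kmax <- config$newton_iterations
  norms <- matrix(NA_real_, nrow = kmax + 1L, ncol = nv)
  norms[1L, ] <- sqrt(rowSums(Rcur^2))
  singular <- rep(FALSE, nv)
  active <- rep(FALSE, nv)
  active[free] <- TRUE

  if (kmax > 0L) {
    for (k in seq_len(kmax)) {
      run <- active & norms[k, ] >= 1e-9
      if (!any(run)) {
        norms[k + 1L, ] <- norms[k, ]
        next
      }
      rj <- .residuals_all(Q, P, graph, config, targets, jacobian = TRUE)
      J <- rj$J
      det <- J[, 1L] * J[, 4L] - J[, 2L] * J[, 3L]
      sing <- run & abs(det) < 1e-12
      if (any(sing)) {
        # singular Jacobian: keep the explicit seed for this step
        Q[sing, ] <- seed_fe[sing, , drop = FALSE]
        singular <- singular | sing
        active[sing] <- FALSE
        run <- run & !sing
      }
      if (any(run)) {
        Fx <- rj$R[run, 1L]; Fy <- rj$R[run, 2L]
        dlx <- (J[run, 4L] * Fx - J[run, 2L] * Fy) / det[run]
        dly <- (J[run, 1L] * Fy - J[run, 3L] * Fx) / det[run]
        Q[run, 1L] <- Q[run, 1L] - dlx
        Q[run, 2L] <- Q[run, 2L] - dly
      }
      Rnew <- .residuals_all(Q, P, graph, config, targets)$R
      norms[k + 1L, ] <- sqrt(rowSums(Rnew^2))
      norms[k + 1L, !run] <- norms[k, !run]
    }
  }

  out <- layout_state(Q, time = state$time + config$dt,
                      step_index = state$step_index + 1L)
  attr(out, "newton_trace") <- list(
    residual_norms = norms,
    seed = ifelse(use_fe, "explicit", "current"),
    singular_fallback = singular)
  out
}
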