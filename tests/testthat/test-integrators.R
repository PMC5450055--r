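test_that("explicit step reproduces the closed-form spring update", {
  sys <- scalar_spring(x0 = 2)
  cfg <- spring_config("forward", dt = 0.01)
  st <- forward_euler_step(sys$state, sys$graph, cfg)
  expect_equal(st$positions[2, ], c(1.9, 0))
  expect_equal(st$positions[1, ], c(0, 0))  # pinned
  expect_equal(st$time, 0.01)
  expect_equal(st$step_index, 1L)

  # a state with zero net forces is a fixed point
  rest <- scalar_spring(x0 = 1)
  st2 <- forward_euler_step(rest$state, rest$graph, spring_config("forward"))
  expect_equal(st2$positions, rest$state$positions)
})

test_that("explicit update diverges once |1 - dt*K| exceeds 1", {
  # dt = 3, K = 10: error amplified by |1 - 30| = 29 each step
  sys <- scalar_spring(x0 = 2)
  cfg <- spring_config("forward", dt = 3)
  st <- sys$state
  err <- abs(st$positions[2, 1] - 1)
  for (i in 1:4) {
    st <- forward_euler_step(st, sys$graph, cfg)
    new_err <- abs(st$positions[2, 1] - 1)
    expect_gt(new_err, err)
    err <- new_err
  }
  expect_gt(err, 29^3)
})

test_that("implicit residual has the closed-form root and limits", {
  sys <- scalar_spring(x0 = 2)
  cfg <- spring_config("backward", dt = 3)
  # root of the linear branch: x = (x_n + dt*K*r_ideal) / (1 + dt*K) = 32/31
  expect_equal(backward_residual(c(32 / 31, 0), 2L, sys$state,
                                 sys$graph, cfg),
               c(0, 0), tolerance = 1e-12)
  # equilibrium is a fixed point: residual vanishes at the rest position
  rest <- scalar_spring(x0 = 1)
  expect_equal(backward_residual(c(1, 0), 2L, rest$state, rest$graph, cfg),
               c(0, 0), tolerance = 1e-12)
  # dt -> 0: residual collapses to P_n - p_guess
  cfg0 <- spring_config("backward", dt = 1e-12)
  expect_equal(backward_residual(c(1.25, 0.5), 2L, sys$state,
                                 sys$graph, cfg0),
               c(2 - 1.25, -0.5), tolerance = 1e-9)
})

test_that("analytic Jacobian matches hand values and finite differences", {
  sys <- scalar_spring(x0 = 2)
  cfg <- spring_config("backward", dt = 3)
  D <- compute_jacobian(c(2, 0), 2L, sys$state, sys$graph, cfg)
  # on-axis: dFx/dx = -1 - dt*K = -31; dFy/dy = -1 + dt*K*(-1 + r/d)
  expect_equal(D[1, 1], -31)
  expect_equal(D[1, 2], 0)
  expect_equal(D[2, 1], 0)
  expect_equal(D[2, 2], -16)

  # off-diagonal symmetry of the unit-vector contribution and FD agreement
  set.seed(11)
  for (i in 1:60) {
    s <- random_structure(sample(10:25, 1), seed = i, min_stem = 1)
    g <- build_compressed_graph(s)
    cfgr <- sim_config(dt = 3,
                       use_ideal_positions = (i %% 2 == 0))
    st <- init_vertex_positions(g, circular_layout(s, 1))
    st$positions <- st$positions +
      matrix(runif(2 * length(g$kind), -0.4, 0.4), ncol = 2)
    v <- sample(seq_along(g$kind), 1)
    q <- st$positions[v, ] + runif(2, -0.5, 0.5)
    D <- compute_jacobian(q, v, st, g, cfgr)
    expect_equal(D[1, 2], D[2, 1], tolerance = 1e-9)
    expect_equal(unclass(D), fd_jacobian(q, v, st, g, cfgr),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("a Newton step solves the 2x2 system and respects its guards", {
  # at the root nothing moves
  D <- matrix(c(-31, 0, 0, -16), 2, 2)
  expect_equal(newton_step(c(1, 2), c(0, 0), D), c(1, 2))
  # identity-like Jacobian: p + residual
  expect_equal(newton_step(c(1, 1), c(0.5, 0), -diag(2)), c(1.5, 1))
  # Newton is exact on the linear scalar spring branch
  sys <- scalar_spring(x0 = 2)
  cfg <- spring_config("backward", dt = 3)
  p0 <- c(2, 0)
  r0 <- backward_residual(p0, 2L, sys$state, sys$graph, cfg)
  D0 <- compute_jacobian(p0, 2L, sys$state, sys$graph, cfg)
  expect_equal(newton_step(p0, r0, D0), c(32 / 31, 0), tolerance = 1e-12)
  # singular Jacobian raises its signal
  expect_error(newton_step(c(0, 0), c(1, 0), matrix(0, 2, 2)),
               class = "rnaspring_singular")
})

test_that("implicit step lands on the closed-form spring solution", {
  sys <- scalar_spring(x0 = 2)
  cfg <- spring_config("backward", dt = 3)
  st <- backward_euler_step(sys$state, sys$graph, cfg)
  expect_equal(st$positions[2, ], c(32 / 31, 0), tolerance = 1e-9)
  tr <- attr(st, "newton_trace")
  # residual already at machine zero after a single Newton iteration
  expect_lt(tr$residual_norms[2, 2], 1e-9)

  # equilibrium state stays put
  rest <- scalar_spring(x0 = 1)
  str <- backward_euler_step(rest$state, rest$graph, cfg)
  expect_equal(str$positions, rest$state$positions, tolerance = 1e-12)
})

test_that("implicit update contracts for every positive time-step", {
  # amplification 1/(1 + dt*K) < 1: monotone approach, no divergence at 3.0
  for (dt in c(0.1, 3, 50)) {
    sys <- scalar_spring(x0 = 2)
    cfg <- spring_config("backward", dt = dt)
    st <- sys$state
    err <- 1
    # only the first steps: later errors sit at machine-epsilon scale
    for (i in 1:3) {
      st <- backward_euler_step(st, sys$graph, cfg)
      new_err <- abs(st$positions[2, 1] - 1)
      expect_equal(new_err / err, 1 / (1 + dt * 10), tolerance = 1e-6)
      err <- new_err
      if (err < 1e-10) break
    }
  }
})

test_that("explicit and implicit steps agree to O(dt^2) as dt shrinks", {
  cl <- cloverleaf_fixture()
  g <- build_compressed_graph(cl)
  st <- init_vertex_positions(g, circular_layout(cl, 1))
  diffs <- vapply(c(1e-2, 1e-3, 1e-4), function(dt) {
    cfg <- sim_config(dt = dt)
    max(abs(forward_euler_step(st, g, cfg)$positions -
            backward_euler_step(st, g, cfg)$positions))
  }, numeric(1))
  # Richardson-style: shrinking dt tenfold shrinks the gap ~ hundredfold
  expect_gt(diffs[1] / diffs[2], 30)
  expect_gt(diffs[2] / diffs[3], 30)
})

test_that("Newton residual norms contract on realistic states", {
  cfg <- preset_config(2)
  suite <- graded_suite(c(60, 90, 120), seed = 77L)
  total <- 0L
  nonincreasing <- 0L
  for (s in suite) {
    g <- build_compressed_graph(s)
    st <- init_vertex_positions(g, circular_layout(s, 1))
    for (k in 1:10) {
      st <- backward_euler_step(st, g, cfg)
      nt <- attr(st, "newton_trace")$residual_norms
      final <- apply(nt, 2, function(col) min(col, na.rm = TRUE))
      start <- nt[1, ]
      total <- total + length(start)
      nonincreasing <- nonincreasing + sum(final <= start + 1e-12)
    }
  }
  expect_gte(nonincreasing / total, 0.99)
})
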