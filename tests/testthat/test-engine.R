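test_that("circular layout spaces nucleotides evenly", {
  s4 <- secondary_structure(length = 4)
  xy <- circular_layout(s4, spacing = 2 * pi / 4)  # radius 1
  expect_equal(xy, rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
               tolerance = 1e-12)
  s1 <- secondary_structure(length = 1)
  xy1 <- circular_layout(s1, spacing = 1)
  expect_equal(xy1, cbind(1 / (2 * pi), 0), tolerance = 1e-12)
  # all consecutive chords equal (regular polygon)
  s <- secondary_structure(length = 17)
  xy17 <- circular_layout(s, spacing = 1)
  chords <- sqrt(rowSums(diff(xy17)^2))
  expect_equal(chords, rep(chords[1], length(chords)), tolerance = 1e-12)
})

test_that("vertex initialisation averages member positions", {
  g <- build_compressed_graph(parse_dotbracket("((....))"))
  s <- parse_dotbracket("((....))")
  nuc <- circular_layout(s, 1)
  st <- init_vertex_positions(g, nuc)
  for (v in seq_along(g$kind)) {
    idx <- g$members[[v]]
    if (length(idx) == 0) idx <- unique(as.vector(g$anchors[[v]]))
    expect_equal(st$positions[v, ], colMeans(nuc[idx, , drop = FALSE]))
  }
  expect_equal(st$time, 0)
  expect_equal(st$step_index, 0L)
  # empty-member exterior sits at the centroid of its stem anchors
  ext <- which(g$kind == "exterior_loop")
  expect_length(g$members[[ext]], 0L)
  expect_equal(st$positions[ext, ], colMeans(nuc[c(1, 8), ]))
})

test_that("simulation stops immediately at equilibrium", {
  sys <- two_loop_system(separation = 1)
  cfg <- spring_config("backward", G = 0, epsilon = 0.3)
  r <- simulate_layout(sys$graph, cfg, init_state = sys$state)
  expect_true(r$converged)
  expect_equal(r$iterations, 0L)
})

test_that("two connected loops settle where the forces balance", {
  sys <- two_loop_system(separation = 2)
  cfg <- spring_config("backward", dt = 3, K = 10, G = 0.01,
                       epsilon = 1e-8)
  r <- simulate_layout(sys$graph, cfg, init_state = sys$state)
  expect_true(r$converged)
  # oracle: scalar root of K(d - r_ideal) = G/d^2
  dstar <- uniroot(function(d) 10 * (d - 1) - 0.01 / d^2, c(1, 2),
                   tol = 1e-14)$root
  expect_equal(r$final_state$positions[2, 1], dstar, tolerance = 1e-6)
  # monotone tail: distance to equilibrium never increases after step 1
  st <- sys$state
  errs <- numeric(0)
  for (i in 1:12) {
    st <- backward_euler_step(st, sys$graph, cfg)
    errs <- c(errs, abs(st$positions[2, 1] - dstar))
  }
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("explicit two-loop run at dt = 3 is flagged diverged, not error", {
  sys <- two_loop_system(separation = 2)
  cfg <- spring_config("forward", dt = 3, G = 0.01, max_iterations = 500L)
  r <- simulate_layout(sys$graph, cfg, init_state = sys$state)
  expect_false(r$converged)
  expect_true(r$diverged)
})

test_that("stability scan brackets the explicit threshold dt*K < 2", {
  sys <- two_loop_system(separation = 2)
  base <- spring_config("forward", G = 0.01, epsilon = 1e-4,
                        max_iterations = 5000L)
  sc <- stability_scan(sys$graph, base, "forward",
                       c(0.01, 0.1, 0.19, 0.21, 3.0),
                       init_state = sys$state)
  expect_equal(sc$largest_stable, 0.19)
  expect_equal(sc$table$converged, c(TRUE, TRUE, TRUE, FALSE, FALSE))

  scb <- stability_scan(sys$graph, base, "backward",
                        c(0.01, 0.1, 0.19, 0.21, 3.0),
                        init_state = sys$state)
  expect_equal(scb$largest_stable, 3.0)
  expect_true(all(scb$table$converged))

  empty <- stability_scan(sys$graph, base, "forward", numeric(0),
                          init_state = sys$state)
  expect_null(empty$table)
  expect_true(is.na(empty$largest_stable))
})

test_that("the shipped configurations carry the documented parameters", {
  c1 <- preset_config(1)
  expect_equal(c1$integrator, "forward")
  expect_equal(c1$K, 10.0)
  expect_equal(c1$G, 0.01)
  expect_equal(c1$dt, 0.01)
  expect_equal(c1$epsilon, 0.0001)
  c2 <- preset_config(2)
  expect_equal(c2$integrator, "backward")
  expect_equal(c2$dt, 3.0)
  expect_equal(c2$epsilon, 0.3)
  expect_equal(c2$newton_iterations, 5L)
  expect_equal(c2$dt / c1$dt, 300)
})

test_that("simulation results are bit-identical across runs", {
  s <- random_structure(90, seed = 5)
  g <- build_compressed_graph(s)
  cfg <- preset_config(2)
  r1 <- simulate_layout(g, cfg)
  r2 <- simulate_layout(g, cfg)
  expect_identical(r1$final_state$positions, r2$final_state$positions)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$max_force_history, r2$max_force_history)
})

test_that("a converged run satisfies the certificate independently", {
  s <- random_structure(80, seed = 9)
  g <- build_compressed_graph(s)
  cfg <- preset_config(2)
  r <- simulate_layout(g, cfg)
  expect_true(r$converged)
  forces <- vapply(seq_along(g$kind), function(v)
    sqrt(sum(net_force(v, r$final_state, g, cfg)^2)), numeric(1))
  expect_true(all(forces <= cfg$epsilon))
})
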