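reference_config <- function() model_params(n = 300, m = 762, a = 0, b = 1, xmin = 2, c = 3.9)

test_that("initial networks honour the budget, floor and connectivity, deterministically", {
  p <- reference_config()
  net <- initial_network(p, seed = 1)
  expect_true(is_connected_network(net))
  expect_equal(igraph::ecount(net), 762)
  expect_gte(min(degree_sequence(net)), 2)
  net2 <- initial_network(p, seed = 1)
  expect_identical(edge_matrix(net), edge_matrix(net2))
  expect_false(identical(edge_matrix(net), edge_matrix(initial_network(p, seed = 2))))
  expect_error(model_params(n = 5, m = 3, c = 1.5), class = "paretonet_infeasible")
})

test_that("rewiring proposals respect the contracts and signal saturation", {
  p <- model_params(n = 10, m = 20, a = 0, b = 1, xmin = 1, c = 1.8)
  net <- initial_network(p, seed = 1)
  set.seed(1)
  for (i in 1:20) {
    mv <- propose_rewire(net, p)
    el <- edge_matrix(net)
    key <- el[, 1] * 10 + el[, 2]
    expect_true((min(mv$removed) * 10 + max(mv$removed)) %in% key)
    expect_false((min(mv$added) * 10 + max(mv$added)) %in% key)
    expect_false(mv$added[1] == mv$added[2])
  }
  # complete graph has no absent pair: saturation
  k4 <- fixture_network("complete", 4)
  pk <- model_params(n = 4, m = 6, a = 0, b = 1, xmin = 3, c = 1)
  expect_error(propose_rewire(k4, pk), class = "paretonet_saturated")
})

test_that("the acceptance rule follows the two-phase contract", {
  # optimise phase: better F2 with unchanged in-band gap is accepted
  expect_true(accept_move(list(f2 = 10, y = 3.93), list(f2 = 14, y = 3.93),
                          c = 3.9, tol = 0.05, phase = "optimise"))
  # optimise phase: better F2 but a worsened gap is rejected
  expect_false(accept_move(list(f2 = 10, y = 3.93), list(f2 = 14, y = 4.30),
                           c = 3.9, tol = 0.05, phase = "optimise"))
  # ... even a small worsening still inside the tolerance band
  expect_false(accept_move(list(f2 = 10, y = 3.93), list(f2 = 14, y = 3.94),
                           c = 3.9, tol = 0.05, phase = "optimise"))
  # optimise phase: F2 ties are rejected (strict greedy)
  expect_false(accept_move(list(f2 = 10, y = 3.93), list(f2 = 10, y = 3.91),
                           c = 3.9, tol = 0.05, phase = "optimise"))
  # constrain phase ignores F2 and wants a strictly smaller gap
  expect_true(accept_move(list(f2 = 10, y = 5.1), list(f2 = 0, y = 4.7),
                          c = 3.9, tol = 0.05, phase = "constrain"))
  expect_false(accept_move(list(f2 = 10, y = 4.7), list(f2 = 99, y = 4.7),
                           c = 3.9, tol = 0.05, phase = "constrain"))
})

test_that("optimisation preserves F1, connectivity and the floor, and reports exact y", {
  p <- model_params(n = 40, m = 90, a = 0, b = 1, xmin = 2, c = 2.4)
  res <- optimise_network(p, optimiser_config(seed = 7, max_iters = 10000))
  expect_true(res$success)
  expect_equal(igraph::ecount(res$final), 90)
  expect_equal(res$objective$f1, 180)
  expect_true(is_connected_network(res$final))
  expect_gte(min(degree_sequence(res$final)), 2)
  expect_lte(res$objective$constraint_gap, 0.05)
  # final y must equal a from-scratch recomputation exactly
  expect_equal(res$objective$y, avg_shortest_path(res$final), tolerance = 1e-12)
  # phase-2 F2 trajectory strictly increases at accepted moves
  tr2 <- res$trajectory[res$trajectory$phase == 2, ]
  expect_true(all(diff(tr2$f2) > 0))
  # phase-1 gap strictly decreases at accepted moves
  tr1 <- res$trajectory[res$trajectory$phase == 1, ]
  if (nrow(tr1) > 1) expect_true(all(diff(abs(tr1$y - p$c)) < 0))
})

test_that("runs are deterministic in (params, config)", {
  p <- model_params(n = 30, m = 55, a = 1, b = 1, xmin = 1, c = 2.5)
  cfg <- optimiser_config(seed = 11, max_iters = 3000)
  r1 <- optimise_network(p, cfg)
  r2 <- optimise_network(p, cfg)
  expect_identical(edge_matrix(r1$final), edge_matrix(r2$final))
  expect_identical(r1$accepted_moves, r2$accepted_moves)
  expect_identical(r1$objective$f2, r2$objective$f2)
})

test_that("the degenerate model a = b = 0 accepts no phase-2 move", {
  p <- model_params(n = 30, m = 55, a = 0, b = 0, xmin = 1, c = 2.5)
  res <- optimise_network(p, optimiser_config(seed = 3, max_iters = 5000))
  expect_equal(res$f2_ordered, res$objective$f1)
  expect_true(all(res$trajectory$phase == 1))
})

test_that("a complete-graph instance saturates immediately but succeeds at c = 1", {
  p <- model_params(n = 6, m = 15, a = 0, b = 1, xmin = 5, c = 1)
  res <- optimise_network(p, optimiser_config(seed = 1, max_iters = 100))
  expect_true(res$saturated)
  expect_true(res$success)
  expect_equal(res$objective$y, 1)
})

test_that("sampled ASPL screening still reports exact y and stays feasible", {
  p <- model_params(n = 60, m = 130, a = 0, b = 1, xmin = 2, c = 2.7)
  res <- optimise_network(p, optimiser_config(seed = 9, max_iters = 8000,
                                              aspl_sample_k = 16))
  expect_equal(res$objective$y, avg_shortest_path(res$final), tolerance = 1e-12)
  expect_true(is_connected_network(res$final))
  expect_equal(igraph::ecount(res$final), 130)
})
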