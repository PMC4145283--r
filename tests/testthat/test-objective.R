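test_that("edge degree covers the special-case family", {
  expect_equal(edge_degree(3, 2, 1, 1), 6)   # degree product
  expect_equal(edge_degree(3, 2, 0, 0), 1)   # constant edge degree
  expect_equal(edge_degree(4, 9, 0, 1), 9)   # neighbour degree
  expect_equal(edge_degree(2, 3, 0.5, 2), sqrt(2) * 9)
  expect_error(edge_degree(0, 2, 1, 1), "degenerate")
})

test_that("F1 is the degree sum", {
  expect_equal(f1(fixture_network("complete", 3)), 6)
  expect_equal(f1(fixture_network("path", 4)), 6)
  expect_equal(f1(fixture_network("star", 4)), 6)
})

test_that("F2 sums ordered adjacent pairs and matches an enumeration oracle", {
  expect_equal(f2(fixture_network("complete", 3), 1, 1), 24)
  expect_equal(f2(fixture_network("star", 4), 0, 1), 12)  # sum of degree^2
  for (seed in 1:10) {
    net <- random_connected_graph(8, 14, seed)
    a <- runif(1, 0, 2); b <- runif(1, 0, 2)
    expect_equal(f2(net, a, b), brute_f2(net, a, b), tolerance = 1e-12)
  }
})

test_that("F2 reduces exactly to F1 at a = b = 0", {
  for (seed in 1:100) {
    net <- random_graph(sample(5:20, 1), sample(4:18, 1), seed)
    expect_identical(f2(net, 0, 0), as.numeric(f1(net)))
  }
})

test_that("F2 is symmetric in (a, b) and isomorphism-invariant", {
  for (seed in 1:10) {
    net <- random_connected_graph(9, 16, seed)
    expect_equal(f2(net, 0.3, 1.7), f2(net, 1.7, 0.3), tolerance = 1e-12)
    perm <- sample.int(9)
    relabelled <- igraph::permute(net, perm)
    expect_equal(f2(net, 1, 2), f2(relabelled, 1, 2), tolerance = 1e-12)
  }
})

test_that("degree-preserving rewires leave F2 unchanged at a=0, b=1", {
  # double-edge swap (0-1, 2-3) -> (0-3, 2-1) preserves every degree
  before <- network_from_edges(6, rbind(c(0, 1), c(2, 3), c(0, 4), c(1, 5),
                                        c(2, 4), c(3, 5)))
  after <- network_from_edges(6, rbind(c(0, 3), c(2, 1), c(0, 4), c(1, 5),
                                       c(2, 4), c(3, 5)))
  expect_equal(degree_sequence(before), degree_sequence(after))
  expect_equal(f2(before, 0, 1), f2(after, 0, 1))
})

test_that("model parameter invariants are enforced", {
  expect_error(model_params(n = 5, m = 3, c = 1.5), "connect",
               class = "paretonet_infeasible")
  expect_error(model_params(n = 10, m = 12, xmin = 3, c = 2), "floor",
               class = "paretonet_infeasible")
  expect_error(model_params(n = 10, m = 20, c = 50), "c must lie",
               class = "paretonet_infeasible")
  p <- model_params(n = 300, m = 762, a = 0, b = 1, xmin = 2, c = 3.9)
  expect_s3_class(p, "model_params")
})

test_that("evaluation flags feasibility and the constraint gap", {
  k300 <- fixture_network("complete", 300)
  p <- model_params(n = 300, m = 300 * 299 / 2, a = 0, b = 1, xmin = 299, c = 1)
  ev <- evaluate_objective(k300, p)
  expect_true(ev$feasible)
  expect_equal(ev$y, 1)
  expect_equal(ev$f1, 2 * p$m)

  p300 <- fixture_network("path", 300)
  pp <- model_params(n = 300, m = 299, a = 0, b = 1, xmin = 1, c = 301 / 3)
  ev2 <- evaluate_objective(p300, pp)
  expect_equal(ev2$y, 301 / 3)
  expect_equal(ev2$constraint_gap, 0)

  # min degree below the floor makes the same network infeasible
  pf <- model_params(n = 300, m = 350, a = 0, b = 1, xmin = 2, c = 301 / 3)
  ev3 <- evaluate_objective(p300, pf)
  expect_false(ev3$min_degree_ok)
  expect_false(ev3$feasible)

  # disconnected input is flagged, not an exception
  disc <- network_from_edges(4, rbind(c(0, 1), c(2, 3)))
  pd <- model_params(n = 4, m = 3, a = 0, b = 1, xmin = 1, c = 1.5)
  evd <- evaluate_objective(disc, pd)
  expect_false(evd$feasible)
  expect_true(is.na(evd$y))
})
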