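test_that("the similarity penalty reduces exactly the cross-block terms", {
  # two triangles joined by one bridge edge 2-3
  net <- network_from_edges(6, rbind(c(0, 1), c(0, 2), c(1, 2),
                                     c(3, 4), c(3, 5), c(4, 5), c(2, 3)))
  blocks <- c(1, 1, 1, 2, 2, 2)
  sim <- similarity_model(blocks, delta = 4)
  plain <- f2(net, 0, 1)
  deg <- degree_sequence(net)
  bridge_terms <- deg[3]^0 * deg[4]^1 + deg[4]^0 * deg[3]^1  # nodes 2 and 3
  expect_equal(f2_community(net, 0, 1, sim), plain - (1 - 1 / 4) * bridge_terms)
  # delta = 1 and single-block assignments are exact reductions
  expect_equal(f2_community(net, 0, 1, similarity_model(blocks, 1)), plain)
  expect_equal(f2_community(net, 0, 1, similarity_model(rep(1, 6), 100)), plain)
})

test_that("the penalty never increases F2", {
  for (seed in 1:10) {
    net <- random_connected_graph(10, 18, seed)
    sim <- similarity_model(planted_blocks(10, 2), delta = runif(1, 1, 10))
    expect_lte(f2_community(net, 0, 1, sim), f2(net, 0, 1) + 1e-12)
  }
})

test_that("modularity matches its brute-force definition", {
  net <- network_from_edges(6, rbind(c(0, 1), c(0, 2), c(1, 2),
                                     c(3, 4), c(3, 5), c(4, 5), c(2, 3)))
  blocks <- c(1, 1, 1, 2, 2, 2)
  expect_equal(partition_modularity(net, blocks), brute_modularity(net, blocks),
               tolerance = 1e-12)
  expect_equal(partition_modularity(net, rep(1, 6)), 0)
  for (seed in 1:5) {
    g <- random_connected_graph(12, 24, seed)
    assign <- sample(1:3, 12, replace = TRUE)
    expect_equal(partition_modularity(g, assign), brute_modularity(g, assign),
                 tolerance = 1e-12)
  }
})

test_that("random partitions of a random graph have modularity near zero", {
  set.seed(21)
  net <- random_connected_graph(40, 120, seed = 21)
  q <- replicate(100, partition_modularity(net, sample(1:2, 40, replace = TRUE)))
  expect_lt(abs(mean(q)), 0.02)
})

test_that("delta = 1 reproduces the plain optimiser move for move", {
  p <- model_params(n = 30, m = 60, a = 0, b = 1, xmin = 1, c = 2.4)
  cfg <- optimiser_config(seed = 5, max_iters = 4000)
  plain <- optimise_network(p, cfg)
  comm <- optimise_community(p, similarity_model(planted_blocks(30, 2), 1), cfg)
  expect_identical(edge_matrix(comm$final), edge_matrix(plain$final))
  expect_equal(comm$trajectory, plain$trajectory)
})

test_that("a strong penalty still leaves the cross-block cut connected", {
  p <- model_params(n = 30, m = 60, a = 0, b = 1, xmin = 1, c = 2.4)
  blocks <- planted_blocks(30, 2)
  res <- optimise_community(p, similarity_model(blocks, 1e6),
                            optimiser_config(seed = 3, max_iters = 4000))
  el <- edge_matrix(res$final)
  cross <- sum(blocks[el[, 1] + 1] != blocks[el[, 2] + 1])
  expect_gte(cross, 1)
  expect_true(is_connected_network(res$final))
})

test_that("similarity penalties steer optimisation toward the planted partition", {
  p <- model_params(n = 60, m = 140, a = 0, b = 1, xmin = 2, c = 2.9)
  blocks <- planted_blocks(60, 2)
  sim <- similarity_model(blocks, delta = 4)
  q_comm <- q_plain <- numeric(3)
  for (s in 1:3) {
    cfg <- optimiser_config(seed = s, max_iters = 20000)
    q_comm[s] <- partition_modularity(optimise_community(p, sim, cfg)$final, blocks)
    q_plain[s] <- partition_modularity(optimise_network(p, cfg)$final, blocks)
  }
  expect_gt(mean(q_comm), mean(q_plain))
})
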