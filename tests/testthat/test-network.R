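test_that("cross-correlation matrices are symmetric with unit diagonal", {
  rest <- rbind(cbind(0, 1:4 * 10, 0), cbind(40, 1:4 * 10, 0))
  spec <- bead_system_spec(rest, blocks = list(1:4, 5:8), rho = 0.6,
                           n_frames = 800, seed = 2)
  cc <- cross_correlation(gen_bead_trajectory(spec)$trajectory,
                          superpose = FALSE)
  expect_equal(diag(cc$C), rep(1, 8), ignore_attr = TRUE)
  expect_lt(max(abs(cc$C - t(cc$C))), 1e-10)
  expect_true(all(abs(cc$C) <= 1))
})

test_that("anti-correlated motion gives C = -1 and rigid motion is removed", {
  top <- bead_topology(4)
  nf <- 60
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(0, 10, 0))
  co <- array(rep(base, nf), dim = c(4, 3, nf))
  z <- sin(seq_len(nf))
  co[1, 3, ] <- z
  co[2, 3, ] <- -z          # equal and opposite
  withr::with_seed(3, co[3, 3, ] <- rnorm(nf, sd = 0.5))
  withr::with_seed(4, co[4, 3, ] <- rnorm(nf, sd = 0.5))
  cc <- cross_correlation(trajectory(top, co), superpose = FALSE)
  expect_equal(cc$C[1, 2], -1, tolerance = 1e-9)

  # independent jitter: off-diagonals are small at large n
  withr::with_seed(5, {
    jit <- array(rep(base, 5000), dim = c(4, 3, 5000)) +
      array(rnorm(4 * 3 * 5000, sd = 0.4), dim = c(4, 3, 5000))
  })
  cj <- cross_correlation(trajectory(top, jit), superpose = FALSE)
  expect_lt(max(abs(cj$C[upper.tri(cj$C)])), 0.1)
})

test_that("zero-variance residues are flagged and masked", {
  top <- bead_topology(3)
  nf <- 50
  co <- array(0, dim = c(3, 3, nf))
  co[1, , ] <- rep(c(0, 0, 0), nf)                 # frozen bead
  withr::with_seed(6, co[2:3, , ] <- rnorm(2 * 3 * nf))
  expect_warning(cc <- cross_correlation(trajectory(top, co),
                                         superpose = FALSE),
                 "zero-variance")
  expect_equal(cc$flagged, 1)
  expect_true(all(is.na(cc$C[1, -1])))
  expect_equal(cc$C[1, 1], 1)
})

test_that("contact edges obey the occupancy rule exactly", {
  # four well-separated beads; scheduled contacts 1-3 (80%) and 2-4 (60%)
  rest <- rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0), c(90, 0, 0))
  spec <- bead_system_spec(rest, blocks = list(1:4), rho = 0,
                           contacts = data.frame(i = c(1, 2), j = c(3, 4),
                                                 occupancy = c(0.80, 0.60)),
                           n_frames = 1000, seed = 7)
  trj <- gen_bead_trajectory(spec)$trajectory
  net <- contact_network(trj, contact_criteria(), weighting = "uniform")
  key <- paste(net$edges$i, net$edges$j)
  expect_true("1 3" %in% key)    # 0.80 >= 0.75
  expect_false("2 4" %in% key)   # 0.60 < 0.75
  expect_equal(net$edges$occupancy[key == "1 3"], 0.8)

  # at exactly the threshold the edge is kept ("at least 75%")
  spec75 <- bead_system_spec(rest, blocks = list(1:4), rho = 0,
                             contacts = data.frame(i = 1, j = 3,
                                                   occupancy = 0.75),
                             n_frames = 1000, seed = 8)
  net75 <- contact_network(gen_bead_trajectory(spec75)$trajectory,
                           contact_criteria(), weighting = "uniform")
  expect_true("1 3" %in% paste(net75$edges$i, net75$edges$j))
})

test_that("sequence-adjacent contacts are excluded and |C|=1 capped", {
  top <- bead_topology(3)
  nf <- 40
  co <- array(0, dim = c(3, 3, nf))
  co[2, 1, ] <- 3.0   # beads 1-2 and 2-3 permanently in contact
  co[3, 1, ] <- 6.0
  z <- sin(seq_len(nf))
  co[1, 3, ] <- z; co[2, 3, ] <- z; co[3, 3, ] <- z + co[3, 3, ]
  trj <- trajectory(top, co)
  cc <- cross_correlation(trj, superpose = FALSE)
  # 1-2 and 2-3 excluded as sequence neighbours; 1-3 too far (6 A)
  net <- contact_network(trj, contact_criteria(), weighting = "uniform")
  expect_equal(nrow(net$edges), 0)
  netu <- contact_network(trj, contact_criteria(exclusion = 0),
                          weighting = "uniform")
  expect_equal(nrow(netu$edges), 2)

  # perfectly coupled beads: |C| = 1 edges get the capped minimal length
  expect_warning(
    cap <- contact_network(trj, contact_criteria(exclusion = 0),
                           correlations = cc),
    "capped")
  expect_true(all(cap$edges$length >= 1e-4))
  expect_true(all(cap$edges$length <= 1e-3))
})

test_that("raising the occupancy threshold never adds edges", {
  rest <- two_cluster_rest()
  spec <- bead_system_spec(rest, blocks = list(1:5, 6:10), rho = 0.5,
                           n_frames = 400, seed = 9)
  trj <- gen_bead_trajectory(spec)$trajectory
  lo <- contact_network(trj, contact_criteria(occupancy = 0.5),
                        weighting = "uniform")
  hi <- contact_network(trj, contact_criteria(occupancy = 0.9),
                        weighting = "uniform")
  lo_keys <- paste(lo$edges$i, lo$edges$j)
  hi_keys <- paste(hi$edges$i, hi$edges$j)
  expect_true(all(hi_keys %in% lo_keys))
})

test_that("edge betweenness matches brute-force path enumeration", {
  # 3-node path: both edges lie on 2 shortest paths
  path3 <- make_network_from_graph({
    g <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
    igraph::E(g)$length <- 1
    g
  })
  bw <- edge_betweenness_w(path3)
  expect_equal(sort(bw$betweenness), c(2, 2))

  # 4-cycle with unit lengths: all edges equal by symmetry
  cyc <- make_network_from_graph({
    g <- igraph::make_ring(4)
    igraph::E(g)$length <- 1
    g
  })
  expect_equal(diff(range(edge_betweenness_w(cyc)$betweenness)), 0)

  # bridge between two K4 cliques dominates
  k4 <- two_k4_network()
  bwk <- edge_betweenness_w(k4)
  bridge <- bwk$betweenness[(bwk$i == 4 & bwk$j == 5) |
                              (bwk$i == 5 & bwk$j == 4)]
  expect_equal(bridge, max(bwk$betweenness))
  expect_gt(bridge, sort(bwk$betweenness, decreasing = TRUE)[2])

  # random weighted graphs vs enumeration oracle
  for (s in 1:50) {
    g <- random_connected_graph(sample(4:8, 1), seed = 100 + s)
    net <- make_network_from_graph(g)
    got <- edge_betweenness_w(net)$betweenness
    want <- brute_edge_betweenness(net$graph, igraph::E(net$graph)$length)
    expect_equal(got, unname(want), tolerance = 1e-8)
  }
})

test_that("Girvan-Newman recovers planted community structure", {
  # triangle: a single community
  tri <- make_network_from_graph({
    g <- igraph::make_ring(3)
    igraph::E(g)$length <- 1
    g
  })
  expect_equal(girvan_newman(tri)$n_communities, 1)

  # two K4 cliques + bridge: exactly the cliques, matching the exhaustive
  # modularity optimum on this 8-node graph
  k4 <- two_k4_network()
  part <- girvan_newman(k4)
  expect_equal(part$n_communities, 2)
  memb <- part$membership
  expect_length(unique(memb[as.character(1:4)]), 1)
  expect_length(unique(memb[as.character(5:8)]), 1)
  expect_false(memb[["1"]] == memb[["5"]])
  ref <- brute_best_partition(as.matrix(k4$edges[, c("i", "j")]),
                              exp(-k4$edges$length),
                              as.character(1:8))
  expect_equal(part$Q, ref$Q, tolerance = 1e-9)

  # edgeless graph: every node its own community at Q = 0
  lone <- make_network_from_graph(igraph::make_empty_graph(3, directed = FALSE))
  p0 <- girvan_newman(lone)
  expect_equal(p0$n_communities, 3)
  expect_equal(p0$Q, 0)
})

test_that("Girvan-Newman recovers generator blocks from bead dynamics", {
  spec <- bead_system_spec(two_cluster_rest(), blocks = list(1:5, 6:10),
                           rho = 0.9, n_frames = 1500, seed = 11)
  gen <- gen_bead_trajectory(spec)
  cc <- cross_correlation(gen$trajectory, superpose = FALSE)
  net <- contact_network(gen$trajectory, contact_criteria(),
                         correlations = cc)
  part <- girvan_newman(net)
  expect_equal(part$n_communities, 2)
  memb <- part$membership
  expect_length(unique(memb[as.character(1:5)]), 1)
  expect_length(unique(memb[as.character(6:10)]), 1)
  expect_false(memb[["1"]] == memb[["10"]])
})

test_that("community graphs accumulate crossing-edge betweenness", {
  k4 <- two_k4_network()
  part <- girvan_newman(k4)
  cg <- community_graph(part, k4)
  expect_equal(nrow(cg$edges), 1)
  bw <- edge_betweenness_w(k4)
  bridge <- bw$betweenness[(bw$i == 4 & bw$j == 5) | (bw$i == 5 & bw$j == 4)]
  expect_equal(cg$edges$weight, bridge)
  expect_equal(sort(cg$nodes$size), c(4, 4))

  # total cumulative betweenness equals the sum over inter-community edges
  spec <- bead_system_spec(two_cluster_rest(), blocks = list(1:5, 6:10),
                           rho = 0.8, n_frames = 800, seed = 12)
  gen <- gen_bead_trajectory(spec)
  cc <- cross_correlation(gen$trajectory, superpose = FALSE)
  net <- contact_network(gen$trajectory, contact_criteria(),
                         correlations = cc)
  part2 <- girvan_newman(net)
  cg2 <- community_graph(part2, net)
  bw2 <- edge_betweenness_w(net)
  memb <- part2$membership
  crossing <- memb[as.character(bw2$i)] != memb[as.character(bw2$j)]
  expect_equal(sum(cg2$edges$weight), sum(bw2$betweenness[crossing]))

  # partition of an edgeless graph yields an edgeless coarse graph
  lone <- make_network_from_graph(igraph::make_empty_graph(2, directed = FALSE))
  expect_equal(nrow(community_graph(girvan_newman(lone), lone)$edges), 0)
})

test_that("Girvan-Newman tracks the exhaustive optimum on small random graphs", {
  hits <- 0
  total <- 20
  for (s in 1:total) {
    g <- random_connected_graph(sample(5:7, 1), seed = 500 + s)
    net <- make_network_from_graph(g)
    part <- girvan_newman(net)
    ref <- brute_best_partition(as.matrix(net$edges[, c("i", "j")]),
                                exp(-net$edges$length),
                                as.character(seq_len(igraph::vcount(g))))
    # GN is restricted to its dendrogram: count agreements, require none worse
    expect_lte(part$Q, ref$Q + 1e-9)
    if (abs(part$Q - ref$Q) < 1e-9) hits <- hits + 1
  }
  expect_gt(hits, 0)
})
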