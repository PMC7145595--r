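# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive (enumeration, grid search) so they share no code path
# with the implementation they check.

# brute-force weighted edge betweenness by simple-path enumeration
brute_edge_betweenness <- function(g, lengths) {
  n <- igraph::vcount(g)
  bw <- setNames(numeric(igraph::ecount(g)), seq_len(igraph::ecount(g)))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- igraph::all_simple_paths(g, from = s, to = t)
      if (length(paths) == 0) next
      plen <- vapply(paths, function(p) {
        eid <- igraph::get_edge_ids(g, rep(as.integer(p), each = 2)[-c(1, 2 * length(p))])
        sum(lengths[eid])
      }, numeric(1))
      best <- min(plen)
      hits <- which(plen <= best + 1e-9)
      for (h in hits) {
        p <- paths[[h]]
        eid <- igraph::get_edge_ids(g, rep(as.integer(p), each = 2)[-c(1, 2 * length(p))])
        bw[eid] <- bw[eid] + 1 / length(hits)
      }
    }
  }
  bw
}

# weighted modularity written from the definition (affinity weights)
brute_modularity <- function(edges_ij, weights, membership) {
  m <- sum(weights)
  if (m == 0) return(0)
  deg <- tapply(c(weights, weights), c(edges_ij[, 1], edges_ij[, 2]), sum)
  deg_full <- setNames(numeric(length(membership)), names(membership))
  deg_full[names(deg)] <- deg
  q <- 0
  for (c in unique(membership)) {
    inside <- membership[as.character(edges_ij[, 1])] == c &
      membership[as.character(edges_ij[, 2])] == c
    e_c <- sum(weights[inside])
    d_c <- sum(deg_full[membership == c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# enumerate all set partitions of n labelled items (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    k <- length(assign)
    if (k == n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (lab in seq_len(next_label)) {
      rec(c(assign, lab), max(next_label, lab + 1))
    }
  }
  rec(integer(0), 1L)
  out
}

# exhaustive-search best modularity over all partitions of a small graph
brute_best_partition <- function(edges_ij, weights, node_names) {
  parts <- all_partitions(length(node_names))
  best_q <- -Inf
  best <- NULL
  for (p in parts) {
    memb <- setNames(p, node_names)
    q <- brute_modularity(edges_ij, weights, memb)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  list(Q = best_q, membership = best)
}

# rotation-grid + refinement search for the optimal superposition RMSD,
# independent of the SVD route
euler_rot <- function(a, b, g) {
  Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
  Rz1 %*% Ry %*% Rz2
}

brute_min_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  grid <- expand.grid(a = seq(0, 2 * pi, by = pi / 15),
                      b = seq(0, pi, by = pi / 15),
                      g = seq(0, 2 * pi, by = pi / 15))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  optim(start, obj, method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 2000))$value
}

# two compact five-bead clusters joined by one permanent geometric bridge
# (beads 4 and 7); all intra-cluster pairs are within the 4.5 A cutoff,
# all cross pairs except the bridge are > 5.2 A apart
two_cluster_rest <- function() {
  rbind(
    c(0, 1.5, 0), c(0, -1.5, 0), c(0, 0, 1.5), c(1.5, 0, 0), c(-1.5, 0, 0),
    c(6.5, 1.5, 0), c(5.0, 0, 0), c(6.5, -1.5, 0), c(6.5, 0, 1.5), c(8.0, 0, 0)
  )
}

# random connected graph with unit-ish lengths for betweenness checks
random_connected_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(n * n) < 0.45, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(m + t(m), mode = "undirected")
    if (igraph::is_connected(g) && igraph::ecount(g) >= n - 1) break
  }
  igraph::E(g)$length <- round(runif(igraph::ecount(g), 0.5, 2), 2)
  g
}

make_network_from_graph <- function(g) {
  ends <- igraph::ends(g, igraph::E(g))
  len <- if (igraph::ecount(g) > 0) igraph::E(g)$length else numeric(0)
  edges <- tibble::tibble(i = as.integer(ends[, 1]), j = as.integer(ends[, 2]),
                          occupancy = 1, correlation = NA_real_,
                          length = len)
  gg <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(igraph::vcount(g)))))
  if (nrow(edges) > 0) igraph::E(gg)$length <- edges$length
  structure(list(graph = gg, edges = edges,
                 nodes = tibble::tibble(resid = seq_len(igraph::vcount(g))),
                 criteria = contact_criteria(), weighting = "uniform"),
            class = "residue_network")
}

# two K4 cliques joined by a single bridge, unit lengths
two_k4_network <- function() {
  el <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  g <- igraph::make_graph(t(el), directed = FALSE)
  igraph::E(g)$length <- 1
  make_network_from_graph(g)
}
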