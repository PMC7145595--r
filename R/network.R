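#' Residue cross-correlation matrix from anchor-atom fluctuations
#'
#' Frames are superposed (two-pass mean-structure fit) and each residue is
#' represented by an anchor atom (CA when present, otherwise its first atom).
#' The normalised covariance of anchor displacements about their time means
#' gives `C_ij` in `[-1, 1]`.
#'
#' @param trj A `trajectory` with at least 2 frames.
#' @param fit Selection used for superposition (default: the anchors).
#' @param superpose Set `FALSE` if the trajectory is already aligned.
#' @return A `correlation_matrix`: the symmetric matrix `C` (unit diagonal),
#'   the residue ids, and any zero-variance residues (their rows are NA).
#' @export
cross_correlation <- function(trj, fit = NULL, superpose = TRUE) {
  stopifnot(inherits(trj, "trajectory"))
  if (n_frames(trj) < 2) stop_usage("cross-correlation needs at least 2 frames.")
  at <- trj$topology$atoms
  res_ids <- sort(unique(at$resid))
  anchor_rows <- vapply(res_ids, function(r) {
    idx <- which(at$resid == r)
    ca <- idx[at$name[idx] == "CA"]
    if (length(ca) > 0) ca[1] else idx[1]
  }, integer(1))
  anchors <- tibble(resid = res_ids, row = anchor_rows)
  work <- if (superpose) {
    superpose_trajectory(trj, fit = fit %||% at$id[anchors$row],
                         reference = "mean")
  } else trj
  nf <- n_frames(work)
  nres <- nrow(anchors)
  S <- matrix(0, nres, nres)
  for (d in 1:3) {
    Xd <- matrix(work$coords[anchors$row, d, ], nrow = nres)
    Xd <- Xd - rowMeans(Xd)
    S <- S + Xd %*% t(Xd)
  }
  v <- diag(S)
  flagged <- anchors$resid[v <= 1e-12]
  denom <- sqrt(outer(v, v))
  C <- S / denom
  C[!is.finite(C)] <- NA
  diag(C) <- 1
  C <- (C + t(C)) / 2  # enforce exact symmetry against rounding
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(anchors$resid, anchors$resid)
  if (length(flagged) > 0) {
    warn(sprintf("zero-variance residue(s) masked: %s",
                 paste(flagged, collapse = ", ")))
  }
  structure(list(C = C, resid = anchors$resid, flagged = flagged),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d residues; off-diagonal range [%.2f, %.2f]\n",
              length(x$resid),
              min(x$C[upper.tri(x$C)], na.rm = TRUE),
              max(x$C[upper.tri(x$C)], na.rm = TRUE)))
  invisible(x)
}

#' Contact criteria for the residue network
#'
#' @param cutoff Heavy-atom distance cutoff in Angstrom (4.5 by default).
#' @param occupancy Minimum fraction of frames in contact; the comparison is
#'   `>=` ("at least"). Default 0.75.
#' @param exclusion Sequence-neighbour exclusion span: pairs with
#'   `|i - j| <= exclusion` never get an edge (default 1, suppressing trivial
#'   backbone contacts).
#' @return A `contact_criteria` object.
#' @export
contact_criteria <- function(cutoff = 4.5, occupancy = 0.75, exclusion = 1) {
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (occupancy <= 0 || occupancy > 1) {
    stop_parameter("`occupancy` must lie in (0, 1].")
  }
  structure(list(cutoff = cutoff, occupancy = occupancy,
                 exclusion = as.integer(exclusion)),
            class = "contact_criteria")
}

# min heavy-atom inter-residue distances, one nres x nres matrix per frame
residue_min_dist <- function(frame, res_of, nres) {
  D <- as.matrix(stats::dist(frame))
  out <- matrix(Inf, nres, nres)
  grp <- split(seq_len(nrow(frame)), res_of)
  for (a in seq_len(nres - 1)) {
    for (b in (a + 1):nres) {
      m <- min(D[grp[[a]], grp[[b]]])
      out[a, b] <- m
      out[b, a] <- m
    }
  }
  out
}

#' Occupancy-filtered residue contact network
#'
#' Draws an edge between residues that are within `cutoff` of each other
#' (minimum heavy-atom distance) in at least `occupancy` of the frames,
#' excluding sequence neighbours. Edge lengths default to `-log |C_ij|`
#' (clamped to `[1e-4, 20]`), the standard dynamical-network convention, so
#' strongly correlated contacts are short; `weighting = "uniform"` gives
#' unit lengths.
#'
#' @param trj A `trajectory`.
#' @param criteria A [contact_criteria()].
#' @param correlations A [cross_correlation()] result (required for the
#'   default correlation weighting).
#' @param weighting `"correlation"` or `"uniform"`.
#' @return A `residue_network`: an igraph graph (vertices named by residue id;
#'   edge attributes `occupancy`, `correlation`, `length`) plus an `edges`
#'   tibble and the criteria.
#' @export
contact_network <- function(trj, criteria = contact_criteria(),
                            correlations = NULL,
                            weighting = c("correlation", "uniform")) {
  stopifnot(inherits(trj, "trajectory"), inherits(criteria, "contact_criteria"))
  weighting <- match.arg(weighting)
  at <- trj$topology$atoms
  heavy <- which(toupper(at$element) != "H")
  res_ids <- sort(unique(at$resid))
  nres <- length(res_ids)
  res_of <- match(at$resid[heavy], res_ids)
  nf <- n_frames(trj)
  occ <- matrix(0L, nres, nres)
  for (f in seq_len(nf)) {
    md <- residue_min_dist(get_frame(trj, f)[heavy, , drop = FALSE], res_of, nres)
    occ <- occ + (md < criteria$cutoff)
  }
  occ <- occ / nf
  Cm <- NULL
  if (weighting == "correlation") {
    if (is.null(correlations)) {
      stop_usage("correlation weighting needs a `correlations` matrix (or use weighting = \"uniform\").")
    }
    Cm <- correlations$C[as.character(res_ids), as.character(res_ids)]
  }
  pairs <- which(upper.tri(occ), arr.ind = TRUE)
  keep <- occ[pairs] >= criteria$occupancy &
    abs(res_ids[pairs[, 1]] - res_ids[pairs[, 2]]) > criteria$exclusion
  pairs <- pairs[keep, , drop = FALSE]
  corr <- if (!is.null(Cm)) Cm[pairs] else rep(NA_real_, nrow(pairs))
  len <- if (weighting == "correlation") {
    if (any(abs(corr) >= 1 - 1e-12, na.rm = TRUE)) {
      warn("|C| = 1 contact(s): edge length capped at the minimum (1e-4).")
    }
    pmin(pmax(-log(pmin(abs(corr), 1)), 1e-4), 20)
  } else rep(1, nrow(pairs))
  edges <- tibble(i = res_ids[pairs[, 1]], j = res_ids[pairs[, 2]],
                  occupancy = occ[pairs], correlation = corr, length = len)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$i), to = as.character(edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(res_ids)))
  if (nrow(edges) > 0) {
    igraph::E(g)$occupancy <- edges$occupancy
    igraph::E(g)$correlation <- edges$correlation
    igraph::E(g)$length <- edges$length
  }
  structure(list(graph = g, edges = edges, nodes = tibble(resid = res_ids),
                 criteria = criteria, weighting = weighting),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("<residue_network> %d residues, %d edges (cutoff %.1f A, occupancy >= %.0f%%)\n",
              nrow(x$nodes), nrow(x$edges), x$criteria$cutoff,
              100 * x$criteria$occupancy))
  invisible(x)
}

#' Weighted shortest-path edge betweenness
#'
#' Betweenness over all vertex pairs with path lengths measured by the edge
#' `length` attribute; tied equal-length shortest paths split their
#' contribution fractionally.
#'
#' @param network A [contact_network()] result (or an igraph graph with a
#'   `length` edge attribute).
#' @return Tibble (`i`, `j`, `betweenness`), one row per edge.
#' @export
edge_betweenness_w <- function(network) {
  g <- if (inherits(network, "residue_network")) network$graph else network
  if (igraph::ecount(g) == 0) {
    return(tibble(i = integer(0), j = integer(0), betweenness = numeric(0)))
  }
  w <- igraph::E(g)$length %||% rep(1, igraph::ecount(g))
  bw <- igraph::edge_betweenness(g, weights = w, directed = FALSE)
  ends <- igraph::ends(g, igraph::E(g))
  tibble(i = as.integer(ends[, 1]), j = as.integer(ends[, 2]),
         betweenness = bw)
}

partition_modularity <- function(g, membership) {
  if (igraph::ecount(g) == 0) return(0)
  w <- exp(-(igraph::E(g)$length %||% rep(1, igraph::ecount(g))))
  igraph::modularity(g, membership, weights = w)
}

#' Girvan-Newman community decomposition
#'
#' Iteratively removes the edge with the highest weighted betweenness
#' (recomputed after every removal; ties broken by the lexicographically
#' smallest residue pair, so runs are reproducible), tracks the nested
#' partitions, and returns the one maximising weighted modularity on the
#' original network (modularity weights are the edge affinities
#' `exp(-length)`, i.e. `|C|` under correlation weighting).
#'
#' @param network A [contact_network()] result.
#' @return A `community_partition`: `membership` (named by residue),
#'   `sizes`, `n_communities`, modularity `Q`, and the partition trace.
#' @export
girvan_newman <- function(network) {
  stopifnot(inherits(network, "residue_network"))
  g0 <- network$graph
  if (igraph::vcount(g0) < 2) stop_usage("need at least 2 nodes.")
  memberships <- list(igraph::components(g0)$membership)
  g <- g0
  while (igraph::ecount(g) > 0) {
    bw <- edge_betweenness_w(g)
    mx <- max(bw$betweenness)
    tied <- which(bw$betweenness >= mx - 1e-9 * max(1, abs(mx)))
    lo <- pmin(bw$i[tied], bw$j[tied])
    hi <- pmax(bw$i[tied], bw$j[tied])
    pick <- tied[order(lo, hi)][1]
    g <- igraph::delete_edges(g, igraph::E(g)[pick])
    comp <- igraph::components(g)$membership
    if (max(comp) > max(memberships[[length(memberships)]])) {
      memberships[[length(memberships) + 1]] <- comp
    }
  }
  qs <- vapply(memberships, function(m) partition_modularity(g0, m), numeric(1))
  best <- which.max(qs)
  memb <- memberships[[best]]
  names(memb) <- igraph::V(g0)$name
  structure(list(
    membership = memb,
    sizes = as.integer(table(memb)),
    n_communities = max(memb),
    Q = qs[best],
    trace = tibble(n_communities = vapply(memberships, max, numeric(1)),
                   Q = qs)
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities (sizes %s), Q = %.3f\n",
              x$n_communities, paste(x$sizes, collapse = "/"), x$Q))
  invisible(x)
}

#' Coarse-grained community graph with cumulative betweenness
#'
#' One node per community (size = residue count); an edge between two
#' communities carries the summed betweenness of the network edges crossing
#' them (the cumulative betweenness). Drawing attributes are attached:
#' node radius proportional to size, edge width proportional to weight.
#'
#' @param partition A [girvan_newman()] result.
#' @param network The [contact_network()] the partition was computed on.
#' @return A `community_graph` with `nodes` and `edges` tibbles.
#' @export
community_graph <- function(partition, network) {
  stopifnot(inherits(partition, "community_partition"),
            inherits(network, "residue_network"))
  memb <- partition$membership
  bw <- edge_betweenness_w(network)
  nodes <- tibble(community = sort(unique(as.integer(memb))))
  nodes$size <- as.integer(table(memb)[as.character(nodes$community)])
  nodes$radius <- sqrt(nodes$size / pi)
  if (nrow(bw) > 0) {
    ca <- memb[as.character(bw$i)]
    cb <- memb[as.character(bw$j)]
    cross <- ca != cb
    edges <- tibble(a = pmin(ca, cb)[cross], b = pmax(ca, cb)[cross],
                    betweenness = bw$betweenness[cross]) |>
      group_by(.data$a, .data$b) |>
      summarise(weight = sum(.data$betweenness), n_edges = n(),
                .groups = "drop")
    edges$width <- if (nrow(edges) > 0 && max(edges$weight) > 0) {
      edges$weight / max(edges$weight) * 5
    } else numeric(nrow(edges))
  } else {
    edges <- tibble(a = integer(0), b = integer(0), weight = numeric(0),
                    n_edges = integer(0), width = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "community_graph")
}
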