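#' Tidy a free-energy landscape into one row per bin
#'
#' @param x A [build_fel()] object.
#' @param ... Unused.
#' @return Tibble (`cv1`, `cv2`, `count`, `F`, `valid`).
#' @export
tidy.fel <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$mids1), j = seq_along(x$mids2))
  tibble(cv1 = x$mids1[grid$i], cv2 = x$mids2[grid$j],
         count = x$counts[cbind(grid$i, grid$j)],
         F = x$F[cbind(grid$i, grid$j)],
         valid = x$valid[cbind(grid$i, grid$j)])
}

#' @rdname tidy.fel
#' @export
glance.fel <- function(x, ...) {
  tibble(n_samples = x$n, bin_size = x$spec$bin_size,
         temperature = x$spec$temperature, n_bins = length(x$F),
         n_valid_bins = sum(x$valid), F_max = max(x$F, na.rm = TRUE))
}

#' Tidy a correlation matrix into residue pairs
#' @param x A [cross_correlation()] object.
#' @param ... Unused.
#' @return Tibble (`resid_i`, `resid_j`, `correlation`).
#' @export
tidy.correlation_matrix <- function(x, ...) {
  grid <- expand.grid(a = seq_along(x$resid), b = seq_along(x$resid))
  tibble(resid_i = x$resid[grid$a], resid_j = x$resid[grid$b],
         correlation = x$C[cbind(grid$a, grid$b)])
}

#' Tidy a residue network into its edge list
#' @param x A [contact_network()] object.
#' @param ... Unused.
#' @export
tidy.residue_network <- function(x, ...) x$edges

#' @rdname tidy.residue_network
#' @export
glance.residue_network <- function(x, ...) {
  tibble(n_residues = nrow(x$nodes), n_edges = nrow(x$edges),
         cutoff = x$criteria$cutoff, occupancy = x$criteria$occupancy,
         weighting = x$weighting)
}

#' Tidy a community partition into residue assignments
#' @param x A [girvan_newman()] object.
#' @param ... Unused.
#' @return Tibble (`resid`, `community`).
#' @export
tidy.community_partition <- function(x, ...) {
  tibble(resid = as.integer(names(x$membership)),
         community = as.integer(x$membership))
}

#' @rdname tidy.community_partition
#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_communities = x$n_communities, Q = x$Q,
         largest = max(x$sizes), smallest = min(x$sizes))
}
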