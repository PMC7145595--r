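#' Specification for a 2D free-energy landscape
#'
#' @param bin_size Bin width for both CVs (Angstrom; 0.3 by default).
#' @param temperature Temperature in Kelvin (300 by default).
#' @param min_count Bins with fewer samples are masked as invalid; masking
#'   (rather than pseudo-counts) avoids spurious shallow minima at the
#'   landscape edges.
#' @param min_samples Minimum number of samples required to build a landscape.
#' @return A `fel_spec` object.
#' @export
fel_spec <- function(bin_size = 0.3, temperature = 300, min_count = 5,
                     min_samples = 1000) {
  check_scalar_number(bin_size, "bin_size", positive = TRUE)
  check_scalar_number(temperature, "temperature", positive = TRUE)
  structure(list(bin_size = bin_size, temperature = temperature,
                 min_count = min_count, min_samples = min_samples),
            class = "fel_spec")
}

#' Build an unweighted 2D free-energy landscape from a CV series
#'
#' Bins the (CV1, CV2) samples on a regular grid (ranges taken from the data
#' with half-bin padding) and converts populations to free energies
#' `F = -kT log(count / N)`, shifted so the global minimum is zero. Bins
#' with fewer than `min_count` samples are masked.
#'
#' @param cv Data frame with the two CV columns (`cv1`, `cv2` by default).
#' @param spec A [fel_spec()].
#' @param cv_names Names of the two CV columns.
#' @return An object of class `fel`: bin edges/centres per CV, `counts`,
#'   free-energy matrix `F` (NA on masked bins), and metadata.
#' @export
#' @examples
#' m <- state_model(data.frame(cv1 = 8, cv2 = 9, sd = 0.4, weight = 1))
#' cv <- gen_cv_series(m, n = 5000, seed = 1)
#' fel <- build_fel(cv, fel_spec())
#' fel
build_fel <- function(cv, spec = fel_spec(), cv_names = c("cv1", "cv2")) {
  stopifnot(inherits(spec, "fel_spec"))
  if (is.null(cv) || nrow(cv) == 0) stop_usage("`cv` series is empty.")
  if (!all(cv_names %in% names(cv))) {
    stop_usage(sprintf("`cv` must contain columns %s.",
                       paste(cv_names, collapse = ", ")))
  }
  x <- cv[[cv_names[1]]]
  y <- cv[[cv_names[2]]]
  n <- length(x)
  if (n < spec$min_samples) {
    stop_usage(sprintf("need at least %d samples to build a landscape (got %d).",
                       spec$min_samples, n))
  }
  if (anyNA(x) || anyNA(y)) stop_data("CV series contains missing values.")
  b <- spec$bin_size
  ex <- seq(min(x) - b / 2, max(x) + b, by = b)
  ey <- seq(min(y) - b / 2, max(y) + b, by = b)
  ix <- findInterval(x, ex, rightmost.closed = TRUE)
  iy <- findInterval(y, ey, rightmost.closed = TRUE)
  counts <- matrix(0L, nrow = length(ex) - 1, ncol = length(ey) - 1)
  tab <- table(factor(ix, levels = seq_len(nrow(counts))),
               factor(iy, levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  kt <- kT(spec$temperature)
  valid <- counts >= spec$min_count
  F <- matrix(NA_real_, nrow = nrow(counts), ncol = ncol(counts))
  F[valid] <- -kt * log(counts[valid] / n)
  F <- F - min(F, na.rm = TRUE)
  structure(list(
    edges1 = ex, edges2 = ey,
    mids1 = (ex[-1] + ex[-length(ex)]) / 2,
    mids2 = (ey[-1] + ey[-length(ey)]) / 2,
    counts = counts, F = F, valid = valid,
    n = n, spec = spec, cv_names = cv_names
  ), class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  cat(sprintf("<fel> %d x %d bins (%.2f A), %d samples, %d valid bins, F range 0..%.2f kcal/mol\n",
              nrow(x$F), ncol(x$F), x$spec$bin_size, x$n, sum(x$valid),
              max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Conformational-state thresholds on the two CVs
#'
#' Defaults encode the active-site conventions used throughout the package:
#' the cap pocket is open when CV1 > 10 A, the AdoMet pocket is open when
#' CV2 > 11 A, and the active site is closed when CV1 < 9 A and CV2 < 10 A.
#' Frames between the closed bounds and open thresholds are labelled
#' `intermediate` rather than forced into a state.
#'
#' @param cap_open CV1 threshold above which the cap pocket counts as open.
#' @param adomet_open CV2 threshold above which the AdoMet pocket counts as open.
#' @param closed_cv1,closed_cv2 Upper bounds of the closed state per CV.
#' @return A `state_thresholds` object.
#' @export
state_thresholds <- function(cap_open = 10, adomet_open = 11,
                             closed_cv1 = 9, closed_cv2 = 10) {
  if (closed_cv1 >= cap_open || closed_cv2 >= adomet_open) {
    stop_parameter("closed bounds must lie below the open thresholds.")
  }
  structure(list(cap_open = cap_open, adomet_open = adomet_open,
                 closed_cv1 = closed_cv1, closed_cv2 = closed_cv2),
            class = "state_thresholds")
}

classify_points <- function(cv1, cv2, th) {
  out <- rep("intermediate", length(cv1))
  out[cv1 > th$cap_open & cv2 > th$adomet_open] <- "fully_open"
  out[cv1 > th$cap_open & cv2 <= th$adomet_open] <- "cap_open"
  out[cv1 < th$closed_cv1 & cv2 < th$closed_cv2] <- "closed"
  factor(out, levels = c("fully_open", "cap_open", "closed", "intermediate"))
}

#' Classify frames into conformational states
#'
#' Every frame receives exactly one label: `fully_open` (CV1 and CV2 above
#' their open thresholds), `cap_open` (CV1 open, CV2 not), `closed` (both
#' below the closed bounds) or `intermediate`.
#'
#' @param cv Data frame with `cv1`, `cv2` columns.
#' @param thresholds A [state_thresholds()].
#' @return The input tibble with a `state_label` column; label fractions are
#'   attached as attribute `"fractions"` (see [state_fractions()]).
#' @export
#' @examples
#' classify_states(data.frame(cv1 = c(11.5, 7.8), cv2 = c(12.2, 9.0)))
classify_states <- function(cv, thresholds = state_thresholds()) {
  stopifnot(inherits(thresholds, "state_thresholds"))
  cv <- as_tibble(cv)
  if (!all(c("cv1", "cv2") %in% names(cv))) {
    stop_usage("`cv` must contain columns cv1, cv2.")
  }
  cv$state_label <- classify_points(cv$cv1, cv$cv2, thresholds)
  fr <- table(cv$state_label) / nrow(cv)
  attr(cv, "fractions") <- tibble(state_label = names(fr),
                                  fraction = as.numeric(fr))
  cv
}

#' Label fractions of a classified CV series
#' @param classified Output of [classify_states()].
#' @return Tibble (`state_label`, `fraction`); fractions sum to 1.
#' @export
state_fractions <- function(classified) {
  fr <- attr(classified, "fractions")
  if (is.null(fr)) {
    fr <- table(classified$state_label) / nrow(classified)
    fr <- tibble(state_label = names(fr), fraction = as.numeric(fr))
  }
  fr
}

neighbour_offsets <- cbind(
  rep(-1:1, times = 3), rep(-1:1, each = 3)
)[-5, , drop = FALSE]

#' Locate free-energy minima on a landscape
#'
#' A minimum is a valid bin strictly lower than all of its valid 8-neighbours.
#' Minima within `merge_radius` of a deeper minimum are merged into it
#' (suppresses noise-split basins). Every valid bin is then assigned to a
#' minimum by steepest descent to give basin population fractions.
#'
#' @param fel A [build_fel()] object.
#' @param merge_radius Merge radius in CV units (default 0.6 A = 2 bins at
#'   the default bin size).
#' @param thresholds [state_thresholds()] used to label each minimum.
#' @return Tibble (`cv1`, `cv2`, `F`, `population`, `state_label`), sorted by
#'   `F` ascending (global minimum first).
#' @export
find_minima <- function(fel, merge_radius = 0.6,
                        thresholds = state_thresholds()) {
  stopifnot(inherits(fel, "fel"))
  if (!any(fel$valid)) stop_usage("landscape has no valid bins.")
  nr <- nrow(fel$F); nc <- ncol(fel$F)
  idx <- which(fel$valid, arr.ind = TRUE)
  is_min <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    f0 <- fel$F[i, j]
    ni <- i + neighbour_offsets[, 1]
    nj <- j + neighbour_offsets[, 2]
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
    nb <- cbind(ni[ok], nj[ok])
    nbv <- nb[fel$valid[nb], , drop = FALSE]
    is_min[r] <- nrow(nbv) == 0 || all(fel$F[nbv] > f0)
  }
  raw <- tibble(i = idx[is_min, 1], j = idx[is_min, 2],
                cv1 = fel$mids1[idx[is_min, 1]],
                cv2 = fel$mids2[idx[is_min, 2]],
                F = fel$F[idx[is_min, , drop = FALSE]])
  raw <- arrange(raw, .data$F)
  # merge shallow minima into deeper ones within the merge radius
  keep <- integer(0)
  parent <- integer(nrow(raw))
  for (r in seq_len(nrow(raw))) {
    merged <- FALSE
    for (k in keep) {
      d <- sqrt((raw$cv1[r] - raw$cv1[k])^2 + (raw$cv2[r] - raw$cv2[k])^2)
      if (d <= merge_radius) {
        parent[r] <- k
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      keep <- c(keep, r)
      parent[r] <- r
    }
  }
  # steepest-descent basin assignment, processed in ascending F order
  ordv <- order(fel$F[fel$valid])
  vidx <- which(fel$valid, arr.ind = TRUE)[ordv, , drop = FALSE]
  basin <- matrix(NA_integer_, nr, nc)  # index into raw minima rows
  min_lookup <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nrow(raw))) min_lookup[raw$i[r], raw$j[r]] <- r
  for (r in seq_len(nrow(vidx))) {
    i <- vidx[r, 1]; j <- vidx[r, 2]
    if (!is.na(min_lookup[i, j])) {
      basin[i, j] <- parent[min_lookup[i, j]]
      next
    }
    ni <- i + neighbour_offsets[, 1]
    nj <- j + neighbour_offsets[, 2]
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
    nb <- cbind(ni[ok], nj[ok])
    nb <- nb[fel$valid[nb], , drop = FALSE]
    if (nrow(nb) == 0) { basin[i, j] <- NA_integer_; next }
    lower <- nb[fel$F[nb] < fel$F[i, j], , drop = FALSE]
    tgt <- if (nrow(lower) > 0) lower[which.min(fel$F[lower]), ] else
      nb[which.min(fel$F[nb]), ]
    basin[i, j] <- basin[tgt[1], tgt[2]]
  }
  pops <- vapply(keep, function(k) {
    sum(fel$counts[fel$valid & !is.na(basin) & basin == k]) / fel$n
  }, numeric(1))
  out <- raw[keep, c("cv1", "cv2", "F")]
  out$population <- pops
  out$state_label <- classify_points(out$cv1, out$cv2, thresholds)
  arrange(out, .data$F)
}

snap_to_bin <- function(fel, point) {
  i <- which.min(abs(fel$mids1 - point[1]))
  j <- which.min(abs(fel$mids2 - point[2]))
  if (!fel$valid[i, j]) {
    # snap to the nearest valid bin
    vi <- which(fel$valid, arr.ind = TRUE)
    d <- (fel$mids1[vi[, 1]] - point[1])^2 + (fel$mids2[vi[, 2]] - point[2])^2
    ij <- vi[which.min(d), ]
    i <- ij[1]; j <- ij[2]
  }
  c(i, j)
}

#' Minimax-path barrier between two landscape points
#'
#' The barrier is read as a saddle height: over all 8-connected paths through
#' valid bins between the two endpoints, take the path whose maximum free
#' energy is smallest; that minimax value minus the endpoint free energy is
#' the barrier seen from each side. Masked bins are impassable.
#'
#' @param fel A [build_fel()] object.
#' @param from,to Numeric `c(cv1, cv2)` coordinates (snapped to the nearest
#'   valid bin) or single rows of [find_minima()] output.
#' @return A list with `saddle` (kcal/mol, on the landscape's F scale),
#'   `barrier_from` (saddle - F(from)), `barrier_to` (saddle - F(to)).
#' @export
barrier_height <- function(fel, from, to) {
  stopifnot(inherits(fel, "fel"))
  as_point <- function(p) {
    if (is.data.frame(p)) c(p$cv1[1], p$cv2[1]) else as.numeric(p)
  }
  a <- snap_to_bin(fel, as_point(from))
  b <- snap_to_bin(fel, as_point(to))
  nr <- nrow(fel$F); nc <- ncol(fel$F)
  if (identical(a, b)) {
    return(list(saddle = fel$F[a[1], a[2]], barrier_from = 0, barrier_to = 0))
  }
  # Dijkstra-style widest/minimax search: cost of a path is its max F
  best <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  best[a[1], a[2]] <- fel$F[a[1], a[2]]
  repeat {
    cand <- which(!done & is.finite(best))
    if (length(cand) == 0) {
      abort("no valid-bin path connects the two points.",
            class = "allostera_disconnected_landscape_error")
    }
    u <- cand[which.min(best[cand])]
    ui <- (u - 1) %% nr + 1
    uj <- (u - 1) %/% nr + 1
    if (ui == b[1] && uj == b[2]) break
    done[u] <- TRUE
    ni <- ui + neighbour_offsets[, 1]
    nj <- uj + neighbour_offsets[, 2]
    ok <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
    nb <- cbind(ni[ok], nj[ok])
    nb <- nb[fel$valid[nb] & !done[nb], , drop = FALSE]
    if (nrow(nb) > 0) {
      alt <- pmax(best[ui, uj], fel$F[nb])
      cur <- best[nb]
      upd <- alt < cur
      best[nb[upd, , drop = FALSE]] <- alt[upd]
    }
  }
  saddle <- best[b[1], b[2]]
  list(saddle = saddle,
       barrier_from = saddle - fel$F[a[1], a[2]],
       barrier_to = saddle - fel$F[b[1], b[2]])
}

#' Convergence report for a free-energy landscape
#'
#' Rebuilds the landscape from leading fractions of the series and at several
#' bin sizes, comparing each to the full-data reference (at `spec$bin_size`):
#' minima count, global-minimum position, and the RMS free-energy difference
#' over bins whose centres fall in valid reference bins. The `converged` flag
#' requires the minima of the two largest fractions to agree in count and to
#' shift by less than one reference bin.
#'
#' @param cv CV series (columns `cv1`, `cv2`).
#' @param spec Reference [fel_spec()].
#' @param fractions Leading fractions of the data to test.
#' @param bin_sizes Bin sizes to test (full data).
#' @param merge_radius Passed to [find_minima()].
#' @return A list with `results` (one row per setting), `converged`, and the
#'   reference `fel`.
#' @export
fel_convergence <- function(cv, spec = fel_spec(),
                            fractions = c(0.25, 0.5, 0.75, 1),
                            bin_sizes = c(0.2, 0.3, 0.4, 0.5),
                            merge_radius = 0.6) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop_parameter("`fractions` must lie in (0, 1].")
  }
  ref <- build_fel(cv, spec)
  ref_min <- find_minima(ref, merge_radius)
  ref_lookup <- function(cv1, cv2) {
    i <- findInterval(cv1, ref$edges1, rightmost.closed = TRUE)
    j <- findInterval(cv2, ref$edges2, rightmost.closed = TRUE)
    ok <- i >= 1 & i <= nrow(ref$F) & j >= 1 & j <= ncol(ref$F)
    out <- rep(NA_real_, length(cv1))
    out[ok] <- ref$F[cbind(i[ok], j[ok])]
    out
  }
  eval_setting <- function(sub_cv, bin) {
    s <- fel_spec(bin_size = bin, temperature = spec$temperature,
                  min_count = spec$min_count, min_samples = spec$min_samples)
    g <- build_fel(sub_cv, s)
    m <- find_minima(g, merge_radius)
    centres <- expand.grid(cv1 = g$mids1, cv2 = g$mids2)
    fv <- as.vector(g$F)
    refF <- ref_lookup(centres$cv1, centres$cv2)
    both <- !is.na(fv) & !is.na(refF)
    rms <- if (any(both)) sqrt(mean((fv[both] - refF[both])^2)) else NA_real_
    tibble(n_minima = nrow(m), min_cv1 = m$cv1[1], min_cv2 = m$cv2[1],
           rms_dF = rms, minima = list(m))
  }
  rows <- list()
  for (f in sort(fractions)) {
    sub <- cv[seq_len(floor(f * nrow(cv))), , drop = FALSE]
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(setting = "fraction", value = f), eval_setting(sub, spec$bin_size))
  }
  for (b in bin_sizes) {
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(setting = "bin_size", value = b), eval_setting(cv, b))
  }
  results <- bind_rows(rows)
  fr <- results[results$setting == "fraction", ]
  conv <- FALSE
  if (nrow(fr) >= 2) {
    last2 <- fr[order(fr$value), ][c(nrow(fr) - 1, nrow(fr)), ]
    m1 <- last2$minima[[1]]; m2 <- last2$minima[[2]]
    if (nrow(m1) == nrow(m2)) {
      # match minima greedily by distance
      shifts <- vapply(seq_len(nrow(m2)), function(k) {
        min(sqrt((m1$cv1 - m2$cv1[k])^2 + (m1$cv2 - m2$cv2[k])^2))
      }, numeric(1))
      conv <- all(shifts < spec$bin_size)
    }
  }
  list(results = results, converged = conv, reference = ref,
       reference_minima = ref_min)
}
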