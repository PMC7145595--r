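#' Parameters for Monte-Carlo pocket-volume estimation
#'
#' @param seed Integer seed (mandatory); frame `f` of a series uses
#'   `seed + f - 1`, so frames are reproducible and independent.
#' @param iterations Monte-Carlo points per frame (>= 1000; default 10 000).
#' @param r_min,r_max Minimum and maximum probe-sphere radii (Angstrom;
#'   defaults 3 and 6). A point belongs to the pocket when some empty probe
#'   sphere with radius in `[r_min - probe_slack, r_max]` contains it.
#' @param probe_slack Relaxation of the lower probe bound (default 1.8,
#'   giving an effective minimum probe radius of 1.2 A).
#' @param spacing Envelope grid spacing (Angstrom).
#' @param n_reference Number of reference snapshots used to define the
#'   envelope (default 2000; capped at the trajectory length).
#' @param atom_radius Uniform atom radius used when the topology carries none.
#' @param burial_frac Fraction of the 26 lattice ray directions that must hit
#'   an atom within `ray_length` for a point to count as buried (pocket, not
#'   bulk solvent).
#' @param ray_length Ray length for the burial test (Angstrom).
#' @return A `pocket_spec` object.
#' @export
pocket_spec <- function(seed, iterations = 10000, r_min = 3, r_max = 6,
                        probe_slack = 1.8, spacing = 1.0, n_reference = 2000,
                        atom_radius = 1.7, burial_frac = 0.5, ray_length = 8) {
  if (!(r_min > 0 && r_min < r_max)) {
    stop_parameter("need 0 < r_min < r_max.")
  }
  if (iterations < 1000) stop_parameter("`iterations` must be >= 1000.")
  check_scalar_number(spacing, "spacing", positive = TRUE)
  structure(list(seed = check_seed(seed), iterations = as.integer(iterations),
                 r_min = r_min, r_max = r_max, probe_slack = probe_slack,
                 r_lo = max(r_min - probe_slack, 1e-6), spacing = spacing,
                 n_reference = as.integer(n_reference),
                 atom_radius = atom_radius, burial_frac = burial_frac,
                 ray_length = ray_length),
            class = "pocket_spec")
}

atom_radii <- function(topology, spec) {
  r <- topology$atoms$radius
  r[is.na(r)] <- spec$atom_radius
  r
}

# min over atoms of (centre distance - radius), chunked; also returns the
# nearest atom index, and optionally the raw squared distances of one chunk
clearance_to_atoms <- function(points, atoms, radii, chunk = 2000L) {
  m <- nrow(points)
  cl <- numeric(m)
  nearest <- integer(m)
  a2 <- rowSums(atoms^2)
  for (s in seq(1, m, by = chunk)) {
    e <- min(s + chunk - 1, m)
    P <- points[s:e, , drop = FALSE]
    D2 <- outer(rowSums(P^2), a2, "+") - 2 * P %*% t(atoms)
    D2[D2 < 0] <- 0
    G <- sweep(sqrt(D2), 2, radii)
    nearest[s:e] <- max.col(-G, ties.method = "first")
    cl[s:e] <- G[cbind(seq_len(nrow(G)), nearest[s:e])]
  }
  list(clearance = cl, nearest = nearest)
}

#' Build a pocket envelope from a reference trajectory
#'
#' The envelope is the region where the pocket is allowed to exist: grid
#' voxels within `r_max` of the defining coordinates (bound-ligand atoms or
#' user seed points), minus voxels that overlap protein atoms in more than
#' `occlusion` of the sampled reference snapshots.
#'
#' @param reference A `trajectory` superposed to a common frame (or `NULL`
#'   for a purely geometric envelope around the points).
#' @param points k x 3 matrix of defining coordinates (Angstrom).
#' @param spec A [pocket_spec()].
#' @param occlusion Fraction of snapshots above which an atom-overlapping
#'   voxel is removed (default 0.95).
#' @return A `pocket_envelope`: voxel centres, spacing, and total volume.
#' @export
build_reference_envelope <- function(reference, points, spec,
                                     occlusion = 0.95) {
  stopifnot(inherits(spec, "pocket_spec"))
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 0) stop_usage("need at least one defining point.")
  h <- spec$spacing
  lo <- floor((apply(points, 2, min) - spec$r_max) / h) * h
  hi <- ceiling((apply(points, 2, max) + spec$r_max) / h) * h
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  gz <- seq(lo[3] + h / 2, hi[3], by = h)
  vox <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  d2min <- rep(Inf, nrow(vox))
  for (k in seq_len(nrow(points))) {
    d2 <- rowSums(sweep(vox, 2, points[k, ])^2)
    d2min <- pmin(d2min, d2)
  }
  vox <- vox[d2min <= spec$r_max^2, , drop = FALSE]
  if (!is.null(reference) && n_atoms(reference) > 0) {
    radii <- atom_radii(reference$topology, spec)
    nf <- n_frames(reference)
    take <- unique(round(seq(1, nf, length.out = min(nf, spec$n_reference))))
    occl <- numeric(nrow(vox))
    for (f in take) {
      cl <- clearance_to_atoms(vox, get_frame(reference, f), radii)$clearance
      occl <- occl + (cl < 0)
    }
    vox <- vox[occl / length(take) <= occlusion, , drop = FALSE]
  }
  if (nrow(vox) == 0) {
    stop_spec("envelope is empty: defining points are buried in protein in every snapshot.")
  }
  pocket_envelope(vox, h)
}

#' Construct a pocket envelope from explicit voxel centres
#'
#' @param voxels m x 3 matrix of voxel centres on a regular grid.
#' @param spacing Grid spacing (voxel volume = spacing^3).
#' @return A `pocket_envelope`.
#' @export
pocket_envelope <- function(voxels, spacing) {
  voxels <- matrix(as.numeric(as.matrix(voxels)), ncol = 3)
  if (nrow(voxels) == 0) stop_spec("envelope must contain at least one voxel.")
  structure(list(voxels = voxels, spacing = spacing,
                 volume = nrow(voxels) * spacing^3),
            class = "pocket_envelope")
}

#' @export
print.pocket_envelope <- function(x, ...) {
  cat(sprintf("<pocket_envelope> %d voxels @ %.2f A -> %.1f A^3\n",
              nrow(x$voxels), x$spacing, x$volume))
  invisible(x)
}

ray_directions <- local({
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g / sqrt(rowSums(g^2))
})

# fraction of lattice directions along which a ray of length `ray` from each
# point passes through an atom
burial_fraction <- function(points, atoms, radii, ray) {
  m <- nrow(points)
  if (m == 0) return(numeric(0))
  hits <- matrix(0L, nrow = m, ncol = nrow(ray_directions))
  a2 <- rowSums(atoms^2)
  D2 <- outer(rowSums(points^2), a2, "+") - 2 * points %*% t(atoms)
  D2[D2 < 0] <- 0
  R2 <- matrix(radii^2, nrow = m, ncol = length(radii), byrow = TRUE)
  for (d in seq_len(nrow(ray_directions))) {
    u <- ray_directions[d, ]
    T <- outer(-(points %*% u)[, 1], (atoms %*% u)[, 1], "+")
    perp2 <- D2 - T^2
    hit <- T >= 0 & T <= ray & perp2 <= R2
    hits[, d] <- as.integer(rowSums(hit) > 0)
  }
  rowMeans(hits)
}

#' Monte-Carlo pocket volume of a single frame
#'
#' Draws `iterations` uniform points inside the envelope and classifies each
#' as pocket interior when (i) it lies outside all atoms but its clearance
#' does not exceed `r_max` (too-open points are bulk), (ii) it is contained
#' in some empty probe sphere of radius at least the effective minimum
#' (checked at the point itself, or at a tangent probe centre placed away
#' from the nearest atom), and (iii) it is buried by the ray criterion.
#' The volume is the envelope volume times the interior fraction. A frame
#' with no atoms returns the full envelope volume (a fully open envelope).
#'
#' @param frame n_atoms x 3 coordinate matrix (or a 1-frame `trajectory`).
#' @param envelope A [pocket_envelope()].
#' @param spec A [pocket_spec()].
#' @param topology Optional [topology()] supplying per-atom radii.
#' @param seed Seed for this frame; defaults to `spec$seed`.
#' @return Volume in cubic Angstrom.
#' @export
pocket_volume_frame <- function(frame, envelope, spec, topology = NULL,
                                seed = NULL) {
  stopifnot(inherits(envelope, "pocket_envelope"), inherits(spec, "pocket_spec"))
  if (inherits(frame, "trajectory")) {
    topology <- topology %||% frame$topology
    frame <- get_frame(frame, 1)
  }
  frame <- as.matrix(frame)
  seed <- check_seed(seed %||% spec$seed)
  if (nrow(frame) == 0) return(envelope$volume)
  radii <- if (!is.null(topology)) atom_radii(topology, spec) else
    rep(spec$atom_radius, nrow(frame))
  withr::local_seed(seed)
  ni <- spec$iterations
  vi <- sample.int(nrow(envelope$voxels), ni, replace = TRUE)
  pts <- envelope$voxels[vi, , drop = FALSE] +
    matrix(runif(3 * ni, -envelope$spacing / 2, envelope$spacing / 2), ncol = 3)
  cl <- clearance_to_atoms(pts, frame, radii)
  open_ok <- cl$clearance > 0 & cl$clearance <= spec$r_max
  covered <- cl$clearance >= spec$r_lo
  # points closer to the wall than the minimum probe radius may still sit
  # inside an empty probe sphere: walk a trial centre away from the nearest
  # atom until such a sphere (radius in [r_lo, r_max]) contains the point
  need <- which(open_ok & !covered)
  if (length(need) > 0) {
    p <- pts[need, , drop = FALSE]
    centres <- p
    ccl <- cl$clearance[need]
    cnear <- cl$nearest[need]
    ok <- rep(FALSE, length(need))
    for (it in 1:4) {
      todo <- which(!ok)
      if (length(todo) == 0) break
      u <- centres[todo, , drop = FALSE] - frame[cnear[todo], , drop = FALSE]
      u <- u / sqrt(rowSums(u^2))
      centres[todo, ] <- centres[todo, , drop = FALSE] +
        u * pmax(spec$r_lo - ccl[todo], 0.1 * spec$r_lo)
      res <- clearance_to_atoms(centres[todo, , drop = FALSE], frame, radii)
      ccl[todo] <- res$clearance
      cnear[todo] <- res$nearest
      reach <- sqrt(rowSums((centres[todo, , drop = FALSE] -
                               p[todo, , drop = FALSE])^2))
      ok[todo] <- res$clearance >= spec$r_lo * (1 - 1e-9) &
        reach <= pmin(res$clearance, spec$r_max)
    }
    covered[need] <- ok
  }
  cand <- which(open_ok & covered)
  pocket <- logical(ni)
  if (length(cand) > 0) {
    bf <- burial_fraction(pts[cand, , drop = FALSE], frame, radii,
                          spec$ray_length)
    pocket[cand] <- bf >= spec$burial_frac
  }
  envelope$volume * mean(pocket)
}

#' Pocket volume along a trajectory
#'
#' @param trj A `trajectory` (already superposed onto the envelope's frame,
#'   or pass `fit`/`reference` to superpose here).
#' @param envelope A [pocket_envelope()].
#' @param spec A [pocket_spec()].
#' @param fit Optional selection: superpose frames on it before measuring.
#' @param reference Reference for the superposition (default frame 1).
#' @return A `volume_series` tibble (`frame`, `volume`) with the spec and
#'   envelope attached; `glance()` gives mean, sd and range.
#' @export
volume_series <- function(trj, envelope, spec, fit = NULL, reference = 1) {
  stopifnot(inherits(trj, "trajectory"))
  if (!is.null(fit)) {
    trj <- superpose_trajectory(trj, fit = fit, reference = reference)
  }
  nf <- n_frames(trj)
  vol <- numeric(nf)
  for (f in seq_len(nf)) {
    vol[f] <- pocket_volume_frame(get_frame(trj, f), envelope, spec,
                                  topology = trj$topology,
                                  seed = spec$seed + f - 1)
  }
  out <- tibble(frame = seq_len(nf), volume = vol)
  class(out) <- c("volume_series", class(out))
  attr(out, "spec") <- spec
  attr(out, "envelope_volume") <- envelope$volume
  out
}

#' @export
glance.volume_series <- function(x, ...) {
  tibble(n_frames = nrow(x), mean_volume = mean(x$volume),
         sd_volume = sd(x$volume), min_volume = min(x$volume),
         max_volume = max(x$volume),
         envelope_volume = attr(x, "envelope_volume"))
}
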