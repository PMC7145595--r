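#' Kabsch superposition of two frames
#'
#' Finds the proper rotation and translation minimising the RMSD of the fit
#' selection between a mobile and a reference frame (SVD solution).
#'
#' @param mobile,reference n_atoms x 3 coordinate matrices sharing a topology.
#' @param fit Row indices (into the coordinate matrices) used for the fit;
#'   defaults to all atoms.
#' @return A list with `rotation` (3 x 3, det = +1), `translation` (length 3),
#'   `rmsd` (post-fit, over the fit atoms) and `apply(coords)` which maps any
#'   coordinate matrix with the mobile frame's orientation onto the reference.
#' @export
kabsch_superpose <- function(mobile, reference, fit = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    stop_usage("mobile and reference must have identical dimensions.")
  }
  fit <- fit %||% seq_len(nrow(mobile))
  if (length(fit) < 3) stop_degenerate_fit()
  P <- mobile[fit, , drop = FALSE]
  Q <- reference[fit, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  if (qr(Pc)$rank < 2) stop_degenerate_fit()
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  apply_fun <- function(coords) {
    sweep(sweep(as.matrix(coords), 2, pc) %*% t(R), 2, qc, "+")
  }
  fitted <- apply_fun(P)
  list(rotation = R,
       translation = as.numeric(qc - as.numeric(R %*% pc)),
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))),
       apply = apply_fun)
}

stop_degenerate_fit <- function() {
  abort("superposition needs at least 3 non-collinear fit atoms.",
        class = "allostera_degenerate_fit_error")
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

resolve_reference <- function(trj, reference) {
  if (is.null(reference)) return(get_frame(trj, 1))
  if (is.numeric(reference) && length(reference) == 1) {
    return(get_frame(trj, reference))
  }
  as.matrix(reference)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' @param trj A `trajectory`.
#' @param fit Selection used for fitting (expression, selection, or ids);
#'   default all atoms.
#' @param reference Frame index, coordinate matrix, or `"mean"` for the
#'   two-pass mean-structure fit (fit to frame 1, average, refit to average).
#' @return A `trajectory` with superposed coordinates.
#' @export
superpose_trajectory <- function(trj, fit = NULL, reference = 1) {
  stopifnot(inherits(trj, "trajectory"))
  rows <- if (is.null(fit)) seq_len(n_atoms(trj)) else selection_rows(trj$topology, fit)
  if (identical(reference, "mean")) {
    pass1 <- superpose_trajectory(trj, fit = rows, reference = 1)
    ref <- apply(pass1$coords, c(1, 2), mean)
    return(superpose_trajectory(trj, fit = rows, reference = ref))
  }
  ref <- resolve_reference(trj, reference)
  out <- trj$coords
  for (f in seq_len(n_frames(trj))) {
    k <- kabsch_superpose(get_frame(trj, f), ref, fit = rows)
    out[, , f] <- k$apply(get_frame(trj, f))
  }
  trajectory(trj$topology, out, time_step_ps = trj$time_step_ps)
}

#' Per-frame RMSD after superposition
#'
#' The fit and measure selections may differ (e.g. fit on the stable core,
#' measure on a mobile element).
#'
#' @param trj A `trajectory`.
#' @param reference Reference frame index or coordinate matrix (default the
#'   first frame).
#' @param fit Selection used for the superposition (default all atoms).
#' @param measure Selection whose RMSD is reported (default the fit selection).
#' @return Tibble (`frame`, `time_ps`, `rmsd`), rmsd in Angstrom.
#' @export
rmsd_series <- function(trj, reference = NULL, fit = NULL, measure = NULL) {
  stopifnot(inherits(trj, "trajectory"))
  ref <- resolve_reference(trj, reference)
  fit_rows <- if (is.null(fit)) seq_len(n_atoms(trj)) else selection_rows(trj$topology, fit)
  meas_rows <- if (is.null(measure)) fit_rows else selection_rows(trj$topology, measure)
  nf <- n_frames(trj)
  val <- numeric(nf)
  for (f in seq_len(nf)) {
    k <- kabsch_superpose(get_frame(trj, f), ref, fit = fit_rows)
    fitted <- k$apply(get_frame(trj, f))
    val[f] <- rmsd_between(fitted[meas_rows, , drop = FALSE],
                           ref[meas_rows, , drop = FALSE])
  }
  tibble(frame = seq_len(nf),
         time_ps = (seq_len(nf) - 1) * trj$time_step_ps,
         rmsd = val)
}

#' Per-residue RMSF about the mean structure
#'
#' Frames are superposed with the two-pass scheme (fit to the first frame,
#' average, refit to the average) before fluctuations are measured. Each
#' residue is reported through its designated atom: CA when present,
#' otherwise its first atom.
#'
#' @param trj A `trajectory` with at least 2 frames.
#' @param selection Atoms/residues to report (default all).
#' @param fit Selection used for superposition (default all atoms).
#' @return Tibble (`resid`, `atom_id`, `rmsf`), rmsf in Angstrom.
#' @export
rmsf <- function(trj, selection = NULL, fit = NULL) {
  stopifnot(inherits(trj, "trajectory"))
  if (n_frames(trj) < 2) stop_usage("RMSF needs at least two frames.")
  fitted <- superpose_trajectory(trj, fit = fit, reference = "mean")
  mean_xyz <- apply(fitted$coords, c(1, 2), mean)
  dev2 <- apply(sweep(fitted$coords, c(1, 2), mean_xyz)^2, 1, mean) * 3
  # mean over frames of squared deviation summed over x,y,z
  per_atom <- sqrt(dev2)
  at <- trj$topology$atoms
  rows <- if (is.null(selection)) seq_len(nrow(at)) else selection_rows(trj$topology, selection)
  sub <- at[rows, ]
  sub$rmsf <- per_atom[rows]
  sub |>
    group_by(.data$resid) |>
    summarise(atom_id = .data$id[if (any(.data$name == "CA")) which(.data$name == "CA")[1] else 1L],
              rmsf = .data$rmsf[if (any(.data$name == "CA")) which(.data$name == "CA")[1] else 1L],
              .groups = "drop")
}

#' Centre-of-mass distance between two atom groups
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology The matching [topology()] (for masses).
#' @param group_a,group_b Selections (expression, selection object, or ids).
#' @param mass_weighted Mass-weight the centroids (default); otherwise
#'   geometric centres.
#' @return Distance in Angstrom.
#' @export
#' @examples
#' top <- bead_topology(2)
#' fr <- rbind(c(0, 0, 0), c(3, 4, 0))
#' com_distance(fr, top, 1, 2)  # 5
com_distance <- function(frame, topology, group_a, group_b,
                         mass_weighted = TRUE) {
  ra <- selection_rows(topology, group_a)
  rb <- selection_rows(topology, group_b)
  ca <- group_com(frame, topology, ra, mass_weighted)
  cb <- group_com(frame, topology, rb, mass_weighted)
  sqrt(sum((ca - cb)^2))
}

group_com <- function(frame, topology, rows, mass_weighted) {
  w <- if (mass_weighted) topology$atoms$mass[rows] else rep(1, length(rows))
  if (sum(w) <= 0) stop_data("zero total mass in COM group.")
  colSums(frame[rows, , drop = FALSE] * w) / sum(w)
}

#' Define a collective variable as a COM distance between two groups
#'
#' @param name CV name (becomes the output column).
#' @param group_a,group_b Disjoint, non-empty selections.
#' @return A `cv_definition`.
#' @export
cv_definition <- function(name, group_a, group_b) {
  if (!nzchar(name)) stop_usage("CV needs a non-empty name.")
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 kind = "com_distance"),
            class = "cv_definition")
}

#' Evaluate collective variables along a trajectory
#'
#' @param trj A `trajectory`.
#' @param definitions A list of [cv_definition()]s (a single one is accepted).
#' @param mass_weighted Passed to [com_distance()].
#' @return Tibble with `frame` plus one column per CV, in definition order.
#' @export
cv_series <- function(trj, definitions, mass_weighted = TRUE) {
  stopifnot(inherits(trj, "trajectory"))
  if (inherits(definitions, "cv_definition")) definitions <- list(definitions)
  top <- trj$topology
  rows <- lapply(definitions, function(d) {
    ra <- selection_rows(top, d$group_a)
    rb <- selection_rows(top, d$group_b)
    if (length(intersect(ra, rb)) > 0) {
      stop_usage(sprintf("CV '%s': groups must be disjoint.", d$name))
    }
    list(a = ra, b = rb)
  })
  nf <- n_frames(trj)
  out <- matrix(NA_real_, nrow = nf, ncol = length(definitions))
  for (f in seq_len(nf)) {
    fr <- get_frame(trj, f)
    for (k in seq_along(definitions)) {
      ca <- group_com(fr, top, rows[[k]]$a, mass_weighted)
      cb <- group_com(fr, top, rows[[k]]$b, mass_weighted)
      out[f, k] <- sqrt(sum((ca - cb)^2))
    }
  }
  res <- as_tibble(as.data.frame(out))
  names(res) <- vapply(definitions, `[[`, character(1), "name")
  dplyr::bind_cols(tibble(frame = seq_len(nf)), res)
}

#' Per-frame distance between two atoms
#'
#' @param trj A `trajectory`.
#' @param atom_a,atom_b Atom ids.
#' @return Tibble (`frame`, `time_ps`, `distance`), Angstrom.
#' @export
distance_series <- function(trj, atom_a, atom_b) {
  stopifnot(inherits(trj, "trajectory"))
  ra <- selection_rows(trj$topology, atom_a)
  rb <- selection_rows(trj$topology, atom_b)
  if (length(ra) != 1 || length(rb) != 1) {
    stop_usage("`atom_a` and `atom_b` must each resolve to one atom.")
  }
  diff <- matrix(trj$coords[ra, , ] - trj$coords[rb, , ], nrow = 3)
  d <- sqrt(colSums(diff^2))
  tibble(frame = seq_len(n_frames(trj)),
         time_ps = (seq_len(n_frames(trj)) - 1) * trj$time_step_ps,
         distance = as.numeric(d))
}
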