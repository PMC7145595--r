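#' Two-dimensional Gaussian state model for collective-variable series
#'
#' Describes a small set of conformational states in a 2D collective-variable
#' space: each state has a (CV1, CV2) mean, per-CV Gaussian widths and a
#' stationary weight. Frames switch state through a Markov resampling move
#' (with probability `switch_prob` the next frame's state is redrawn from the
#' stationary weights), which gives the series realistic autocorrelation while
#' keeping the stationary distribution exactly equal to `weight`.
#'
#' @param states Data frame with columns `cv1`, `cv2` (means, Angstrom),
#'   `sd1`, `sd2` (per-CV standard deviations, Angstrom; a single `sd` column
#'   is accepted for isotropic states) and `weight` (stationary weights,
#'   nonnegative, summing to 1 after normalisation).
#' @param switch_prob Per-frame probability of redrawing the state; in `[0, 1]`.
#' @return A `state_model_2d` object.
#' @export
#' @examples
#' m <- state_model(data.frame(cv1 = c(7.8, 11.0), cv2 = c(9.0, 8.5),
#'                             sd = 0.4, weight = c(0.6, 0.4)))
#' head(gen_cv_series(m, n = 100, seed = 1))
state_model <- function(states, switch_prob = 0.1) {
  states <- as_tibble(states)
  if (!all(c("cv1", "cv2", "weight") %in% names(states))) {
    stop_usage("`states` needs columns cv1, cv2, weight (plus sd or sd1/sd2).")
  }
  if ("sd" %in% names(states) && !all(c("sd1", "sd2") %in% names(states))) {
    states$sd1 <- states$sd
    states$sd2 <- states$sd
  }
  if (!all(c("sd1", "sd2") %in% names(states))) {
    stop_usage("`states` needs per-CV standard deviations (sd or sd1/sd2).")
  }
  if (any(states$sd1 <= 0) || any(states$sd2 <= 0)) {
    stop_parameter("state standard deviations must be > 0.")
  }
  if (any(states$weight < 0) || sum(states$weight) <= 0) {
    stop_parameter("state weights must be nonnegative with a positive sum.")
  }
  states$weight <- states$weight / sum(states$weight)
  check_scalar_number(switch_prob, "switch_prob")
  if (switch_prob < 0 || switch_prob > 1) {
    stop_parameter("`switch_prob` must lie in [0, 1].")
  }
  structure(list(states = states, switch_prob = switch_prob),
            class = "state_model_2d")
}

#' Generate a collective-variable time series from a state model
#'
#' @param model A [state_model()].
#' @param n Number of frames (> 0).
#' @param seed Integer seed (mandatory).
#' @return A tibble with columns `frame`, `cv1`, `cv2` and the ground-truth
#'   `state` label (row index into `model$states`).
#' @export
gen_cv_series <- function(model, n, seed) {
  stopifnot(inherits(model, "state_model_2d"))
  if (!is.numeric(n) || n < 1) stop_usage("`n` must be a positive frame count.")
  seed <- check_seed(seed)
  n <- as.integer(n)
  st <- model$states
  withr::local_seed(seed)
  # Markov resampling chain: state is piecewise-constant between redraw events.
  redraw <- c(TRUE, runif(n - 1) < model$switch_prob)
  k <- sum(redraw)
  drawn <- sample.int(nrow(st), size = k, replace = TRUE, prob = st$weight)
  state <- drawn[cumsum(redraw)]
  tibble(
    frame = seq_len(n),
    cv1 = rnorm(n, mean = st$cv1[state], sd = st$sd1[state]),
    cv2 = rnorm(n, mean = st$cv2[state], sd = st$sd2[state]),
    state = state
  )
}

# bead systems ----------------------------------------------------------------

#' Specify a block-correlated bead system with scheduled contacts
#'
#' Defines a toy "protein" of beads whose per-frame displacements are
#' correlated within ground-truth blocks (communities) and independent across
#' blocks, and whose designated bead pairs are in contact (within
#' `contact_distance`) in an exact, scheduled fraction of frames.
#'
#' @param rest_positions n_beads x 3 matrix of rest coordinates (Angstrom).
#' @param blocks List of integer vectors partitioning `1:n_beads`.
#' @param rho Within-block displacement correlation in `[0, 1]`.
#' @param contacts Data frame with columns `i`, `j`, `occupancy` (fraction of
#'   frames in contact, in `[0, 1]`); may be `NULL`.
#' @param n_frames Number of frames.
#' @param seed Integer seed (mandatory).
#' @param fluct_sd Per-axis displacement standard deviation (Angstrom).
#' @param contact_distance Distance placed between scheduled contact pairs;
#'   must sit below the network cutoff being exercised (default 3.5).
#' @param cutoff Contact cutoff the occupancies are defined against (4.5).
#' @return A `bead_system_spec`.
#' @export
bead_system_spec <- function(rest_positions, blocks, rho, contacts = NULL,
                             n_frames = 1000, seed, fluct_sd = 0.25,
                             contact_distance = 3.5, cutoff = 4.5) {
  rest_positions <- as.matrix(rest_positions)
  nb <- nrow(rest_positions)
  if (ncol(rest_positions) != 3) stop_usage("`rest_positions` must be n x 3.")
  ids <- sort(unlist(blocks))
  if (!identical(ids, seq_len(nb))) {
    stop_spec("`blocks` must partition all beads exactly once.")
  }
  check_scalar_number(rho, "rho")
  if (rho < 0 || rho > 1) stop_parameter("`rho` must lie in [0, 1].")
  seed <- check_seed(seed)
  if (!is.null(contacts)) {
    contacts <- as_tibble(contacts)
    if (!all(c("i", "j", "occupancy") %in% names(contacts))) {
      stop_usage("`contacts` needs columns i, j, occupancy.")
    }
    if (any(contacts$occupancy < 0 | contacts$occupancy > 1)) {
      stop_spec("contact occupancies must lie in [0, 1].")
    }
    # a pair whose rest distance sits near the cutoff cannot realise a clean
    # "out of contact" phase once fluctuations are added
    rest_d <- sqrt(rowSums((rest_positions[contacts$i, , drop = FALSE] -
                            rest_positions[contacts$j, , drop = FALSE])^2))
    margin <- cutoff + 8 * fluct_sd
    bad <- contacts$occupancy < 1 & rest_d <= margin
    if (any(bad)) {
      stop_spec(sprintf(
        "contact pair (%d,%d): rest distance %.2f A cannot realise occupancy %.2f (needs > %.2f A when apart).",
        contacts$i[which(bad)[1]], contacts$j[which(bad)[1]],
        rest_d[which(bad)[1]], contacts$occupancy[which(bad)[1]], margin))
    }
  }
  structure(list(rest_positions = rest_positions, blocks = blocks, rho = rho,
                 contacts = contacts, n_frames = as.integer(n_frames),
                 seed = seed, fluct_sd = fluct_sd,
                 contact_distance = contact_distance, cutoff = cutoff),
            class = "bead_system_spec")
}

#' Generate a bead trajectory with known community and contact ground truth
#'
#' Displacements use a shared-factor construction: beads in the same block mix
#' a common Gaussian factor (weight `sqrt(rho)`) with independent noise, so
#' the pairwise within-block displacement correlation is `rho` and the
#' cross-block correlation is 0 in expectation. Scheduled contact frames place
#' the pair at exactly `contact_distance`, so occupancies are exact up to
#' rounding to whole frames.
#'
#' @param spec A [bead_system_spec()].
#' @return A list with `trajectory`, and ground truth `blocks`, `contacts`
#'   (with the realised `n_contact_frames`), and `rho`.
#' @export
gen_bead_trajectory <- function(spec) {
  stopifnot(inherits(spec, "bead_system_spec"))
  nb <- nrow(spec$rest_positions)
  nf <- spec$n_frames
  withr::local_seed(spec$seed)
  coords <- array(0, dim = c(nb, 3, nf))
  disp <- array(rnorm(nb * 3 * nf, sd = spec$fluct_sd), dim = c(nb, 3, nf))
  if (spec$rho > 0) {
    for (b in spec$blocks) {
      shared <- array(rnorm(3 * nf, sd = spec$fluct_sd), dim = c(1, 3, nf))
      disp[b, , ] <- sqrt(spec$rho) * shared[rep(1, length(b)), , , drop = FALSE] +
        sqrt(1 - spec$rho) * disp[b, , , drop = FALSE]
    }
  }
  for (f in seq_len(nf)) coords[, , f] <- spec$rest_positions + disp[, , f]

  realised <- NULL
  if (!is.null(spec$contacts) && nrow(spec$contacts) > 0) {
    realised <- spec$contacts
    realised$n_contact_frames <- 0L
    for (r in seq_len(nrow(spec$contacts))) {
      i <- spec$contacts$i[r]; j <- spec$contacts$j[r]
      k <- round(spec$contacts$occupancy[r] * nf)
      if (k > 0) {
        sched <- pmin(pmax(round((seq_len(k) - 0.5) * nf / k), 1L), nf)
        u <- spec$rest_positions[j, ] - spec$rest_positions[i, ]
        u <- if (sum(u^2) > 0) u / sqrt(sum(u^2)) else c(1, 0, 0)
        for (f in sched) {
          coords[j, , f] <- coords[i, , f] + u * spec$contact_distance
        }
        realised$n_contact_frames[r] <- length(sched)
      }
    }
  }
  top <- bead_topology(nb)
  list(trajectory = trajectory(top, coords),
       blocks = spec$blocks, contacts = realised, rho = spec$rho)
}

#' Minimal one-bead-per-residue topology
#' @param n Number of beads.
#' @param radius Bead radius in Angstrom.
#' @return A [topology()] with beads named CA.
#' @export
bead_topology <- function(n, radius = 1.7) {
  topology(tibble(id = seq_len(n), name = "CA", element = "C",
                  resid = seq_len(n), resname = "BEA", chain = "A",
                  mass = 12.011, radius = radius))
}

# cavity systems --------------------------------------------------------------

#' Specify a bead shell enclosing a spherical cavity of known volume
#'
#' @param cavity_radius Radius of the empty cavity (Angstrom); 0 builds a
#'   solid reference cluster with no cavity.
#' @param centre Cavity centre (length-3, Angstrom).
#' @param bead_radius Radius of the shell beads.
#' @param n_layers Number of concentric shell layers (>= 1).
#' @param spacing Approximate bead spacing on each layer (Angstrom).
#' @param shell_radius Radius of the innermost bead-centre layer; defaults to
#'   `cavity_radius + bead_radius` so bead surfaces are tangent to the cavity.
#' @return A `cavity_spec`.
#' @export
cavity_spec <- function(cavity_radius, centre = c(0, 0, 0), bead_radius = 1.7,
                        n_layers = 2, spacing = 1.2, shell_radius = NULL) {
  check_scalar_number(cavity_radius, "cavity_radius")
  if (cavity_radius < 0) stop_spec("`cavity_radius` must be >= 0.")
  shell_radius <- shell_radius %||% (cavity_radius + bead_radius)
  if (cavity_radius > 0 && shell_radius - bead_radius < cavity_radius - 1e-9) {
    stop_spec("cavity must sit strictly inside the shell (shell_radius - bead_radius >= cavity_radius).")
  }
  structure(list(cavity_radius = cavity_radius, centre = centre,
                 bead_radius = bead_radius, n_layers = n_layers,
                 spacing = spacing, shell_radius = shell_radius),
            class = "cavity_spec")
}

# near-uniform points on a sphere (golden-spiral layout)
fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a cavity-bearing bead system with analytic ground-truth volume
#'
#' @param spec A [cavity_spec()].
#' @return A list with `trajectory` (single frame), `analytic_volume`
#'   (4/3 pi r^3, cubic Angstrom) and the `spec`.
#' @export
gen_cavity_system <- function(spec) {
  stopifnot(inherits(spec, "cavity_spec"))
  pts <- NULL
  if (spec$cavity_radius > 0) {
    for (l in seq_len(spec$n_layers)) {
      r <- spec$shell_radius + (l - 1) * spec$bead_radius
      n <- max(12L, ceiling(4 * pi * r^2 / spec$spacing^2))
      pts <- rbind(pts, fibonacci_sphere(n, r))
    }
  } else {
    # solid reference cluster: beads packed on a grid filling the shell
    r_out <- spec$shell_radius + (spec$n_layers - 1) * spec$bead_radius
    g <- seq(-r_out, r_out, by = spec$spacing)
    grid <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts <- grid[sqrt(rowSums(grid^2)) <= r_out, , drop = FALSE]
  }
  pts <- sweep(pts, 2, spec$centre, "+")
  top <- bead_topology(nrow(pts), radius = spec$bead_radius)
  list(trajectory = trajectory(top, pts),
       analytic_volume = 4 / 3 * pi * spec$cavity_radius^3,
       spec = spec)
}

# analytic potentials ---------------------------------------------------------

#' Construct an analytic test potential
#'
#' Forms (energies in kcal/mol, coordinates in Angstrom):
#' * `harmonic`: `V = k/2 (x - centre)^2`.
#' * `double_well_1d`: `V = barrier ((x/a)^2 - 1)^2 + tilt/2 (x/a)`; with
#'   `tilt = 0` the minima sit at `x = +-a` and the saddle at `x = 0` is
#'   exactly `barrier` above them.
#' * `two_well_2d`: symmetric double well along x with minima at
#'   `(x_min1, y0)` and `(x_min2, y0)`, saddle exactly `barrier` above the
#'   minima, harmonic (`ky`) in y.
#'
#' An optional dihedral-like channel `V_D = amp/2 (1 - cos(2 pi x / period))`
#' is added to the total energy and exposed separately for dual-boost runs.
#'
#' @param form One of `"harmonic"`, `"double_well_1d"`, `"two_well_2d"`.
#' @param ... Form parameters (see above): `k`, `centre`, `barrier`, `a`,
#'   `tilt`, `x_min1`, `x_min2`, `y0`, `ky`, and `dihedral = list(amp, period)`.
#' @return A `potential` object with functions `value(x)`, `grad(x)`,
#'   `dihedral(x)`, `dihedral_grad(x)` and the dimension `dim`.
#' @export
#' @examples
#' p <- make_potential("harmonic", k = 1)
#' p$value(2)   # 2.0
#' p$grad(2)    # 2.0
make_potential <- function(form, ...) {
  pars <- list(...)
  dih <- pars$dihedral
  if (!is.null(dih)) {
    d_fun <- function(x) dih$amp / 2 * (1 - cos(2 * pi * x1_of(x) / dih$period))
    d_grad1 <- function(x) dih$amp * pi / dih$period * sin(2 * pi * x1_of(x) / dih$period)
  } else {
    d_fun <- function(x) rep(0, n_pts(x))
    d_grad1 <- function(x) rep(0, n_pts(x))
  }
  if (form == "harmonic") {
    k <- pars$k %||% 1
    centre <- pars$centre %||% 0
    base <- function(x) k / 2 * (x - centre)^2
    base_g <- function(x) k * (x - centre)
    pot_1d(form, pars, base, base_g, d_fun, d_grad1)
  } else if (form == "double_well_1d") {
    h <- pars$barrier %||% 1
    a <- pars$a %||% 1
    tilt <- pars$tilt %||% 0
    if (h < 0) stop_parameter("`barrier` must be >= 0.")
    base <- function(x) h * ((x / a)^2 - 1)^2 + tilt / 2 * (x / a)
    base_g <- function(x) 4 * h * (x / a) * ((x / a)^2 - 1) / a + tilt / (2 * a)
    pot_1d(form, pars, base, base_g, d_fun, d_grad1)
  } else if (form == "two_well_2d") {
    h <- pars$barrier %||% 1.5
    x1 <- pars$x_min1 %||% -1
    x2 <- pars$x_min2 %||% 1
    y0 <- pars$y0 %||% 0
    ky <- pars$ky %||% 2
    if (h < 0) stop_parameter("`barrier` must be >= 0.")
    cx <- (x1 + x2) / 2
    a <- abs(x2 - x1) / 2
    val <- function(x) {
      x <- as_points(x, 2)
      u <- (x[, 1] - cx) / a
      h * (u^2 - 1)^2 + ky / 2 * (x[, 2] - y0)^2 + d_fun(x)
    }
    grd <- function(x) {
      x <- as_points(x, 2)
      u <- (x[, 1] - cx) / a
      g <- cbind(4 * h * u * (u^2 - 1) / a + d_grad1(x),
                 ky * (x[, 2] - y0))
      drop_if_single(g)
    }
    structure(list(form = form, params = pars, dim = 2L,
                   value = val, grad = grd,
                   dihedral = function(x) d_fun(as_points(x, 2)),
                   dihedral_grad = function(x) {
                     x <- as_points(x, 2)
                     drop_if_single(cbind(d_grad1(x), rep(0, nrow(x))))
                   }),
              class = "potential")
  } else {
    stop_usage(sprintf("unknown potential form '%s'.", form))
  }
}

n_pts <- function(x) if (is.matrix(x)) nrow(x) else length(x)
x1_of <- function(x) if (is.matrix(x)) x[, 1] else x
as_points <- function(x, dim) {
  if (is.matrix(x)) {
    if (ncol(x) != dim) stop_usage(sprintf("expected %d-column points.", dim))
    x
  } else {
    matrix(x, ncol = dim, byrow = TRUE)
  }
}
drop_if_single <- function(m) if (nrow(m) == 1) drop(m) else m

pot_1d <- function(form, pars, base, base_g, d_fun, d_grad1) {
  structure(list(
    form = form, params = pars, dim = 1L,
    value = function(x) base(x) + d_fun(x),
    grad = function(x) base_g(x) + d_grad1(x),
    dihedral = d_fun,
    dihedral_grad = d_grad1
  ), class = "potential")
}

#' Metropolis Boltzmann sampling of a 2D potential
#'
#' Draws samples from `exp(-V / kT)` with a Gaussian random-walk proposal.
#' Used to turn an analytic surface with a known saddle into a synthetic
#' collective-variable series for landscape recovery tests.
#'
#' @param potential A 2D [make_potential()] object.
#' @param n Number of samples to return.
#' @param temperature Temperature in Kelvin.
#' @param seed Integer seed (mandatory).
#' @param x0 Starting point (length 2); defaults to `c(0, 0)`.
#' @param step_sd Proposal standard deviation per coordinate (Angstrom).
#' @param burn_in Number of discarded initial moves.
#' @return Tibble with columns `frame`, `cv1`, `cv2`; the acceptance rate is
#'   attached as attribute `acceptance`.
#' @export
sample_potential_2d <- function(potential, n, temperature = 300, seed,
                                x0 = c(0, 0), step_sd = 0.3, burn_in = 1000) {
  stopifnot(inherits(potential, "potential"), potential$dim == 2L)
  seed <- check_seed(seed)
  n <- as.integer(n)
  beta <- 1 / kT(temperature)
  vfun <- potential$value
  withr::local_seed(seed)
  total <- n + burn_in
  dx <- matrix(rnorm(2 * total, sd = step_sd), ncol = 2)
  lu <- log(runif(total))
  out <- matrix(NA_real_, nrow = total, ncol = 2)
  x <- x0
  vx <- vfun(matrix(x, ncol = 2))
  acc <- 0L
  for (i in seq_len(total)) {
    xp <- x + dx[i, ]
    vp <- vfun(matrix(xp, ncol = 2))
    if (lu[i] < beta * (vx - vp)) {
      x <- xp; vx <- vp; acc <- acc + 1L
    }
    out[i, ] <- x
  }
  res <- tibble(frame = seq_len(n),
                cv1 = out[(burn_in + 1):total, 1],
                cv2 = out[(burn_in + 1):total, 2])
  attr(res, "acceptance") <- acc / total
  res
}
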