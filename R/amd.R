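#' Dual-boost acceleration parameters
#'
#' Holds the reference energies and acceleration factors of the dual-boost
#' scheme. Below the reference `E_P` a boost
#' `(E_P - V)^2 / (alpha_P + E_P - V)` is added to the total potential energy,
#' and analogously with (`E_D`, `alpha_D`) for the dihedral-like energy
#' component; above the references the surface is untouched. `mode` selects
#' which channels are active.
#'
#' @param mode One of `"none"`, `"total"`, `"dihedral"`, `"dual"`.
#' @param E_P,alpha_P Reference total energy and acceleration (kcal/mol);
#'   `alpha_P` must be > 0 when the total channel is active.
#' @param E_D,alpha_D Reference dihedral energy and acceleration (kcal/mol).
#' @return An `amd_params` object.
#' @export
#' @examples
#' amd_params("total", E_P = -90, alpha_P = 10)
amd_params <- function(mode = c("none", "total", "dihedral", "dual"),
                       E_P = NULL, alpha_P = NULL, E_D = NULL, alpha_D = NULL) {
  mode <- match.arg(mode)
  total_on <- mode %in% c("total", "dual")
  dih_on <- mode %in% c("dihedral", "dual")
  if (total_on) {
    if (is.null(E_P) || is.null(alpha_P)) {
      stop_parameter("total-energy channel needs E_P and alpha_P.")
    }
    if (alpha_P <= 0) stop_parameter("`alpha_P` must be > 0 for an active channel.")
  }
  if (dih_on) {
    if (is.null(E_D) || is.null(alpha_D)) {
      stop_parameter("dihedral channel needs E_D and alpha_D.")
    }
    if (alpha_D <= 0) stop_parameter("`alpha_D` must be > 0 for an active channel.")
  }
  structure(list(mode = mode, E_P = E_P, alpha_P = alpha_P,
                 E_D = E_D, alpha_D = alpha_D,
                 total_on = total_on, dihedral_on = dih_on),
            class = "amd_params")
}

#' Choose boost references from an unboosted pre-run
#'
#' A common desk-scale heuristic: set the reference energy four standard
#' deviations above the mean of a short unboosted run and the acceleration to
#' one standard deviation, per channel.
#'
#' @param V Vector of total potential energies from a pre-run (kcal/mol).
#' @param V_D Optional vector of dihedral-component energies.
#' @param mode Requested boost mode.
#' @return An [amd_params()] object.
#' @export
amd_params_from_prerun <- function(V, V_D = NULL,
                                   mode = c("total", "dual", "dihedral")) {
  mode <- match.arg(mode)
  if (length(V) < 2) stop_usage("pre-run must contain at least 2 samples.")
  args <- list(mode = mode)
  if (mode %in% c("total", "dual")) {
    args$E_P <- mean(V) + 4 * sd(V)
    args$alpha_P <- max(sd(V), 1e-8)
  }
  if (mode %in% c("dihedral", "dual")) {
    if (is.null(V_D)) stop_usage("dihedral channel requested but no V_D given.")
    args$E_D <- mean(V_D) + 4 * sd(V_D)
    args$alpha_D <- max(sd(V_D), 1e-8)
  }
  do.call(amd_params, args)
}

#' Boost energy of the dual-boost scheme
#'
#' @param V Total potential energy (kcal/mol); vectorised.
#' @param V_D Dihedral-component energy (kcal/mol); vectorised.
#' @param params An [amd_params()].
#' @return The nonnegative boost `dV` (kcal/mol), zero wherever both active
#'   channels are at or above their references.
#' @export
#' @examples
#' p <- amd_params("total", E_P = -90, alpha_P = 50)
#' boost_energy(-80, 0, p)          # above threshold: 0
#' boost_energy(-100, 0, p)         # 10^2 / (50 + 10)
boost_energy <- function(V, V_D = 0, params) {
  stopifnot(inherits(params, "amd_params"))
  if (!all(is.finite(V)) || !all(is.finite(V_D))) {
    stop_usage("energies must be finite.")
  }
  dv <- numeric(max(length(V), length(V_D)))
  if (params$total_on) {
    u <- params$E_P - V
    dv <- dv + ifelse(u > 0, u^2 / (params$alpha_P + u), 0)
  }
  if (params$dihedral_on) {
    u <- params$E_D - V_D
    dv <- dv + ifelse(u > 0, u^2 / (params$alpha_D + u), 0)
  }
  dv
}

# d(V + boost)/dV per channel: alpha^2 / (alpha + E - V)^2 below threshold, 1 above.
boost_scale <- function(E, alpha, V) {
  u <- E - V
  ifelse(u > 0, alpha^2 / (alpha + u)^2, 1)
}

#' Force on the boosted surface
#'
#' Returns `-grad V*` at `x`. Below the total-energy reference the force is
#' scaled by `alpha_P^2 / (alpha_P + E_P - V)^2` (chain rule on the boost),
#' with the analogous extra term for the dihedral channel.
#'
#' @param x Position (scalar for 1D potentials, length-2 for 2D).
#' @param potential A [make_potential()] object (must provide a gradient).
#' @param params An [amd_params()].
#' @return The force vector `-grad V*(x)`.
#' @export
modified_force <- function(x, potential, params) {
  stopifnot(inherits(potential, "potential"), inherits(params, "amd_params"))
  if (is.null(potential$grad)) {
    abort("potential does not provide a gradient.",
          class = "allostera_capability_error")
  }
  g <- potential$grad(x)
  if (params$mode == "none") return(-g)
  V <- potential$value(x)
  gs <- g
  if (params$total_on) {
    gs <- gs * boost_scale(params$E_P, params$alpha_P, V)
  }
  if (params$dihedral_on) {
    vd <- potential$dihedral(x)
    sD <- boost_scale(params$E_D, params$alpha_D, vd)
    gs <- gs + (sD - 1) * potential$dihedral_grad(x)
  }
  -gs
}

#' Settings for the overdamped Langevin integrator
#'
#' @param timestep Integration timestep (ps-like reduced units, > 0).
#' @param n_steps Number of steps (>= 1).
#' @param x0 Initial position.
#' @param seed Integer seed (mandatory).
#' @param friction Friction coefficient (> 0).
#' @param temperature Temperature in Kelvin.
#' @param record_stride Record every `record_stride`-th step.
#' @return A `langevin_settings` object.
#' @export
langevin_settings <- function(timestep, n_steps, x0, seed, friction = 1,
                              temperature = 300, record_stride = 1L) {
  check_scalar_number(timestep, "timestep", positive = TRUE)
  check_scalar_number(friction, "friction", positive = TRUE)
  check_scalar_number(temperature, "temperature", positive = TRUE)
  if (!is.numeric(n_steps) || n_steps < 1) stop_parameter("`n_steps` must be >= 1.")
  structure(list(timestep = timestep, n_steps = as.integer(n_steps), x0 = x0,
                 seed = check_seed(seed), friction = friction,
                 temperature = temperature,
                 record_stride = as.integer(record_stride)),
            class = "langevin_settings")
}

#' Overdamped Langevin dynamics on a (possibly boosted) surface
#'
#' Euler--Maruyama position updates
#' `x <- x + F*(x) dt / gamma + sqrt(2 kT dt / gamma) xi` where `F*` is the
#' force on the boosted surface (or the plain force when `mode = "none"`).
#' Temperature enters only through the noise, so equilibrium sampling of the
#' target surface is exact up to discretisation.
#'
#' @param potential A [make_potential()] object.
#' @param params An [amd_params()].
#' @param settings A [langevin_settings()].
#' @return A tibble (`step`, `x` (and `y` in 2D), `V`, `V_D`, `dV`).
#' @export
run_langevin <- function(potential, params, settings) {
  stopifnot(inherits(potential, "potential"), inherits(params, "amd_params"),
            inherits(settings, "langevin_settings"))
  d <- potential$dim
  dt <- settings$timestep
  gam <- settings$friction
  ns <- settings$n_steps
  noise_sd <- sqrt(2 * kT(settings$temperature) * dt / gam)
  withr::local_seed(settings$seed)
  noise <- matrix(rnorm(ns * d, sd = noise_sd), ncol = d)
  stride <- settings$record_stride
  n_rec <- ns %/% stride
  rec <- matrix(NA_real_, nrow = n_rec, ncol = d + 4)
  x <- as.numeric(settings$x0)
  if (length(x) != d) stop_usage("`x0` length must match the potential dimension.")
  k <- 0L
  for (i in seq_len(ns)) {
    f <- modified_force(x, potential, params)
    x <- x + f * dt / gam + noise[i, ]
    if (!all(is.finite(x))) {
      abort(sprintf("integration diverged at step %d.", i),
            class = "allostera_integration_error")
    }
    if (i %% stride == 0L) {
      k <- k + 1L
      V <- potential$value(x)
      vd <- potential$dihedral(x)
      if (!is.finite(V) || !is.finite(vd)) {
        abort(sprintf("integration diverged at step %d.", i),
              class = "allostera_integration_error")
      }
      rec[k, ] <- c(i, x, V, vd, boost_energy(V, vd, params))
    }
  }
  cols <- c("step", if (d == 1) "x" else c("x", "y"), "V", "V_D", "dV")
  out <- as_tibble(as.data.frame(rec))
  names(out) <- cols
  out
}

#' Count well-to-well transitions by midpoint crossing
#'
#' @param x Position series.
#' @param midpoint Dividing surface between the wells.
#' @return Number of crossings of `midpoint`.
#' @export
count_transitions <- function(x, midpoint = 0) {
  sum(abs(diff(x > midpoint)))
}

#' Reweighted (or unweighted) free-energy profile from boosted samples
#'
#' Each sample contributes the Boltzmann factor of its boost,
#' `exp(dV / kT)`; bins accumulate those weights and
#' `F = -kT log(weight)`, shifted so the minimum is zero. With `dV = 0`
#' throughout (or `reweight = FALSE`) this reduces to the ordinary unweighted
#' profile. One- and two-dimensional records are supported (columns `x`
#' and optionally `y`).
#'
#' @param records Tibble from [run_langevin()] (needs `x`, optionally `y`,
#'   and `dV`).
#' @param breaks Number of bins per axis, or a vector of break points (1D).
#' @param temperature Temperature in Kelvin.
#' @param reweight If `FALSE`, ignore the boost weights.
#' @return Tibble with bin centres (`x`, and `y` in 2D), `count`, `weight`
#'   and free energy `F` (kcal/mol, min-shifted to 0).
#' @export
reweight_profile <- function(records, breaks = 50, temperature = 300,
                             reweight = TRUE) {
  if (is.null(records) || nrow(records) == 0) {
    stop_usage("`records` must contain at least one sample.")
  }
  kt <- kT(temperature)
  dv <- if ("dV" %in% names(records)) records$dV else rep(0, nrow(records))
  if (!reweight) dv <- rep(0, nrow(records))
  logw <- (dv - max(dv)) / kt
  two_d <- "y" %in% names(records)
  bin_axis <- function(v, breaks) {
    if (length(breaks) == 1) {
      breaks <- seq(min(v), max(v), length.out = breaks + 1)
      breaks[1] <- breaks[1] - 1e-9
      breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
    }
    idx <- findInterval(v, breaks, rightmost.closed = TRUE)
    idx[idx < 1 | idx > length(breaks) - 1] <- NA
    list(idx = idx, mid = (breaks[-1] + breaks[-length(breaks)]) / 2)
  }
  bx <- bin_axis(records$x, breaks)
  if (two_d) {
    by <- bin_axis(records$y, breaks)
    key <- interaction(bx$idx, by$idx, drop = FALSE)
    df <- tibble(ix = bx$idx, iy = by$idx, logw = logw)
    agg <- df |>
      filter(!is.na(.data$ix), !is.na(.data$iy)) |>
      group_by(.data$ix, .data$iy) |>
      summarise(count = n(),
                lsw = log_sum_exp(.data$logw), .groups = "drop")
    out <- tibble(x = bx$mid[agg$ix], y = by$mid[agg$iy],
                  count = agg$count, weight = exp(agg$lsw),
                  F = -kt * agg$lsw)
  } else {
    df <- tibble(ix = bx$idx, logw = logw)
    agg <- df |>
      filter(!is.na(.data$ix)) |>
      group_by(.data$ix) |>
      summarise(count = n(), lsw = log_sum_exp(.data$logw), .groups = "drop")
    out <- tibble(x = bx$mid[agg$ix], count = agg$count,
                  weight = exp(agg$lsw), F = -kt * agg$lsw)
  }
  out$F <- out$F - min(out$F)
  out
}

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}
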