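# Boltzmann constant in kcal/mol/K; kT at 300 K = 0.59616 kcal/mol.
KB_KCAL <- 0.0019872

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol.
#' @export
#' @examples
#' kT(300)
kT <- function(temperature = 300) {
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be a positive number (K).",
          class = "allostera_parameter_error")
  }
  KB_KCAL * temperature
}

# classed abort helpers -------------------------------------------------------

stop_format <- function(msg) abort(msg, class = "allostera_format_error")
stop_usage <- function(msg) abort(msg, class = "allostera_usage_error")
stop_parameter <- function(msg) abort(msg, class = "allostera_parameter_error")
stop_spec <- function(msg) abort(msg, class = "allostera_spec_error")
stop_selection <- function(msg) abort(msg, class = "allostera_selection_error")
stop_topology <- function(msg) abort(msg, class = "allostera_topology_error")
stop_data <- function(msg) abort(msg, class = "allostera_data_error")
stop_config <- function(msg) abort(msg, class = "allostera_config_error")

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_parameter(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    stop_parameter(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Seeds are mandatory throughout the synthetic generators; they are applied
# locally so user RNG state is never clobbered.
check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_usage("a single integer `seed` is required (never defaulted silently).")
  }
  as.integer(seed)
}

elements_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, FE = 55.845, ZN = 65.38, MG = 24.305, NA. = 22.99,
  CL = 35.45, K = 39.098, CA = 40.078, X = 12.011
)

element_mass <- function(element) {
  el <- toupper(element)
  m <- elements_masses[el]
  m[is.na(m)] <- elements_masses[["X"]]
  unname(m)
}
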