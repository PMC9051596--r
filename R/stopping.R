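# Stopping power of liquid water and CSDA ranges.

#' Load the water stopping-power table
#'
#' Collision stopping power of electrons in liquid water on a ~30-point
#' logarithmic grid (0.1 keV - 2 MeV), with the cumulative CSDA range
#' integral precomputed by trapezoidal quadrature of `1/S(E)` in log-energy.
#'
#' @param path optional path to a 2-column table (`energy_keV`,
#'   `stopping_keV_per_um`); default is the shipped reference table.
#' @return object of class `stopping_power_table` with fields `energy_keV`,
#'   `stopping_keV_per_um`, `csda_um` (range at each node), and a refined
#'   log-spaced range grid (`range_energy_keV`, `range_um`) used for
#'   interpolation by [csda_range()] and the transport stepper.
#' @export
water_stopping_power <- function(path = system.file("extdata", "water_stopping_power.tsv",
                                                    package = "lutadsb")) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (any(tab$stopping_keV_per_um <= 0)) stop("stopping power must be positive")
  if (is.unsorted(tab$energy_keV, strictly = TRUE)) stop("energy grid must be increasing")
  e <- tab$energy_keV; s <- tab$stopping_keV_per_um
  # trapezoid of 1/S on a refined log grid (kept for interpolation: linear
  # node-to-node interpolation of the range is otherwise ~1% biased)
  grid <- exp(seq(log(e[1]), log(e[length(e)]), length.out = 60L * length(e)))
  sg <- exp(approx(log(e), log(s), xout = log(grid), rule = 2)$y)
  inv <- 1 / sg
  cr <- c(0, cumsum((inv[-1] + inv[-length(inv)]) / 2 * diff(grid)))
  structure(list(
    energy_keV = e,
    stopping_keV_per_um = s,
    csda_um = approx(grid, cr, xout = e, rule = 2)$y,
    range_energy_keV = grid,
    range_um = cr
  ), class = "stopping_power_table")
}

#' Interpolated stopping power
#' @param energy_keV energies (vector), within the table support.
#' @param table a [water_stopping_power()] table.
#' @return stopping power in keV/um (log-log interpolation).
#' @export
stopping_power_at <- function(energy_keV, table = water_stopping_power()) {
  check_support(energy_keV, table)
  exp(approx(log(table$energy_keV), log(table$stopping_keV_per_um),
             xout = log(energy_keV), rule = 2)$y)
}

#' CSDA range
#'
#' Continuous-slowing-down-approximation range
#' `integral from E_min to E of dE'/S(E')` by quadrature on the grid, i.e. the
#' path length an electron travels before slowing to the bottom of the table
#' (0.1 keV, the tracking cutoff).
#'
#' @param energy_keV energies (vector), within the table support.
#' @param table a [water_stopping_power()] table.
#' @return range in um; monotone in energy.
#' @export
csda_range <- function(energy_keV, table = water_stopping_power()) {
  check_support(energy_keV, table)
  approx(table$range_energy_keV, table$range_um, xout = energy_keV, rule = 2)$y
}

check_support <- function(energy_keV, table) {
  lo <- table$energy_keV[1]; hi <- table$energy_keV[length(table$energy_keV)]
  if (any(energy_keV < lo - 1e-12) || any(energy_keV > hi + 1e-12))
    stop(sprintf("energy outside table support [%g, %g] keV", lo, hi))
  invisible(TRUE)
}

#' Transport settings
#'
#' @param tracking_cutoff_keV electrons below this kinetic energy deposit
#'   locally (default 0.1 keV = 100 eV).
#' @param delta_production_threshold_keV secondary (delta-ray) production
#'   threshold (default 1.75 keV, the energy matching a 0.2 um range cut in
#'   liquid water); set `Inf` to disable explicit secondaries.
#' @param max_step_um step-length cap far from the scored nucleus.
#' @param straggling_enabled Gaussian restricted energy-loss straggling.
#' @param scattering_enabled Highland-style multiple Coulomb scattering.
#' @return object of class `transport_settings`.
#' @export
transport_settings <- function(tracking_cutoff_keV = 0.1,
                               delta_production_threshold_keV = 1.75,
                               max_step_um = 10,
                               straggling_enabled = TRUE,
                               scattering_enabled = TRUE) {
  if (max_step_um <= 0) stop("max_step_um must be positive")
  if (tracking_cutoff_keV >= delta_production_threshold_keV)
    stop("tracking cutoff must be below the delta production threshold")
  structure(list(
    tracking_cutoff_keV = tracking_cutoff_keV,
    delta_production_threshold_keV = delta_production_threshold_keV,
    max_step_um = max_step_um,
    straggling_enabled = isTRUE(straggling_enabled),
    scattering_enabled = isTRUE(scattering_enabled)
  ), class = "transport_settings")
}
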