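# R-side transport interface: single histories, phase-space campaigns, and
# the delimited phase-space file format.

nucleus_to_cpp <- function(nucleus) {
  list(type = if (nucleus$kind == "ellipsoid") 0L else 1L,
       half_axes = nucleus$half_axes, center = nucleus$center)
}

world_to_cpp <- function(medium) {
  list(radius = medium$radius, height = medium$height,
       cx = medium$center_xy[1], cy = medium$center_xy[2])
}

#' Transport a single electron history
#'
#' Condensed-history transport of one emission event (and all its delta-ray
#' secondaries) through water, scoring energy deposits, crossings into the
#' scored nucleus, and energy escaping the medium cylinder. Energy is
#' conserved exactly: initial = sum(deposits) + escaped.
#'
#' @param event list or one-row data.frame with `x`, `y`, `z` (um), `ux`,
#'   `uy`, `uz` (unit direction) and `energy_keV`.
#' @param nucleus scored [nucleus_shape()].
#' @param medium the world [medium_cylinder()].
#' @param settings a [transport_settings()].
#' @param table a [water_stopping_power()] table.
#' @return list with `deposits` (data.frame `x,y,z,amount_keV,in_nucleus,
#'   step_um`), `entries` (data.frame of nucleus-entry records),
#'   `escaped_keV`, `deposited_keV`, `nucleus_keV`.
#' @export
transport_electron <- function(event, nucleus, medium = medium_cylinder(),
                               settings = transport_settings(),
                               table = water_stopping_power()) {
  d <- c(event$ux, event$uy, event$uz)
  if (abs(sqrt(sum(d^2)) - 1) > 1e-6) stop("event direction must be a unit vector")
  if (event$energy_keV <= 0) stop("event energy must be positive")
  res <- cpp_transport_electron(c(event$x, event$y, event$z), d, event$energy_keV,
                                nucleus_to_cpp(nucleus), world_to_cpp(medium),
                                unclass(table), unclass(settings), TRUE)
  dep <- as.data.frame(res$deposits)
  names(dep) <- c("x", "y", "z", "amount_keV", "in_nucleus", "step_um")
  dep$in_nucleus <- dep$in_nucleus > 0
  ent <- as.data.frame(res$entries)
  names(ent) <- c("x", "y", "z", "ux", "uy", "uz", "energy_keV")
  list(deposits = dep, entries = ent, escaped_keV = res$escaped_keV,
       deposited_keV = res$deposited_keV, nucleus_keV = res$nucleus_keV)
}

#' Isotropic unit directions
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors uniform on the sphere.
#' @export
sample_isotropic_direction <- function(n = 1L) {
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(ux = r * cos(phi), uy = r * sin(phi), uz = z)
}

#' Run a phase-space campaign
#'
#' Samples `n_primaries` emission events of one particle type from one source
#' mode, transports each through the geometry, and scores (a) a phase-space
#' record for every particle crossing into the central nucleus (re-entries
#' and delta rays share the primary's event identifier) and (b) per-event
#' energy imparted to the nucleus. Campaigns for beta and IC electrons and
#' for cell and medium sources are run separately, mirroring the source
#' separation of the measurement chain.
#'
#' @param population a [build_planar_population()].
#' @param scheme a [decay_scheme()].
#' @param scenario an [activity_scenario()].
#' @param particle `"beta"` or `"ic"`.
#' @param source_mode `"cell"` or `"medium"`.
#' @param n_primaries number of primary decays to sample.
#' @param medium the [medium_cylinder()] world.
#' @param settings a [transport_settings()].
#' @param table a [water_stopping_power()] table.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return object of class `ps_campaign`: `phase_space` data.frame (columns
#'   `event_id, x_um, y_um, z_um, ux, uy, uz, energy_keV, particle,
#'   origin_compartment`), `nucleus_deposits` data.frame (in-nucleus energy
#'   deposits with positions and step lengths), `event_nucleus_keV`,
#'   `event_energy_keV`, `event_deposited_keV`, `event_escaped_keV` vectors,
#'   plus `n_primaries`, `particle`, `source_mode`.
#' @export
run_phase_space_campaign <- function(population, scheme, scenario,
                                     particle = c("beta", "ic"),
                                     source_mode = c("cell", "medium"),
                                     n_primaries = 1000L,
                                     medium = NULL,
                                     settings = transport_settings(),
                                     table = water_stopping_power(),
                                     seed = NULL) {
  particle <- match.arg(particle)
  source_mode <- match.arg(source_mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(medium)) {
    ctr <- population$placements[population$central_index, ]
    medium <- medium_cylinder(center_xy = c(ctr[1], ctr[2]))
  }
  sites <- sample_emission_site(scenario, population, medium, source_mode, n_primaries)
  dirs <- sample_isotropic_direction(n_primaries)
  energies <- if (particle == "beta") sample_beta_energy(scheme, n_primaries)
              else sample_ic_energy(scheme, n_primaries)

  nuc <- central_nucleus(population)
  res <- cpp_run_campaign(as.matrix(sites[, c("x", "y", "z")]), dirs, energies,
                          nucleus_to_cpp(nuc), world_to_cpp(medium),
                          unclass(table), unclass(settings))

  ent <- as.data.frame(res$entries)
  if (nrow(ent)) {
    names(ent) <- c("event_id", "x_um", "y_um", "z_um", "ux", "uy", "uz", "energy_keV")
    ent$event_id <- as.integer(ent$event_id)
    ent$particle <- particle
    ent$origin_compartment <- sites$origin_compartment[ent$event_id]
  } else {
    ent <- empty_phase_space()
  }
  ndep <- as.data.frame(res$nucleus_deposits)
  if (nrow(ndep)) {
    names(ndep) <- c("event_id", "x", "y", "z", "amount_keV", "step_um")
    ndep$event_id <- as.integer(ndep$event_id)
  } else {
    ndep <- data.frame(event_id = integer(), x = numeric(), y = numeric(),
                       z = numeric(), amount_keV = numeric(), step_um = numeric())
  }
  structure(list(
    phase_space = ent,
    nucleus_deposits = ndep,
    event_nucleus_keV = res$event_nucleus_keV,
    event_energy_keV = energies,
    event_deposited_keV = res$event_deposited_keV,
    event_escaped_keV = res$event_escaped_keV,
    n_primaries = as.integer(n_primaries),
    particle = particle, source_mode = source_mode,
    nucleus = nuc
  ), class = "ps_campaign")
}

empty_phase_space <- function() {
  data.frame(event_id = integer(), x_um = numeric(), y_um = numeric(),
             z_um = numeric(), ux = numeric(), uy = numeric(), uz = numeric(),
             energy_keV = numeric(), particle = character(),
             origin_compartment = character(), stringsAsFactors = FALSE)
}

#' Write / read a phase-space file
#'
#' Delimited text, one row per nucleus-entry record, header naming the
#' columns `event_id, x_um, y_um, z_um, ux, uy, uz, energy_keV, particle,
#' origin_compartment`. Numeric columns round-trip losslessly to at least 6
#' significant digits (written at 10).
#'
#' @param phase_space data.frame in phase-space layout (or a `ps_campaign`).
#' @param path output file.
#' @return `read_phase_space` returns the data.frame.
#' @export
write_phase_space <- function(phase_space, path) {
  if (inherits(phase_space, "ps_campaign")) phase_space <- phase_space$phase_space
  df <- phase_space
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_space
#' @export
read_phase_space <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$event_id <- as.integer(df$event_id)
  df
}
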