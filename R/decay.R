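# Lu-177 source term: decay scheme, emission-energy sampling (continuous beta
# spectrum + discrete conversion-electron lines), emission-site sampling over
# cell compartments and medium, and activity -> cumulated decays.

#' Decay scheme
#'
#' Electron emissions of the radionuclide: continuous beta branches given by
#' endpoint energy and branching probability, and discrete internal-conversion
#' (IC) electron lines given by energy and intensity per decay. Emission
#' yields default to 1 beta and 0.15 IC electrons per decay. Photons and Auger
#' electrons are excluded by design (negligible for this cellular dosimetry).
#'
#' @param beta_branches data.frame with columns `endpoint_keV`, `probability`
#'   (probabilities are normalized to sum to 1).
#' @param ic_lines data.frame with columns `energy_keV`, `intensity`.
#' @param yield_beta,yield_ic emissions per decay (defaults 1 and 0.15).
#' @param half_life_h physical half-life in hours (Lu-177: 159.528 h).
#' @param daughter_z atomic number of the daughter nuclide for the Fermi
#'   function (Hf: 72).
#' @param beta_spectrum optional fully tabulated beta spectrum (data.frame
#'   with `energy_keV`, `density`); when given it replaces the Fermi-theory
#'   spectral shape.
#' @return object of class `decay_scheme`.
#' @export
decay_scheme <- function(beta_branches, ic_lines,
                         yield_beta = 1, yield_ic = 0.15,
                         half_life_h = 159.528, daughter_z = 72,
                         beta_spectrum = NULL) {
  if (nrow(beta_branches) == 0) stop("empty beta branch list")
  if (any(beta_branches$endpoint_keV <= 0) || any(ic_lines$energy_keV <= 0))
    stop("all emission energies must be positive")
  if (any(beta_branches$probability < 0)) stop("negative branch probability")
  beta_branches$probability <- beta_branches$probability / sum(beta_branches$probability)
  sch <- structure(list(
    beta_branches = beta_branches, ic_lines = ic_lines,
    yield_beta = yield_beta, yield_ic = yield_ic,
    half_life_h = half_life_h, daughter_z = daughter_z,
    beta_spectrum = beta_spectrum
  ), class = "decay_scheme")
  sch$beta_cdf <- build_beta_cdf(sch)
  sch
}

#' Read a decay scheme from a sectioned delimited text file
#'
#' Format: optional `# half_life_h: <hours>` comment, a `[beta]` section with
#' `endpoint_keV,probability` rows and an `[ic]` section with
#' `energy_keV,intensity` rows.
#'
#' @param path file path; default is the Lu-177 table shipped with the package.
#' @param ... passed to [decay_scheme()].
#' @return object of class `decay_scheme`.
#' @export
read_decay_scheme <- function(path = system.file("extdata", "lu177_decay_scheme.txt",
                                                 package = "lutadsb"), ...) {
  lines <- readLines(path)
  hl <- grep("half_life_h:", lines, value = TRUE)
  half_life <- if (length(hl)) as.numeric(sub(".*half_life_h:\\s*", "", hl[1])) else 159.528
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  ib <- which(lines == "[beta]"); ii <- which(lines == "[ic]")
  if (!length(ib) || !length(ii)) stop("decay scheme file needs [beta] and [ic] sections")
  parse_sec <- function(from, to) {
    block <- lines[(from + 1L):(to)]
    read.table(text = paste(block, collapse = "\n"), sep = ",", header = TRUE)
  }
  beta <- parse_sec(ib, if (ii > ib) ii - 1L else length(lines))
  ic <- parse_sec(ii, if (ib > ii) ib - 1L else length(lines))
  decay_scheme(beta, ic, half_life_h = half_life, ...)
}

#' The shipped Lu-177 default scheme
#' @return object of class `decay_scheme`.
#' @export
lu177_default_scheme <- function() read_decay_scheme()

#' Allowed-transition beta spectral density (unnormalized)
#'
#' Fermi-theory allowed shape `N(E) ~ F(Z, E) p E_tot (Q - E)^2` with the
#' relativistic point-charge Fermi function approximated as
#' `F = 2 pi eta / (1 - exp(-2 pi eta))`, `eta = alpha Z / beta_v`. Screening
#' is omitted; the scheme also accepts a fully tabulated spectrum instead.
#'
#' @param energy_keV kinetic energies (vector).
#' @param endpoint_keV branch endpoint.
#' @param z daughter atomic number.
#' @return unnormalized density values (0 outside the support).
#' @export
beta_spectral_density <- function(energy_keV, endpoint_keV, z = 72) {
  E <- energy_keV
  ok <- E > 0 & E < endpoint_keV
  out <- numeric(length(E))
  if (!any(ok)) return(out)
  Et <- E[ok] + ELECTRON_MASS_KEV
  pc <- sqrt(Et^2 - ELECTRON_MASS_KEV^2)
  beta_v <- pc / Et
  eta <- (z / 137.035999) / beta_v
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  out[ok] <- fermi * pc * Et * (endpoint_keV - E[ok])^2
  out
}

# per-branch inverse-CDF tables on a fine grid (cached inside the scheme)
build_beta_cdf <- function(scheme) {
  if (!is.null(scheme$beta_spectrum)) {
    tab <- scheme$beta_spectrum
    dens <- pmax(tab$density, 0)
    cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(tab$energy_keV))
    cdf <- c(0, cdf) / max(cdf)
    return(list(list(energy = tab$energy_keV, cdf = cdf, weight = 1)))
  }
  lapply(seq_len(nrow(scheme$beta_branches)), function(i) {
    q <- scheme$beta_branches$endpoint_keV[i]
    e <- seq(1e-3, q, length.out = 1024L)
    d <- beta_spectral_density(e, q, scheme$daughter_z)
    cdf <- cumsum((d[-1] + d[-length(d)]) / 2 * diff(e))
    cdf <- c(0, cdf) / max(cdf)
    list(energy = e, cdf = cdf, weight = scheme$beta_branches$probability[i])
  })
}

#' Sample beta kinetic energies
#'
#' Chooses a branch by branching probability, then draws from that branch's
#' allowed-transition spectral shape by inverse-CDF interpolation.
#'
#' @param scheme a [decay_scheme()].
#' @param n number of draws.
#' @return energies in keV, all below the chosen branch endpoints.
#' @export
sample_beta_energy <- function(scheme, n = 1L) {
  tabs <- scheme$beta_cdf
  w <- vapply(tabs, `[[`, numeric(1), "weight")
  br <- sample.int(length(tabs), n, replace = TRUE, prob = w)
  u <- runif(n)
  out <- numeric(n)
  for (i in seq_along(tabs)) {
    sel <- br == i
    if (any(sel))
      out[sel] <- approx(tabs[[i]]$cdf, tabs[[i]]$energy, xout = u[sel],
                         ties = "ordered", rule = 2)$y
  }
  out
}

#' Sample internal-conversion electron line energies
#' @param scheme a [decay_scheme()].
#' @param n number of draws.
#' @return line energies in keV drawn proportionally to intensity.
#' @export
sample_ic_energy <- function(scheme, n = 1L) {
  lines <- scheme$ic_lines
  if (nrow(lines) == 0) stop("ic_lines is empty")
  if (all(lines$intensity <= 0)) stop("all IC intensities are zero")
  if (nrow(lines) == 1L) return(rep(lines$energy_keV, n))
  lines$energy_keV[sample.int(nrow(lines), n, replace = TRUE, prob = lines$intensity)]
}

#' Activity scenario
#'
#' Exposure conditions: added activity, exposure time, the measured uptake
#' split between internalized and membrane-bound activity (73% / 27% at
#' 2.5 MBq/mL), the internalization compartment hypothesis (Golgi or
#' cytoplasm), and the conversion from added activity to cell-bound activity.
#' Uptake is instant and permanent (no efflux). `uptake_per_cell` (Bq bound
#' per cell per MBq/mL added) and `medium_fraction` are synthetic defaults —
#' the underlying uptake assay values are not published — and every
#' downstream equation takes the resulting cumulated decays explicitly.
#'
#' @param added_activity_MBq_per_mL added activity (default 2.5).
#' @param exposure_h exposure time in hours (default 4).
#' @param fraction_internalized probability an in-cell decay is internalized
#'   (default 0.73); membrane fraction is the complement.
#' @param internalization_compartment `"golgi"` or `"cytoplasm"`.
#' @param uptake_per_cell Bq bound per cell per MBq/mL added (synthetic
#'   default 0.04).
#' @param medium_fraction fraction of added activity remaining in the medium
#'   (default 1: uptake is a negligible drain on the medium pool).
#' @return object of class `activity_scenario`.
#' @export
activity_scenario <- function(added_activity_MBq_per_mL = 2.5,
                              exposure_h = 4,
                              fraction_internalized = 0.73,
                              internalization_compartment = c("golgi", "cytoplasm"),
                              uptake_per_cell = 0.04,
                              medium_fraction = 1) {
  internalization_compartment <- match.arg(internalization_compartment)
  if (added_activity_MBq_per_mL < 0) stop("negative activity")
  if (exposure_h <= 0) stop("exposure time must be positive")
  if (fraction_internalized < 0 || fraction_internalized > 1)
    stop("fraction_internalized must be in [0, 1]")
  structure(list(
    added_activity_MBq_per_mL = added_activity_MBq_per_mL,
    exposure_h = exposure_h,
    fraction_internalized = fraction_internalized,
    fraction_membrane = 1 - fraction_internalized,
    internalization_compartment = internalization_compartment,
    uptake_per_cell = uptake_per_cell,
    medium_fraction = medium_fraction
  ), class = "activity_scenario")
}

#' Sample emission sites
#'
#' Cell mode: the emitting cell is uniform over the population (source sampled
#' in all cells simultaneously); within the cell the site is membrane-bound
#' with probability `fraction_membrane`, otherwise uniform in the configured
#' internalization compartment. Medium mode: uniform in the medium cylinder.
#'
#' @param scenario an [activity_scenario()].
#' @param population a [build_planar_population()] result.
#' @param medium a [medium_cylinder()].
#' @param source_mode `"cell"` or `"medium"`.
#' @param n number of sites.
#' @return data.frame with `x`, `y`, `z` (um) and `origin_compartment`.
#' @export
sample_emission_site <- function(scenario, population, medium,
                                 source_mode = c("cell", "medium"), n = 1L) {
  source_mode <- match.arg(source_mode)
  if (source_mode == "medium") {
    pts <- sample_uniform_point(medium, n)
    return(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      origin_compartment = rep("medium", n),
                      stringsAsFactors = FALSE))
  }
  cell_idx <- sample.int(population$n_cells, n, replace = TRUE)
  in_membrane <- runif(n) < scenario$fraction_membrane
  comp <- ifelse(in_membrane, "membrane", scenario$internalization_compartment)
  pts <- matrix(NA_real_, n, 3)
  for (cmp in unique(comp)) {
    sel <- which(comp == cmp)
    # vectorized per compartment, then translate by each cell's placement
    raw <- sample_compartment(population$cells, cmp, length(sel))
    off <- population$placements[cell_idx[sel], , drop = FALSE]
    raw[, 1] <- raw[, 1] + off[, 1]
    raw[, 2] <- raw[, 2] + off[, 2]
    pts[sel, ] <- raw
  }
  data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
             origin_compartment = comp, stringsAsFactors = FALSE)
}

#' Cumulated decays over the exposure interval
#'
#' With instant, permanent uptake each pool decays physically from its initial
#' activity, so cumulated decays are `n = A0 (1 - exp(-lambda t)) / lambda`.
#' The medium pool activity is the added concentration times the medium
#' volume times `medium_fraction`; the per-cell bound pool is
#' `uptake_per_cell x added activity`.
#'
#' @param scenario an [activity_scenario()].
#' @param scheme a [decay_scheme()] (supplies the half-life).
#' @param medium a [medium_cylinder()] defining the medium volume.
#' @param n_cells cells carrying bound activity (default 50, the modeled
#'   population); `n_C` counts decays over all of them, matching how the
#'   cell-source reach probability is normalized (the source is sampled in
#'   all cells simultaneously).
#' @return list with `n_M` (decays in the medium over the interval) and `n_C`
#'   (decays bound to the cells, membrane + internalized).
#' @export
cumulated_decays <- function(scenario, scheme, medium = medium_cylinder(),
                             n_cells = 50L) {
  lambda <- log(2) / (scheme$half_life_h * 3600)     # s^-1
  t <- scenario$exposure_h * 3600
  integ <- (1 - exp(-lambda * t)) / lambda           # s
  vol_mL <- compartment_volume(medium) * 1e-12   # 1 um^3 = 1e-12 cm^3 = 1e-12 mL
  A_medium <- scenario$added_activity_MBq_per_mL * 1e6 * vol_mL * scenario$medium_fraction  # Bq
  A_cells <- scenario$uptake_per_cell * scenario$added_activity_MBq_per_mL * n_cells  # Bq, all cells
  list(n_M = A_medium * integ, n_C = A_cells * integ)
}
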