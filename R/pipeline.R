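# Pipeline: phase-space replay into the nucleus, DSB yield per campaign, the
# decay-weighted combination formula, dose-response fitting, and the
# end-to-end scenario runner with config, manifest and fixtures.

#' Replay phase-space particles through the nucleus
#'
#' Second simulation step: every recorded particle is restarted just inside
#' its entry point with its recorded direction and energy and transported
#' until stopped or gone, scoring in-nucleus energy deposits grouped by the
#' original event identifier (particles sharing a primary stay grouped).
#'
#' @param phase_space phase-space data.frame (or a `ps_campaign`).
#' @param nucleus the scored [nucleus_shape()] (taken from the campaign when
#'   one is given).
#' @param medium world [medium_cylinder()]; defaults to one centered on the
#'   nucleus.
#' @param settings a [transport_settings()].
#' @param table a [water_stopping_power()] table.
#' @param seed integer seed; `NULL` continues the RNG stream.
#' @return list with `deposits` (in-nucleus deposits: `event_id, x, y, z,
#'   amount_keV, step_um`), `n_sp` (records replayed), `dose_Gy`,
#'   `dose_per_sp_Gy`, `nucleus`.
#' @export
replay_phase_space <- function(phase_space, nucleus = NULL, medium = NULL,
                               settings = transport_settings(),
                               table = water_stopping_power(), seed = NULL) {
  if (inherits(phase_space, "ps_campaign")) {
    if (is.null(nucleus)) nucleus <- phase_space$nucleus
    phase_space <- phase_space$phase_space
  }
  if (is.null(nucleus)) stop("nucleus shape required")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(medium))
    medium <- medium_cylinder(center_xy = nucleus$center[1:2])
  n_sp <- nrow(phase_space)
  if (n_sp == 0)
    return(list(deposits = data.frame(event_id = integer(), x = numeric(),
                                      y = numeric(), z = numeric(),
                                      amount_keV = numeric(), step_um = numeric()),
                n_sp = 0L, dose_Gy = 0, dose_per_sp_Gy = NA_real_,
                nucleus = nucleus))
  starts <- as.matrix(phase_space[, c("x_um", "y_um", "z_um")])
  dirs <- as.matrix(phase_space[, c("ux", "uy", "uz")])
  starts <- starts + 1e-4 * dirs  # nudge inside so the entry is not re-scored
  res <- cpp_run_campaign(starts, dirs, phase_space$energy_keV,
                          nucleus_to_cpp(nucleus), world_to_cpp(medium),
                          unclass(table), unclass(settings))
  dep <- as.data.frame(res$nucleus_deposits)
  if (nrow(dep)) {
    names(dep) <- c("event_id", "x", "y", "z", "amount_keV", "step_um")
    # map replay row ids back to the original primary event ids
    dep$event_id <- phase_space$event_id[as.integer(dep$event_id)]
  } else {
    dep <- data.frame(event_id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), amount_keV = numeric(), step_um = numeric())
  }
  dose <- sum(res$event_nucleus_keV) * KEV_TO_J / nucleus_mass_kg(nucleus)
  list(deposits = dep, n_sp = n_sp, dose_Gy = dose,
       dose_per_sp_Gy = dose / n_sp, nucleus = nucleus)
}

#' DSB yield of one campaign (replay + damage + clustering)
#'
#' Runs the damage chain for a phase-space campaign: replay into the nucleus,
#' strand-break induction, DSB clustering, and yield normalization per source
#' particle, per Gbp and per Gy.
#'
#' @param campaign a `ps_campaign`.
#' @param genome a [genome_model()] (defaults to one on the campaign nucleus).
#' @param params a [damage_parameters()].
#' @param settings,table transport settings/stopping table for the replay.
#' @param seed integer seed for replay and damage sampling.
#' @param n_replicates independent replays of the same phase space (particle
#'   splitting). Replaying each recorded particle `k` times with fresh RNG is
#'   unbiased for the per-SP expectation and tightens the DSB statistics
#'   without rerunning the irradiation; clustering never crosses replicates.
#' @return list with `yield` ([damage_yield()]), `clusters` (last replicate),
#'   `breaks` (last replicate), `replay` (last replicate), `n_sp` (records in
#'   the phase space), `n_sp_effective` (records x replicates).
#' @export
campaign_dsb_yield <- function(campaign, genome = NULL,
                               params = damage_parameters(),
                               settings = transport_settings(),
                               table = water_stopping_power(), seed = NULL,
                               n_replicates = 1L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(genome)) genome <- genome_model(campaign$nucleus)
  n_dsb <- 0L; n_simple <- 0L; n_complex <- 0L
  total_nuc_keV <- 0; batch_ids <- integer(0); n_breaks_total <- 0L
  rep <- NULL; breaks <- NULL; clusters <- NULL
  for (r in seq_len(n_replicates)) {
    rep <- replay_phase_space(campaign, settings = settings, table = table)
    breaks <- induce_strand_breaks(rep$deposits, genome, params)
    clusters <- cluster_dsbs(breaks, genome_bp = genome$total_bp)
    summ <- dsb_summary(clusters)
    n_dsb <- n_dsb + nrow(summ)
    n_simple <- n_simple + sum(summ$complexity == "simple")
    n_complex <- n_complex + sum(summ$complexity == "complex")
    if (nrow(summ)) batch_ids <- c(batch_ids, summ$event_id + (r - 1L) * 10000000)
    total_nuc_keV <- total_nuc_keV + sum(rep$deposits$amount_keV)
    n_breaks_total <- n_breaks_total + nrow(breaks)
  }
  n_sp_eff <- max(rep$n_sp, 1L) * n_replicates
  dose_per_sp <- if (rep$n_sp > 0)
    total_nuc_keV * KEV_TO_J / nucleus_mass_kg(rep$nucleus) / n_sp_eff
  else NA_real_
  yield <- damage_yield(n_dsb, n_source_particles = n_sp_eff,
                        gbp = genome$total_gbp,
                        mean_dose_per_sp_gy = dose_per_sp)
  yield$n_simple <- n_simple; yield$n_complex <- n_complex
  yield$rel_sd <- batch_rel_sd(batch_ids, n_dsb, 10L)
  list(yield = yield, clusters = clusters, breaks = breaks,
       replay = rep, n_sp = rep$n_sp, n_sp_effective = n_sp_eff,
       n_breaks = n_breaks_total, dose_per_sp_Gy = dose_per_sp)
}

#' Combination inputs
#'
#' Everything the activity-to-DSB combination formula needs: cumulated decays
#' in medium and cells, reach probabilities and per-SP DSB yields per
#' emission type, and the IC emission weight (0.15 electrons per decay).
#'
#' @param n_M,n_C cumulated decays in the medium and in the cells.
#' @param p_M_beta,p_C_beta,p_M_ic,p_C_ic reach probabilities per type.
#' @param yield_beta,yield_ic DSBs per source particle per type.
#' @param ic_weight IC emissions per decay (default 0.15).
#' @return object of class `combination_inputs`.
#' @export
combination_inputs <- function(n_M, n_C, p_M_beta, p_C_beta,
                               p_M_ic = 0, p_C_ic = 0,
                               yield_beta = 0, yield_ic = 0, ic_weight = 0.15) {
  vals <- c(n_M, n_C, p_M_beta, p_C_beta, p_M_ic, p_C_ic,
            yield_beta, yield_ic, ic_weight)
  if (any(vals < 0)) stop("combination inputs must be non-negative")
  if (any(c(p_M_beta, p_C_beta, p_M_ic, p_C_ic) > 1)) stop("probabilities must be <= 1")
  structure(as.list(environment())[c("n_M", "n_C", "p_M_beta", "p_C_beta",
                                     "p_M_ic", "p_C_ic", "yield_beta",
                                     "yield_ic", "ic_weight")],
            class = "combination_inputs")
}

#' Number of DSBs per cell from cumulated activity
#'
#' The combination formula:
#' `N_DSBs = (n_M p_M->N + n_C p_C->N)_beta x (N_DSBs/SP)_beta
#'  + 0.15 (n_M p_M->N + n_C p_C->N)_IC x (N_DSBs/SP)_IC`,
#' with the reach probabilities and per-SP yields taken from the
#' corresponding beta and IC campaigns.
#'
#' @param inputs a [combination_inputs()].
#' @return expected DSBs per cell (numeric).
#' @export
combine_yields <- function(inputs) {
  with(inputs,
       (n_M * p_M_beta + n_C * p_C_beta) * yield_beta +
         ic_weight * (n_M * p_M_ic + n_C * p_C_ic) * yield_ic)
}

#' Fit the dose-DSB line
#'
#' Ordinary least squares of DSBs per cell on mean absorbed dose to the
#' nucleus (mGy).
#'
#' @param points data.frame with columns `dose_mGy` and `n_dsb` (and an
#'   optional `label`; one fit per label).
#' @return data.frame with `label`, `slope_per_mGy`, `intercept`, `r_squared`,
#'   `slope_se`.
#' @export
fit_dose_response <- function(points) {
  if (nrow(points) < 2) stop("need at least 2 dose-response points")
  if (is.null(points$label)) points$label <- "scenario"
  do.call(rbind, lapply(split(points, points$label), function(df) {
    if (nrow(df) < 2) stop("need at least 2 points per label")
    fit <- lm(n_dsb ~ dose_mGy, data = df)
    sm <- suppressWarnings(summary(fit))  # exact lines trip the perfect-fit warning
    data.frame(label = df$label[1],
               slope_per_mGy = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = sm$r.squared,
               slope_se = sm$coefficients[2, 2],
               stringsAsFactors = FALSE)
  }))
}

#' Default end-to-end configuration
#'
#' Nested list mirroring the config file sections
#' geometry/source/transport/damage/pipeline; every default is overridable.
#'
#' @param seed integer master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    geometry = list(morphology = 1, n_cells = 50, confluence_target = 0.5,
                    medium_diameter_um = 1760, medium_height_um = 1760),
    source = list(activity_MBq_per_mL = 2.5, exposure_h = 4,
                  fraction_internalized = 0.73,
                  internalization_compartment = "golgi",
                  uptake_per_cell = 0.04, medium_fraction = 1),
    transport = list(tracking_cutoff_keV = 0.1,
                     delta_production_threshold_keV = 1.75,
                     max_step_um = 10, straggling_enabled = TRUE,
                     scattering_enabled = TRUE),
    damage = list(sb_per_keV = lutadsb_sb_per_keV, direct_threshold_eV = 17.5,
                  indirect_fraction = 0.6, site_extra_mean = 0.2,
                  strand_corr = 0.5, total_gbp = 6, voxel_um = 0.5),
    pipeline = list(seed = as.integer(seed), n_primaries_cell = 200000,
                    n_primaries_medium = 500000, n_replicates = 25,
                    particles = c("beta", "ic"),
                    dose_scale_factors = c(0.5, 0.75, 1, 1.25, 1.5))
  )
}

#' Read / write a JSON configuration
#' @param path config file path.
#' @param config nested configuration list.
#' @return `read_config` returns the nested list merged over the defaults.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (sec in names(user))
    base[[sec]] <- utils::modifyList(base[[sec]] %||% list(), as.list(user[[sec]]))
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full scenario
#'
#' Orchestrates the whole chain from one configuration: (1) beta and IC
#' phase-space campaigns for cell and medium sources, (2) microdosimetric
#' summaries per campaign, (3) phase-space replay, strand-break induction and
#' DSB yields, (4) the activity combination and the dose-response fit
#' obtained by scaling cumulated decays at fixed geometry. Reports and a
#' reproducibility manifest (seed, config, package version) are written to
#' `out_dir` when given.
#'
#' @param config nested configuration list (see [default_config()]); a path
#'   to a JSON config is also accepted.
#' @param out_dir optional output directory for phase-space files, report
#'   tables and the manifest.
#' @param quiet suppress per-stage progress messages.
#' @return list with `campaigns`, `summaries` (one row per campaign),
#'   `damage` (yield table), `combination` (inputs and DSBs per cell),
#'   `dose_response` (points and fit), `manifest`.
#' @export
run_scenario <- function(config = default_config(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stage <- function(name, expr) {
    if (!quiet) message("[lutadsb] stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  seed <- as.integer(config$pipeline$seed)

  geom <- stage("geometry", {
    morph <- table1_morphology(config$geometry$morphology)
    pop <- build_planar_population(morph, config$geometry$n_cells,
                                   config$geometry$confluence_target,
                                   seed = seed)
    ctr <- pop$placements[pop$central_index, ]
    med <- medium_cylinder(config$geometry$medium_diameter_um,
                           config$geometry$medium_height_um,
                           center_xy = c(ctr[1], ctr[2]))
    list(pop = pop, med = med)
  })
  scheme <- lu177_default_scheme()
  scen <- activity_scenario(config$source$activity_MBq_per_mL,
                            config$source$exposure_h,
                            config$source$fraction_internalized,
                            config$source$internalization_compartment,
                            config$source$uptake_per_cell,
                            config$source$medium_fraction)
  settings <- transport_settings(config$transport$tracking_cutoff_keV,
                                 config$transport$delta_production_threshold_keV,
                                 config$transport$max_step_um,
                                 config$transport$straggling_enabled,
                                 config$transport$scattering_enabled)
  table <- water_stopping_power()
  genome <- genome_model(central_nucleus(geom$pop),
                         total_gbp = config$damage$total_gbp,
                         voxel_um = config$damage$voxel_um)
  params <- damage_parameters(sb_per_keV = config$damage$sb_per_keV,
                              direct_threshold_eV = config$damage$direct_threshold_eV,
                              indirect_fraction = config$damage$indirect_fraction,
                              site_extra_mean = config$damage$site_extra_mean,
                              strand_corr = config$damage$strand_corr)

  particles <- config$pipeline$particles
  sources <- c("cell", "medium")
  campaigns <- list(); damages <- list(); summaries <- list()
  k <- 0L
  for (pt in particles) for (src in sources) {
    k <- k + 1L
    key <- paste(pt, src, sep = "_")
    n_prim <- if (src == "cell") config$pipeline$n_primaries_cell
              else config$pipeline$n_primaries_medium
    cmp <- stage(paste0("phase-space ", key),
                 run_phase_space_campaign(geom$pop, scheme, scen, pt, src,
                                          n_primaries = n_prim,
                                          medium = geom$med, settings = settings,
                                          table = table, seed = seed + 100L * k))
    dmg <- stage(paste0("damage ", key),
                 campaign_dsb_yield(cmp, genome, params, settings, table,
                                    seed = seed + 100L * k + 50L,
                                    n_replicates = config$pipeline$n_replicates %||% 1L))
    campaigns[[key]] <- cmp; damages[[key]] <- dmg
    summaries[[key]] <- cbind(campaign = key, campaign_summary(cmp),
                              stringsAsFactors = FALSE)
  }
  summary_tab <- do.call(rbind, summaries)
  damage_tab <- do.call(rbind, lapply(names(damages), function(key) {
    y <- damages[[key]]$yield
    data.frame(campaign = key, n_SP = y$n_source_particles,
               n_SSB = damages[[key]]$n_breaks,
               n_DSB_simple = y$n_simple, n_DSB_complex = y$n_complex,
               per_sp_per_gbp = y$per_sp_per_gbp, per_sp = y$per_sp,
               per_gy_per_gbp = y$per_gy_per_gbp, rel_SD = y$rel_sd,
               dose_per_sp_Gy = damages[[key]]$dose_per_sp_Gy,
               stringsAsFactors = FALSE)
  }))

  comb <- stage("combination", {
    nd <- cumulated_decays(scen, scheme, geom$med, n_cells = geom$pop$n_cells)
    p <- function(key) if (is.null(campaigns[[key]])) 0 else reach_probability(campaigns[[key]])$p
    y <- function(key) if (is.null(damages[[key]])) 0 else damages[[key]]$yield$per_sp
    inputs <- combination_inputs(
      n_M = nd$n_M, n_C = nd$n_C,
      p_M_beta = p("beta_medium"), p_C_beta = p("beta_cell"),
      p_M_ic = p("ic_medium"), p_C_ic = p("ic_cell"),
      yield_beta = y("beta_cell"), yield_ic = y("ic_cell"),
      ic_weight = scheme$yield_ic)
    list(inputs = inputs, n_dsb_per_cell = combine_yields(inputs),
         cumulated = nd)
  })

  dr <- stage("dose-response", {
    dose_sp <- function(key) {
      d <- damages[[key]]$dose_per_sp_Gy
      if (is.null(d) || !is.finite(d)) 0 else d
    }
    base_dose_mGy <- 1e3 * (
      (comb$cumulated$n_M * comb$inputs$p_M_beta +
       comb$cumulated$n_C * comb$inputs$p_C_beta) * dose_sp("beta_cell") +
      scheme$yield_ic *
      (comb$cumulated$n_M * comb$inputs$p_M_ic +
       comb$cumulated$n_C * comb$inputs$p_C_ic) * dose_sp("ic_cell"))
    sf <- config$pipeline$dose_scale_factors
    pts <- data.frame(dose_mGy = base_dose_mGy * sf,
                      n_dsb = comb$n_dsb_per_cell * sf,
                      label = scen$internalization_compartment)
    list(points = pts, fit = fit_dose_response(pts))
  })

  manifest <- list(seed = seed, config = config,
                   package_version = as.character(utils::packageVersion("lutadsb")),
                   n_campaigns = length(campaigns),
                   confluence = geom$pop$confluence)

  out <- list(population = geom$pop, campaigns = campaigns,
              summaries = summary_tab, damage = damage_tab,
              combination = comb, dose_response = dr, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(campaigns))
      write_phase_space(campaigns[[key]],
                        file.path(out_dir, paste0("phase_space_", key, ".tsv")))
    write.table(summary_tab, file.path(out_dir, "microdose_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(damage_tab, file.path(out_dir, "damage_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(dr$points, file.path(out_dir, "dose_response.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' Generate deterministic synthetic fixtures
#'
#' Small, documented inputs so every module is testable in isolation:
#' `phase_space` (1000 primaries of which 250 reach, so the reach probability
#' is exactly 0.25), `break_list` (the three worked clustering examples),
#' `dose_points` (five points exactly on a 0.017 DSBs per cell per mGy line),
#' `toy_geometry` (a small JSON config).
#'
#' @param kind one of `"phase_space"`, `"break_list"`, `"dose_points"`,
#'   `"toy_geometry"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the path of the file written.
#' @export
generate_fixtures <- function(kind, seed = 1L, dir = tempdir()) {
  set.seed(as.integer(seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- switch(kind,
    phase_space = {
      ids <- sort(sample.int(1000L, 250L))
      n <- length(ids)
      d <- sample_isotropic_direction(n)
      df <- data.frame(event_id = ids,
                       x_um = runif(n, -12, 12), y_um = runif(n, -8.5, 8.5),
                       z_um = runif(n, 1.1, 4.9),
                       ux = d[, 1], uy = d[, 2], uz = d[, 3],
                       energy_keV = runif(n, 5, 400),
                       particle = "beta", origin_compartment = "cytoplasm",
                       stringsAsFactors = FALSE)
      p <- file.path(dir, "fixture_phase_space.tsv")
      write_phase_space(df, p); p
    },
    break_list = {
      df <- data.frame(
        event_id = c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L),
        bp_coordinate = c(100, 105, 200, 210, 300, 304, 308, 400),
        strand = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L),
        mechanism = "direct", stringsAsFactors = FALSE)
      p <- file.path(dir, "fixture_break_list.tsv")
      write_break_list(df, p); p
    },
    dose_points = {
      df <- data.frame(dose_mGy = c(100, 200, 400, 600, 800),
                       n_dsb = 0.017 * c(100, 200, 400, 600, 800),
                       label = "cytoplasm")
      p <- file.path(dir, "fixture_dose_points.tsv")
      write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE); p
    },
    toy_geometry = {
      cfg <- default_config(seed)
      cfg$geometry$n_cells <- 9
      cfg$pipeline$n_primaries_cell <- 200
      cfg$pipeline$n_primaries_medium <- 200
      cfg$pipeline$n_replicates <- 5
      p <- file.path(dir, "fixture_toy_config.json")
      write_config(cfg, p); p
    },
    stop("unknown fixture kind: ", kind))
  invisible(path)
}
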