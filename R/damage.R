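# DNA damage surrogate: genome voxel model, strand-break induction from
# in-nucleus energy deposits, opposite-strand DSB clustering (< 10 bp rule),
# complexity classification and yield normalization.

#' Genome model over the nucleus
#'
#' A voxel grid covering the nucleus; every in-nucleus position maps to
#' exactly one voxel, and the genomic content (default 6 Gbp, G0/G1) is
#' spread over the voxels proportionally to voxel volume (uniform bp
#' density). Genome coordinates are 0-based, half-open `[0, total_bp)`.
#'
#' @param nucleus a [nucleus_shape()].
#' @param total_gbp genomic content in Gbp (default 6).
#' @param voxel_um voxel edge length (default 0.5 um).
#' @return object of class `genome_model`.
#' @export
genome_model <- function(nucleus, total_gbp = 6, voxel_um = 0.5) {
  h <- nucleus$half_axes; ctr <- nucleus$center
  lo <- ctr - h; hi <- ctr + h
  nx <- ceiling((hi - lo) / voxel_um)
  # voxel centers; keep voxels whose center lies in the nucleus, plus all
  # boundary voxels so that every in-nucleus position maps somewhere
  idx <- expand.grid(i = seq_len(nx[1]), j = seq_len(nx[2]), k = seq_len(nx[3]))
  centers <- cbind(lo[1] + (idx$i - 0.5) * voxel_um,
                   lo[2] + (idx$j - 0.5) * voxel_um,
                   lo[3] + (idx$k - 0.5) * voxel_um)
  keep <- rep(TRUE, nrow(idx))   # full bounding-box grid: simple, exhaustive
  key <- (idx$i - 1L) + nx[1] * ((idx$j - 1L) + nx[2] * (idx$k - 1L))
  total_bp <- total_gbp * 1e9
  # bp proportional to the voxel volume actually inside the nucleus,
  # estimated by a fixed 4^3 sub-grid containment fraction
  frac <- voxel_inside_fraction(nucleus, centers, voxel_um)
  w <- frac / sum(frac)
  bp <- floor(w * total_bp)
  rem <- total_bp - sum(bp)
  # distribute the integer remainder over the largest voxels
  if (rem > 0) {
    o <- order(w, decreasing = TRUE)
    add <- rep(0, length(w)); take <- as.integer(rem %% length(w))
    full <- rem %/% length(w)
    add <- add + full
    if (take > 0) add[o[seq_len(take)]] <- add[o[seq_len(take)]] + 1
    bp <- bp + add
  }
  starts <- cumsum(c(0, bp[-length(bp)]))
  structure(list(nucleus = nucleus, total_bp = total_bp, total_gbp = total_gbp,
                 voxel_um = voxel_um, lo = lo, n = nx,
                 key = key, bp = bp, starts = starts),
            class = "genome_model")
}

voxel_inside_fraction <- function(nucleus, centers, voxel_um) {
  offs <- (c(-1.5, -0.5, 0.5, 1.5) / 4) * voxel_um
  sub <- as.matrix(expand.grid(offs, offs, offs))
  frac <- numeric(nrow(centers))
  for (s in seq_len(nrow(sub))) {
    pts <- sweep(centers, 2, sub[s, ], "+")
    frac <- frac + region_contains(nucleus, pts)
  }
  frac <- frac / nrow(sub)
  # never zero for voxels that might still receive deposits at the rim
  pmax(frac, 1e-6)
}

#' Genomic coordinate of a spatial position
#'
#' Maps a position to its voxel and adds a local offset along the voxel's
#' local DNA axis (x) at the packing rate, so two deposits separated by `r`
#' nm along that axis differ by `floor(r * bp_per_nm)` bp (locally linear
#' DNA at 0.34 nm/bp).
#'
#' @param genome a [genome_model()].
#' @param position length-3 point or `n x 3` matrix (um).
#' @param bp_per_nm genomic packing (default 1/0.34 bp per nm).
#' @return numeric bp coordinates in `[0, total_bp)`.
#' @export
bp_coordinate <- function(genome, position, bp_per_nm = 1 / 0.34) {
  x <- as_point_matrix(position)
  ijk <- floor(sweep(x, 2, genome$lo) / genome$voxel_um)
  ijk <- pmin(pmax(ijk, 0), matrix(genome$n - 1L, nrow(x), 3, byrow = TRUE))
  # full-grid layout: linear key + 1 is the row index in the voxel table
  vox <- ijk[, 1] + genome$n[1] * (ijk[, 2] + genome$n[2] * ijk[, 3]) + 1L
  corner <- sweep(ijk * genome$voxel_um, 2, genome$lo, "+")
  r_nm <- (x[, 1] - corner[, 1]) * 1e3
  off <- floor(r_nm * bp_per_nm)
  pmin(genome$starts[vox] + pmin(off, pmax(genome$bp[vox] - 1, 0)),
       genome$total_bp - 1)
}

#' Damage model parameters
#'
#' The surrogate collapses the physical/physicochemical/chemical damage
#' chain into a small parameter set: `sb_per_keV` strand-break candidates per
#' keV imparted (the in-repo calibrated constant), an indirect fraction
#' standing in for the 2.5 ns radical chemistry, a 17.5 eV gate for direct
#' backbone breaks, and the genomic packing rate. Breaks arrive in damage
#' sites of mean multiplicity `1 + site_extra_mean` spread over the genomic
#' span of the parent deposit's step.
#'
#' @param sb_per_keV strand-break candidates per keV (calibrated default, see
#'   the calibration script shipped under `scripts/`).
#' @param direct_threshold_eV minimum deposit energy able to produce a direct
#'   break (default 17.5 eV).
#' @param indirect_fraction probability a break is chemistry-mediated
#'   (default 0.6).
#' @param bp_per_nm genomic packing (default 1/0.34).
#' @param site_extra_mean Poisson mean of extra breaks per damage site
#'   (default 0.2; sets DSB complexity — the default puts the simple-DSB
#'   fraction in the 80-92% range seen for low-LET radiation).
#' @param site_jitter_bp half-width of within-site break scatter (default 3).
#' @param strand_corr probability consecutive within-site breaks switch
#'   strand (0.5 = independent strands).
#' @return object of class `damage_parameters`.
#' @export
damage_parameters <- function(sb_per_keV = lutadsb_sb_per_keV,
                              direct_threshold_eV = 17.5,
                              indirect_fraction = 0.6,
                              bp_per_nm = 1 / 0.34,
                              site_extra_mean = 0.2,
                              site_jitter_bp = 3L,
                              strand_corr = 0.5) {
  if (sb_per_keV <= 0 || direct_threshold_eV <= 0) stop("damage parameters must be positive")
  if (indirect_fraction < 0 || indirect_fraction > 1) stop("indirect_fraction in [0,1]")
  structure(as.list(environment()), class = "damage_parameters")
}

# one-time in-repo calibration (scripts/calibrate_sb_per_kev.R) so the
# end-to-end yield sits at the centre of the reference 2.3-3.0 DSB/(Gy Gbp)
# band; do not tune by hand.
lutadsb_sb_per_keV <- 0.0402

#' Induce strand breaks from in-nucleus energy deposits
#'
#' Each deposit spawns damage sites (Poisson with expectation
#' `sb_per_keV x amount / (1 + site_extra_mean)`) spread uniformly over the
#' genomic span of the deposit's condensed-history step; each site carries
#' `1 + Poisson(site_extra_mean)` breaks jittered within `site_jitter_bp`.
#' Expected breaks per deposit are exactly `sb_per_keV x amount`. Direct
#' breaks require the parent deposit to exceed the direct threshold;
#' deposits outside the nucleus are skipped (count reported as an attribute).
#'
#' @param deposits data.frame with `event_id`, `x`, `y`, `z`, `amount_keV`,
#'   `step_um` (in-nucleus deposits of a campaign or replay).
#' @param genome a [genome_model()].
#' @param params a [damage_parameters()].
#' @return data.frame of breaks: `event_id`, `bp_coordinate`, `strand` (0/1),
#'   `mechanism` ("direct"/"indirect"); attribute `n_skipped` counts deposits
#'   outside the nucleus.
#' @export
induce_strand_breaks <- function(deposits, genome, params = damage_parameters()) {
  if (nrow(deposits) == 0) return(empty_breaks())
  inside <- region_contains(genome$nucleus, as.matrix(deposits[, c("x", "y", "z")]))
  skipped <- sum(!inside)
  dep <- deposits[inside, , drop = FALSE]
  if (nrow(dep) == 0) {
    out <- empty_breaks(); attr(out, "n_skipped") <- skipped; return(out)
  }
  mult <- 1 + params$site_extra_mean
  n_sites <- rpois(nrow(dep), params$sb_per_keV * dep$amount_keV / mult)
  tot_sites <- sum(n_sites)
  if (tot_sites == 0) {
    out <- empty_breaks(); attr(out, "n_skipped") <- skipped; return(out)
  }
  di <- rep.int(seq_len(nrow(dep)), n_sites)     # deposit index per site
  anchor <- bp_coordinate(genome, as.matrix(dep[di, c("x", "y", "z")]), params$bp_per_nm)
  span <- pmax(1, dep$step_um[di] * 1e3 * params$bp_per_nm)
  center <- round(anchor + runif(tot_sites, -0.5, 0.5) * span)
  k <- 1L + rpois(tot_sites, params$site_extra_mean)  # breaks per site
  si <- rep.int(seq_len(tot_sites), k)
  n_br <- length(si)
  jitter <- sample.int(2L * params$site_jitter_bp + 1L, n_br, replace = TRUE) -
    params$site_jitter_bp - 1L
  bp <- pmin(pmax(center[si] + jitter, 0), genome$total_bp - 1)
  # strand: first break of a site random, then switch with prob strand_corr
  first <- c(TRUE, si[-1] != si[-n_br])
  flips <- ifelse(first, rbinom(n_br, 1L, 0.5),
                  rbinom(n_br, 1L, params$strand_corr))
  strand <- integer(n_br)
  run_start <- which(first)
  # cumulative xor within each site run
  grp_cum <- ave(flips, si, FUN = cumsum)
  strand <- grp_cum %% 2L
  mech <- ifelse(runif(n_br) < params$indirect_fraction, "indirect", "direct")
  # direct breaks need the parent deposit above the threshold
  big_enough <- dep$amount_keV[di[si]] * 1e3 >= params$direct_threshold_eV
  keep <- mech == "indirect" | big_enough
  out <- data.frame(event_id = dep$event_id[di[si]][keep],
                    bp_coordinate = bp[keep],
                    strand = strand[keep],
                    mechanism = mech[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}

empty_breaks <- function() {
  structure(data.frame(event_id = integer(), bp_coordinate = numeric(),
                       strand = integer(), mechanism = character(),
                       stringsAsFactors = FALSE),
            n_skipped = 0L)
}

#' Cluster strand breaks into DSBs
#'
#' A DSB is at least 2 strand breaks on opposite strands separated by less
#' than `max_sep_bp` base pairs (strict inequality); clusters are the maximal
#' sets under the transitive closure of that pairing, so chained
#' opposite-strand pairs merge. Breaks never joined to an opposite-strand
#' partner remain single-strand breaks and are not returned.
#'
#' @param breaks data.frame with `bp_coordinate` and `strand` (0/1) columns.
#' @param max_sep_bp clustering distance (default 10; pairs join when
#'   separation `< max_sep_bp`).
#' @param genome_bp optional genome length for coordinate validation.
#' @return object of class `dsb_clusters`: a list of member data.frames, each
#'   sorted by coordinate.
#' @export
cluster_dsbs <- function(breaks, max_sep_bp = 10, genome_bp = NULL) {
  if (!is.null(genome_bp) &&
      any(breaks$bp_coordinate < 0 | breaks$bp_coordinate >= genome_bp))
    stop("break coordinates outside genome range")
  n <- nrow(breaks)
  if (n == 0) return(structure(list(), class = "dsb_clusters"))
  ord <- order(breaks$bp_coordinate)
  bp <- breaks$bp_coordinate[ord]; strand <- breaks$strand[ord]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  paired <- logical(n)
  j_start <- 1L
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && bp[j] - bp[i] < max_sep_bp) {
      if (strand[j] != strand[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
        paired[i] <- TRUE; paired[j] <- TRUE
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- which(paired)
  if (!length(keep)) return(structure(list(), class = "dsb_clusters"))
  groups <- split(keep, roots[keep])
  clusters <- lapply(groups, function(ix) {
    members <- breaks[ord[ix], , drop = FALSE]
    members[order(members$bp_coordinate), , drop = FALSE]
  })
  names(clusters) <- NULL
  structure(clusters, class = "dsb_clusters")
}

#' Classify DSB complexity
#'
#' Simple: exactly 2 constituent strand breaks. Complex: 3 or more, with at
#' least one on the strand opposite the others (guaranteed by the clustering
#' rule).
#'
#' @param cluster one member data.frame from [cluster_dsbs()].
#' @return `"simple"` or `"complex"`.
#' @export
classify_complexity <- function(cluster) {
  if (nrow(cluster) < 2) stop("a DSB cluster has at least 2 breaks")
  if (length(unique(cluster$strand)) < 2) stop("a DSB cluster spans both strands")
  if (nrow(cluster) == 2) "simple" else "complex"
}

#' One-row-per-DSB summary
#' @param clusters a `dsb_clusters` object.
#' @return data.frame with `n_breaks`, `bp_min`, `bp_max`, `span_bp`,
#'   `complexity`, `event_id` (of the first member).
#' @export
dsb_summary <- function(clusters) {
  if (!length(clusters))
    return(data.frame(n_breaks = integer(), bp_min = numeric(), bp_max = numeric(),
                      span_bp = numeric(), complexity = character(),
                      event_id = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(clusters, function(cl) data.frame(
    n_breaks = nrow(cl), bp_min = min(cl$bp_coordinate),
    bp_max = max(cl$bp_coordinate),
    span_bp = max(cl$bp_coordinate) - min(cl$bp_coordinate),
    complexity = classify_complexity(cl),
    event_id = cl$event_id[1], stringsAsFactors = FALSE)))
}

#' Normalized DSB yields
#'
#' @param clusters a `dsb_clusters` object (or an integer DSB count).
#' @param n_source_particles number of source particles (phase-space records)
#'   the damage derives from.
#' @param gbp genomic content in Gbp (default 6).
#' @param mean_dose_per_sp_gy mean absorbed dose to the nucleus per source
#'   particle, Gy; enables the per-Gy yield.
#' @param n_batches batches for the relative-SD estimate of the per-SP mean
#'   (by event identifier; default 10).
#' @return object of class `damage_yield`: `n_dsb`, `n_simple`, `n_complex`,
#'   `per_sp_per_gbp`, `per_sp`, `per_gy_per_gbp`, `rel_sd`.
#' @export
damage_yield <- function(clusters, n_source_particles, gbp = 6,
                         mean_dose_per_sp_gy = NULL, n_batches = 10L) {
  if (n_source_particles <= 0) stop("n_source_particles must be > 0")
  if (inherits(clusters, "dsb_clusters")) {
    summ <- dsb_summary(clusters)
    n_dsb <- nrow(summ)
    n_simple <- sum(summ$complexity == "simple")
    n_complex <- sum(summ$complexity == "complex")
    rel_sd <- batch_rel_sd(summ$event_id, n_dsb, n_batches)
  } else {
    n_dsb <- as.numeric(clusters); n_simple <- NA_integer_; n_complex <- NA_integer_
    rel_sd <- NA_real_
  }
  per_sp_per_gbp <- n_dsb / (n_source_particles * gbp)
  per_gy <- if (is.null(mean_dose_per_sp_gy) || !is.finite(mean_dose_per_sp_gy) ||
                mean_dose_per_sp_gy <= 0) {
    if (n_dsb > 0) NA_real_ else 0
  } else per_sp_per_gbp / mean_dose_per_sp_gy
  structure(list(n_dsb = n_dsb, n_simple = n_simple, n_complex = n_complex,
                 per_sp_per_gbp = per_sp_per_gbp,
                 per_sp = per_sp_per_gbp * gbp,
                 per_gy_per_gbp = per_gy,
                 rel_sd = rel_sd,
                 n_source_particles = n_source_particles, gbp = gbp),
            class = "damage_yield")
}

batch_rel_sd <- function(event_ids, n_dsb, n_batches) {
  if (n_dsb == 0 || !length(event_ids)) return(NA_real_)
  # partition by raw id so batches are a pseudo-random split of the events
  b <- floor(as.numeric(event_ids)) %% n_batches
  counts <- tabulate(b + 1L, nbins = n_batches)
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::sd(counts) / sqrt(n_batches) / m
}

#' Break list import/export (SDD-inspired delimited format)
#'
#' Columns `event_id, bp_coordinate, strand, mechanism`, so break lists from
#' external track-structure codes can be clustered by this module alone.
#'
#' @param breaks breaks data.frame.
#' @param path file path.
#' @export
write_break_list <- function(breaks, path) {
  write.table(breaks[, c("event_id", "bp_coordinate", "strand", "mechanism")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_break_list
#' @export
read_break_list <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
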