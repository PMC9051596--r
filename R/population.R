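# Planar population of identical cells on the dish plane.

#' Build a planar population of identical cells
#'
#' Places `n_cells` replicas of one morphology on a rectangular grid with
#' pitch solved analytically so that the projected footprint coverage of the
#' substrate rectangle equals `confluence_target`, then jitters each cell
#' inside its own grid tile so placements are irregular but provably
#' non-overlapping. The cell closest to the substrate centroid is the central
#' (scored) cell.
#'
#' @param morphology a [cell_morphology()].
#' @param n_cells number of cells (default 50).
#' @param confluence_target fraction of substrate covered, in (0, 1).
#' @param seed integer seed for the jitter; `NULL` leaves the RNG stream alone.
#' @param jitter fraction (0..1) of the free margin used for jitter.
#' @return object of class `planar_population` with fields `cells` (the shared
#'   morphology), `placements` (n x 2 xy translations), `central_index`,
#'   `substrate_dim`, `confluence`.
#' @export
build_planar_population <- function(morphology, n_cells = 50L,
                                    confluence_target = 0.5,
                                    seed = NULL, jitter = 0.9) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (confluence_target <= 0 || confluence_target >= 1)
    stop("confluence_target must be in (0, 1)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  fx <- morphology$footprint[1]; fy <- morphology$footprint[2]
  cols <- ceiling(sqrt(n_cells * fy / fx))   # roughly square substrate
  rows <- ceiling(n_cells / cols)
  # coverage = n * fx * fy / (rows * cols * px * py); isotropic pitch factor k
  k <- sqrt(n_cells / (confluence_target * rows * cols))
  if (k <= 1) stop(sprintf(
    "cannot achieve confluence %.2f without overlap (needs pitch factor %.3f <= 1)",
    confluence_target, k))
  px <- fx * k; py <- fy * k
  free_x <- (px - fx) / 2; free_y <- (py - fy) / 2

  idx <- seq_len(n_cells) - 1L
  cx <- (idx %% cols) * px + px / 2
  cy <- (idx %/% cols) * py + py / 2
  cx <- cx + runif(n_cells, -free_x * jitter, free_x * jitter)
  cy <- cy + runif(n_cells, -free_y * jitter, free_y * jitter)

  sub_dim <- c(cols * px, rows * py)
  achieved <- n_cells * fx * fy / prod(sub_dim)
  if (abs(achieved - confluence_target) > 0.05)
    stop(sprintf("achieved confluence %.3f outside +/-0.05 of target %.3f",
                 achieved, confluence_target))

  centroid <- sub_dim / 2
  central <- which.min((cx - centroid[1])^2 + (cy - centroid[2])^2)
  # recentre so the central cell is at the origin
  placements <- cbind(x = cx - cx[central], y = cy - cy[central])

  structure(list(
    cells = morphology,
    n_cells = as.integer(n_cells),
    placements = placements,
    central_index = central,
    substrate_dim = sub_dim,
    pitch = c(px, py),
    confluence = achieved
  ), class = "planar_population")
}

#' Achieved confluence of a population
#' @param population a `planar_population`.
#' @return covered fraction of the substrate rectangle.
#' @export
population_confluence <- function(population) population$confluence

#' Pairwise footprint overlap area of the population (should be exactly zero)
#' @param population a `planar_population`.
#' @return total pairwise overlap of cell bounding-box footprints, um^2.
#' @export
population_overlap_area <- function(population) {
  p <- population$placements
  fx <- population$cells$footprint[1]; fy <- population$cells$footprint[2]
  n <- nrow(p); total <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1L)) {
    ox <- pmax(0, fx - abs(p[i, 1] - p[(i + 1):n, 1]))
    oy <- pmax(0, fy - abs(p[i, 2] - p[(i + 1):n, 2]))
    total <- total + sum(ox * oy)
  }
  total
}

#' Nucleus of the central cell in world coordinates
#' @param population a `planar_population`.
#' @return a [nucleus_shape()] translated to the central placement.
#' @export
central_nucleus <- function(population) {
  nuc <- population$cells$nucleus
  off <- population$placements[population$central_index, ]
  nuc$center <- unname(nuc$center + c(off[1], off[2], 0))
  nuc
}
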