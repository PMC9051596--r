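# Whole-cell morphology surrogates matched to the measured compartment
# volumes and bounding boxes of the three U2OS-SSTR2 cells.

#' Parametric cell morphology
#'
#' Builds a nested-compartment cell: the cytoplasm solid as an elliptic
#' cylinder of the measured bounding-box height whose footprint keeps the
#' bounding-box aspect and is scaled so the solid volume equals
#' cytoplasm + nucleus + Golgi (the cytoplasm compartment volume — solid
#' minus the nested organelles — then matches the measured value exactly); a
#' 7.5 nm membrane shell over the cytoplasm surface; an ellipsoidal Golgi
#' (aspect 2:1:0.6) volume-matched and placed adjacent to the nucleus along
#' +x; and the nucleus itself as an ellipsoid or elliptic cylinder in
#' half-dimensions. The cell sits on the dish plane z = 0; all compartments
#' are centered at mid-height. The measured x/y bounding box is kept as the
#' placement footprint; the solid itself is leaner than the box (real
#' cytoplasmic lobes are not represented).
#'
#' The constructor verifies the nesting invariants numerically (nucleus and
#' Golgi strictly inside the cytoplasm, Golgi disjoint from the nucleus) and
#' errors on violation.
#'
#' @param cell_id identifier.
#' @param nucleus_kind `"ellipsoid"` or `"elliptic_cylinder"`.
#' @param nucleus_half_axes half-dimensions (a, b, c) in um.
#' @param cy_volume measured cytoplasm volume, um^3.
#' @param cy_bbox full bounding-box dimensions (x, y, z) of the cytoplasm, um.
#' @param golgi_volume measured Golgi volume, um^3.
#' @param membrane_thickness membrane shell thickness, um (default 0.0075).
#' @param golgi_gap clearance between nucleus and Golgi surfaces along +x, um.
#' @param golgi_aspect relative semi-axes of the Golgi ellipsoid.
#' @return object of class `cell_morphology`.
#' @examples
#' cell <- table1_morphology(1)
#' compartment_volume(cell$nucleus)
#' @export
cell_morphology <- function(cell_id,
                            nucleus_kind, nucleus_half_axes,
                            cy_volume, cy_bbox, golgi_volume,
                            membrane_thickness = 0.0075,
                            golgi_gap = 0.2,
                            golgi_aspect = c(2, 1, 0.6)) {
  if (cy_volume <= 0 || golgi_volume <= 0) stop("invalid geometry: volumes must be positive")
  half_box <- as.numeric(cy_bbox) / 2
  zc <- half_box[3]  # mid-height center so the cell spans z in [0, cy_bbox_z]

  nucleus <- nucleus_shape(nucleus_kind, nucleus_half_axes, center = c(0, 0, zc))

  # footprint semi-axes with the box aspect, scaled to the total solid volume
  solid_volume <- cy_volume + golgi_volume + compartment_volume(nucleus)
  ab <- solid_volume / (pi * cy_bbox[3])
  aspect <- half_box[1] / half_box[2]
  b_cy <- sqrt(ab / aspect); a_cy <- aspect * b_cy
  if (a_cy > half_box[1] * (1 + 1e-9))
    stop("invalid geometry: cytoplasm volume exceeds its bounding box")
  cytoplasm <- region_elliptic_cylinder(c(a_cy, b_cy, half_box[3]), center = c(0, 0, zc))

  s <- (golgi_volume * 3 / (4 * pi * prod(golgi_aspect)))^(1 / 3)
  g_axes <- golgi_aspect * s
  # adjacent along +x, where the elongated cytoplasm leaves room in all
  # three measured morphologies
  g_center <- c(nucleus_half_axes[1] + golgi_gap + g_axes[1], 0, zc)
  golgi <- region_ellipsoid(g_axes, g_center)

  membrane <- region_shell(cytoplasm, membrane_thickness)

  check_nested(nucleus, cytoplasm, "nucleus", "cytoplasm")
  check_nested(golgi, cytoplasm, "golgi", "cytoplasm")
  if (any(region_contains(nucleus, boundary_probe(golgi))))
    stop("invalid geometry: golgi overlaps nucleus")

  structure(list(
    cell_id = cell_id,
    nucleus = nucleus, cytoplasm = cytoplasm, golgi = golgi, membrane = membrane,
    volumes = c(cytoplasm = compartment_volume(cytoplasm) -
                  compartment_volume(golgi) - compartment_volume(nucleus),
                golgi = compartment_volume(golgi),
                nucleus = compartment_volume(nucleus)),
    bbox = as.numeric(cy_bbox),
    footprint = as.numeric(cy_bbox[1:2])
  ), class = "cell_morphology")
}

# deterministic probe points on a region boundary for nesting checks
boundary_probe <- function(region, n = 400L) {
  set.seed(20260918L)  # fixed internal probe pattern; not a simulation stream
  g <- matrix(rnorm(3L * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  if (inherits(region, "nucleus_shape")) {
    h <- region$half_axes
    if (region$kind == "ellipsoid") {
      p <- sweep(g, 2, h, "*")
    } else {
      th <- runif(n, 0, 2 * pi); z <- runif(n, -1, 1)
      p <- cbind(h[1] * cos(th), h[2] * sin(th), h[3] * z)
      # include cap rims and faces
      p <- rbind(p, cbind(h[1] * cos(th) * sqrt(runif(n)),
                          h[2] * sin(th) * sqrt(runif(n)),
                          h[3] * sign(z)))
    }
    return(sweep(p, 2, region$center, "+"))
  }
  if (inherits(region, "region_ellipsoid"))
    return(sweep(sweep(g, 2, region$half_axes, "*"), 2, region$center, "+"))
  stop("unsupported region for boundary_probe")
}

check_nested <- function(inner, outer, iname, oname) {
  pts <- boundary_probe(inner)
  if (!all(region_contains(outer, pts)))
    stop(sprintf("invalid geometry: %s not contained in %s", iname, oname))
  invisible(TRUE)
}

#' The three measured cell morphologies
#'
#' Convenience constructors carrying the measured compartment volumes,
#' cytoplasm bounding boxes and nucleus half-dimensions of the three imaged
#' cells: cell 1 has an ellipsoidal nucleus (a=12, b=8.5, c=1.9 um), cells 2
#' and 3 elliptic-cylinder nuclei (13, 7, 1.25) and (8, 11, 2).
#'
#' @param which 1, 2 or 3.
#' @param ... overrides passed on to [cell_morphology()].
#' @return object of class `cell_morphology`.
#' @export
table1_morphology <- function(which = 1, ...) {
  spec <- switch(as.character(which),
    "1" = list(nucleus_kind = "ellipsoid", nucleus_half_axes = c(12, 8.5, 1.9),
               cy_volume = 3465.64, cy_bbox = c(72.24, 31.78, 5.99), golgi_volume = 68.46),
    "2" = list(nucleus_kind = "elliptic_cylinder", nucleus_half_axes = c(13, 7, 1.25),
               cy_volume = 1876.58, cy_bbox = c(99.21, 30.86, 3.52), golgi_volume = 24.34),
    "3" = list(nucleus_kind = "elliptic_cylinder", nucleus_half_axes = c(8, 11, 2),
               cy_volume = 4228.08, cy_bbox = c(88.70, 64.28, 6.29), golgi_volume = 63.18),
    stop("which must be 1, 2 or 3"))
  args <- utils::modifyList(c(list(cell_id = paste0("cell", which)), spec), list(...))
  do.call(cell_morphology, args)
}

#' Sample a uniform point inside one named compartment of a cell
#'
#' The cytoplasm compartment excludes the nucleus and Golgi interiors
#' (rejection), so nested compartments never double-count activity.
#'
#' @param cell a [cell_morphology()].
#' @param compartment `"cytoplasm"`, `"golgi"`, `"membrane"` or `"nucleus"`.
#' @param n number of points.
#' @param offset optional xy translation of the cell placement.
#' @return `n x 3` matrix in um.
#' @export
sample_compartment <- function(cell, compartment, n = 1L, offset = c(0, 0)) {
  pts <- switch(compartment,
    nucleus = sample_uniform_point(cell$nucleus, n),
    golgi = sample_uniform_point(cell$golgi, n),
    membrane = sample_uniform_point(cell$membrane, n),
    cytoplasm = {
      out <- matrix(NA_real_, 0, 3)
      while (nrow(out) < n) {
        cand <- sample_uniform_point(cell$cytoplasm, max(n - nrow(out), 16L))
        keep <- !(region_contains(cell$nucleus, cand) | region_contains(cell$golgi, cand))
        out <- rbind(out, cand[keep, , drop = FALSE])
      }
      out[seq_len(n), , drop = FALSE]
    },
    stop("unknown compartment: ", compartment))
  pts[, 1] <- pts[, 1] + offset[1]
  pts[, 2] <- pts[, 2] + offset[2]
  pts
}
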