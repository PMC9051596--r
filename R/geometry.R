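# Cell-compartment geometry: parametric regions, containment, uniform
# sampling, and ray intersections with the scored nucleus.
#
# Conventions: all lengths in micrometres; the culture dish plane is z = 0 and
# cells occupy z >= 0; points exactly on a surface count as inside the inner
# compartment. All media are water at 1 g/cm^3.

#' Nucleus shape
#'
#' The scored nucleus is either an ellipsoid or an elliptic cylinder, given in
#' half-dimensions `(a, b, c)`: for the ellipsoid these are the three
#' semi-axes; for the elliptic cylinder `a`, `b` are the footprint semi-axes
#' and `c` the half-height (height `2c`).
#'
#' @param kind `"ellipsoid"` or `"elliptic_cylinder"`.
#' @param half_axes numeric length-3, half-dimensions in um, all positive.
#' @param center numeric length-3 center in um.
#' @return An object of class `nucleus_shape`.
#' @examples
#' compartment_volume(nucleus_shape("ellipsoid", c(12, 8.5, 1.9)))
#' @export
nucleus_shape <- function(kind = c("ellipsoid", "elliptic_cylinder"),
                          half_axes, center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  half_axes <- as.numeric(half_axes)
  if (length(half_axes) != 3 || any(!is.finite(half_axes)) || any(half_axes <= 0))
    stop("invalid geometry: nucleus half_axes must be 3 positive numbers")
  if (length(center) != 3 || any(!is.finite(center)))
    stop("invalid geometry: center must be a finite 3-vector")
  structure(list(kind = kind, half_axes = half_axes, center = as.numeric(center)),
            class = c("nucleus_shape", "region"))
}

#' Axis-aligned ellipsoidal region (used for the Golgi surrogate)
#' @param half_axes semi-axes in um.
#' @param center center in um.
#' @return object of class `region_ellipsoid`.
#' @export
region_ellipsoid <- function(half_axes, center = c(0, 0, 0)) {
  if (any(half_axes <= 0)) stop("invalid geometry: degenerate half axes")
  structure(list(half_axes = as.numeric(half_axes), center = as.numeric(center)),
            class = c("region_ellipsoid", "region"))
}

#' p-norm ball ("superellipsoid") region, the cytoplasm surrogate
#'
#' Solid `sum(|x_i - c_i| / A_i)^p <= 1`. For `p = 2` this is an ellipsoid;
#' smaller exponents give leaner, lobed solids filling a smaller fraction of
#' their bounding box, which is how a spread-out adherent cytoplasm is
#' emulated while matching both the measured bounding box and volume.
#'
#' @param half_axes bounding-box half-dimensions `(A, B, C)` in um.
#' @param p exponent, > 0.
#' @param center center in um.
#' @return object of class `region_pball`.
#' @export
region_pball <- function(half_axes, p, center = c(0, 0, 0)) {
  if (any(half_axes <= 0) || p <= 0) stop("invalid geometry: degenerate p-ball")
  structure(list(half_axes = as.numeric(half_axes), p = p, center = as.numeric(center)),
            class = c("region_pball", "region"))
}

#' Axis-aligned elliptic-cylinder region (the cytoplasm solid surrogate)
#'
#' Solid `((x-cx)/a)^2 + ((y-cy)/b)^2 <= 1`, `|z - cz| <= c`.
#'
#' @param half_axes `(a, b, c)`: footprint semi-axes and half-height, um.
#' @param center center in um.
#' @return object of class `region_elliptic_cylinder`.
#' @export
region_elliptic_cylinder <- function(half_axes, center = c(0, 0, 0)) {
  if (any(half_axes <= 0)) stop("invalid geometry: degenerate half axes")
  structure(list(half_axes = as.numeric(half_axes), center = as.numeric(center)),
            class = c("region_elliptic_cylinder", "region"))
}

#' Thin shell over a star-shaped region surface (cell membrane surrogate)
#'
#' Radial band: points whose ray from the region center crosses the base
#' surface at distance r and whose own distance lies in `(r, r + thickness]`
#' along that ray (to first order a shell of constant thickness, which is
#' 7.5 nm here against ~30 um cell dimensions).
#'
#' @param base a star-shaped region with a [region_radius()] method (the
#'   cytoplasm solid).
#' @param thickness shell thickness in um (default 0.0075).
#' @return object of class `region_shell`.
#' @export
region_shell <- function(base, thickness = 0.0075) {
  stopifnot(inherits(base, "region"), thickness > 0)
  structure(list(base = base, thickness = thickness), class = c("region_shell", "region"))
}

#' Surface radius of a star-shaped region along directions
#' @param region a region object centered at `region$center`.
#' @param directions `n x 3` matrix of unit vectors.
#' @return distances from the center to the surface.
#' @export
region_radius <- function(region, directions) UseMethod("region_radius")

#' @export
region_radius.region_pball <- function(region, directions)
  pball_radius(region, as_point_matrix(directions))

#' @export
region_radius.region_ellipsoid <- function(region, directions) {
  d <- as_point_matrix(directions)
  1 / sqrt(rowSums(sweep(d, 2, region$half_axes, "/")^2))
}

#' @export
region_radius.region_elliptic_cylinder <- function(region, directions) {
  d <- as_point_matrix(directions)
  h <- region$half_axes
  re <- 1 / sqrt(pmax((d[, 1] / h[1])^2 + (d[, 2] / h[2])^2, 1e-300))
  rz <- ifelse(abs(d[, 3]) < 1e-300, Inf, h[3] / abs(d[, 3]))
  pmin(re, rz)
}

#' @export
region_radius.nucleus_shape <- function(region, directions) {
  if (region$kind == "ellipsoid")
    region_radius.region_ellipsoid(region, directions)
  else
    region_radius.region_elliptic_cylinder(region, directions)
}

#' Upright circular cylinder sitting on the dish plane (culture medium)
#' @param diameter,height in um (defaults 1760, the maximum beta range).
#' @param center_xy xy-position of the axis.
#' @return object of class `region_cylinder`.
#' @export
medium_cylinder <- function(diameter = 1760, height = 1760, center_xy = c(0, 0)) {
  if (diameter <= 0 || height <= 0) stop("invalid geometry: degenerate cylinder")
  structure(list(radius = diameter / 2, height = height, center_xy = as.numeric(center_xy)),
            class = c("region_cylinder", "region"))
}

# volume of the unit p-ball scaled by half axes: 8*A*B*C*Gamma(1+1/p)^3/Gamma(1+3/p)
pball_volume_factor <- function(p) gamma(1 + 1 / p)^3 / gamma(1 + 3 / p)

#' Analytic compartment volume
#'
#' Closed-form volumes: ellipsoid `4/3 pi a b c`; elliptic cylinder
#' `pi a b (2c)`; p-ball `8 A B C Gamma(1+1/p)^3 / Gamma(1+3/p)`; cylinder
#' `pi r^2 h`. The membrane shell volume is thickness x surface area with the
#' area estimated by deterministic quadrature over directions.
#'
#' @param region a region object.
#' @return volume in um^3.
#' @examples
#' compartment_volume(nucleus_shape("elliptic_cylinder", c(13, 7, 1.25)))
#' @export
compartment_volume <- function(region) UseMethod("compartment_volume")

#' @export
compartment_volume.nucleus_shape <- function(region) {
  h <- region$half_axes
  switch(region$kind,
    ellipsoid = 4 / 3 * pi * prod(h),
    elliptic_cylinder = pi * h[1] * h[2] * (2 * h[3]))
}

#' @export
compartment_volume.region_ellipsoid <- function(region)
  4 / 3 * pi * prod(region$half_axes)

#' @export
compartment_volume.region_pball <- function(region)
  8 * prod(region$half_axes) * pball_volume_factor(region$p)

#' @export
compartment_volume.region_cylinder <- function(region)
  pi * region$radius^2 * region$height

#' @export
compartment_volume.region_elliptic_cylinder <- function(region) {
  h <- region$half_axes
  pi * h[1] * h[2] * (2 * h[3])
}

#' @export
compartment_volume.region_shell <- function(region) {
  # thickness x surface area; area by spherical quadrature of the radius map
  # r(theta, phi): dA = r sqrt(r^2 sin^2 th + r_th^2 sin^2 th + r_ph^2) dth dph
  b <- region$base
  n <- 128L
  th <- (seq_len(n) - 0.5) * pi / n
  ph <- (seq_len(2L * n) - 0.5) * pi / n
  g <- expand.grid(th = th, ph = ph)
  rad <- function(t, p) region_radius(b, cbind(sin(t) * cos(p), sin(t) * sin(p), cos(t)))
  eps <- 1e-4
  r <- rad(g$th, g$ph)
  rt <- (rad(g$th + eps, g$ph) - rad(g$th - eps, g$ph)) / (2 * eps)
  rp <- (rad(g$th, g$ph + eps) - rad(g$th, g$ph - eps)) / (2 * eps)
  dA <- r * sqrt(r^2 * sin(g$th)^2 + rt^2 * sin(g$th)^2 + rp^2) * (pi / n)^2 / 2
  sum(dA) * region$thickness
}

# radius of the p-ball surface along unit directions d (matrix n x 3)
pball_radius <- function(pb, d) {
  s <- rowSums((abs(d) / matrix(pb$half_axes, nrow(d), 3, byrow = TRUE))^pb$p)
  s^(-1 / pb$p)
}

#' Point containment test
#'
#' Boundary points resolve as inside (closed regions); nested compartments in
#' a [cell_morphology()] resolve to the innermost compartment.
#'
#' @param region a region object.
#' @param point numeric length-3 point, or an `n x 3` matrix of points.
#' @return logical vector.
#' @export
region_contains <- function(region, point) UseMethod("region_contains")

as_point_matrix <- function(point) {
  if (is.matrix(point)) point else matrix(as.numeric(point), ncol = 3)
}

#' @export
region_contains.nucleus_shape <- function(region, point) {
  x <- sweep(as_point_matrix(point), 2, region$center)
  h <- region$half_axes
  if (region$kind == "ellipsoid") {
    rowSums(sweep(x, 2, h, "/")^2) <= 1
  } else {
    (x[, 1] / h[1])^2 + (x[, 2] / h[2])^2 <= 1 & abs(x[, 3]) <= h[3]
  }
}

#' @export
region_contains.region_ellipsoid <- function(region, point) {
  x <- sweep(as_point_matrix(point), 2, region$center)
  rowSums(sweep(x, 2, region$half_axes, "/")^2) <= 1
}

#' @export
region_contains.region_pball <- function(region, point) {
  x <- sweep(as_point_matrix(point), 2, region$center)
  rowSums(sweep(abs(x), 2, region$half_axes, "/")^region$p) <= 1
}

#' @export
region_contains.region_cylinder <- function(region, point) {
  x <- as_point_matrix(point)
  dx <- x[, 1] - region$center_xy[1]
  dy <- x[, 2] - region$center_xy[2]
  dx^2 + dy^2 <= region$radius^2 & x[, 3] >= 0 & x[, 3] <= region$height
}

#' @export
region_contains.region_shell <- function(region, point) {
  b <- region$base
  x <- sweep(as_point_matrix(point), 2, b$center)
  r <- sqrt(rowSums(x^2))
  ok <- r > 0
  out <- rep(FALSE, nrow(x))
  if (any(ok)) {
    d <- x[ok, , drop = FALSE] / r[ok]
    rs <- region_radius(b, d)
    out[ok] <- r[ok] > rs & r[ok] <= rs + region$thickness
  }
  out
}

#' Uniform point sampling inside a region
#'
#' Direct transforms where closed-form (ellipsoids, cylinders), rejection from
#' the bounding box for p-balls, and radial offsetting of surface points for
#' the membrane shell. Sampling consumes the R RNG stream, so `set.seed()`
#' makes it reproducible.
#'
#' @param region a region object.
#' @param n number of points.
#' @return `n x 3` matrix of points in um.
#' @export
sample_uniform_point <- function(region, n = 1L) UseMethod("sample_uniform_point")

sample_unit_ball <- function(n) {
  # Marsaglia: normalize gaussians, scale by U^(1/3)
  g <- matrix(rnorm(3L * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  g * runif(n)^(1 / 3)
}

#' @export
sample_uniform_point.nucleus_shape <- function(region, n = 1L) {
  h <- region$half_axes
  if (region$kind == "ellipsoid") {
    p <- sweep(sample_unit_ball(n), 2, h, "*")
  } else {
    u <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    p <- cbind(h[1] * u * cos(th), h[2] * u * sin(th), runif(n, -h[3], h[3]))
  }
  sweep(p, 2, region$center, "+")
}

#' @export
sample_uniform_point.region_ellipsoid <- function(region, n = 1L) {
  sweep(sweep(sample_unit_ball(n), 2, region$half_axes, "*"), 2, region$center, "+")
}

#' @export
sample_uniform_point.region_cylinder <- function(region, n = 1L) {
  u <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  cbind(region$center_xy[1] + region$radius * u * cos(th),
        region$center_xy[2] + region$radius * u * sin(th),
        runif(n, 0, region$height))
}

#' @export
sample_uniform_point.region_pball <- function(region, n = 1L) {
  h <- region$half_axes
  acc_floor <- 1e-4
  expected_acc <- pball_volume_factor(region$p)
  if (expected_acc < acc_floor) stop("pathological region: rejection acceptance below 1e-4")
  out <- matrix(NA_real_, 0, 3)
  guard <- 0L
  while (nrow(out) < n) {
    m <- max(64L, ceiling((n - nrow(out)) / expected_acc * 1.2))
    cand <- cbind(runif(m, -h[1], h[1]), runif(m, -h[2], h[2]), runif(m, -h[3], h[3]))
    keep <- rowSums(sweep(abs(cand), 2, h, "/")^region$p) <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
    guard <- guard + 1L
    if (guard > 1000L) stop("pathological region: rejection sampling failed to converge")
  }
  sweep(out[seq_len(n), , drop = FALSE], 2, region$center, "+")
}

#' @export
sample_uniform_point.region_shell <- function(region, n = 1L) {
  b <- region$base
  g <- matrix(rnorm(3L * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  rs <- region_radius(b, g)
  r <- rs + runif(n) * region$thickness
  sweep(g * r, 2, b$center, "+")
}

#' @export
region_contains.region_elliptic_cylinder <- function(region, point) {
  x <- sweep(as_point_matrix(point), 2, region$center)
  h <- region$half_axes
  (x[, 1] / h[1])^2 + (x[, 2] / h[2])^2 <= 1 & abs(x[, 3]) <= h[3]
}

#' @export
sample_uniform_point.region_elliptic_cylinder <- function(region, n = 1L) {
  h <- region$half_axes
  u <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  p <- cbind(h[1] * u * cos(th), h[2] * u * sin(th), runif(n, -h[3], h[3]))
  sweep(p, 2, region$center, "+")
}

#' First nucleus crossing of a ray
#'
#' Intersects the ray `start + t * direction`, `t > 0`, with the nucleus
#' boundary and returns the first entry point and the chord length through the
#' solid, or `NULL` if the ray misses it. A ray starting inside returns the
#' start itself as entry with the remaining chord.
#'
#' @param nucleus a [nucleus_shape()].
#' @param start numeric length-3 ray origin in um.
#' @param direction numeric length-3 unit vector.
#' @return `NULL`, or a list with `entry` (point), `t_entry`, and `chord` (um).
#' @export
nucleus_crossing <- function(nucleus, start, direction) {
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit vector")
  iv <- ray_nucleus_interval(nucleus, as.numeric(start), direction)
  if (is.null(iv)) return(NULL)
  t0 <- max(iv[1], 0); t1 <- iv[2]
  if (t1 <= max(t0, 0) || t1 <= 0) return(NULL)
  list(entry = as.numeric(start) + t0 * direction, t_entry = t0, chord = t1 - t0)
}

# [t_in, t_out] of the ray-solid intersection, or NULL; t may be negative.
ray_nucleus_interval <- function(nucleus, p, d) {
  h <- nucleus$half_axes
  q <- p - nucleus$center
  if (nucleus$kind == "ellipsoid") {
    ds <- d / h; qs <- q / h
    A <- sum(ds^2); B <- 2 * sum(qs * ds); C <- sum(qs^2) - 1
    disc <- B^2 - 4 * A * C
    if (disc <= 0) return(NULL)
    s <- sqrt(disc)
    return(c((-B - s) / (2 * A), (-B + s) / (2 * A)))
  }
  # elliptic cylinder: ellipse interval in xy intersected with z-slab interval
  A <- (d[1] / h[1])^2 + (d[2] / h[2])^2
  B <- 2 * (q[1] * d[1] / h[1]^2 + q[2] * d[2] / h[2]^2)
  C <- (q[1] / h[1])^2 + (q[2] / h[2])^2 - 1
  if (A < 1e-300) {
    if (C > 0) return(NULL)
    e <- c(-Inf, Inf)
  } else {
    disc <- B^2 - 4 * A * C
    if (disc <= 0) return(NULL)
    s <- sqrt(disc)
    e <- c((-B - s) / (2 * A), (-B + s) / (2 * A))
  }
  if (abs(d[3]) < 1e-300) {
    if (abs(q[3]) > h[3]) return(NULL)
    z <- c(-Inf, Inf)
  } else {
    z <- sort(c((-h[3] - q[3]) / d[3], (h[3] - q[3]) / d[3]))
  }
  t0 <- max(e[1], z[1]); t1 <- min(e[2], z[2])
  if (t1 <= t0) return(NULL)
  c(t0, t1)
}
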