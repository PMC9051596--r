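# Optional triangle-mesh regions (ASCII OBJ or PLY, units um), for
# user-supplied imaged morphologies in place of the parametric surrogates.

#' Load a closed triangle surface as a region
#'
#' Reads an ASCII Wavefront OBJ (`v`/`f` records; polygons are fan-
#' triangulated) or ASCII PLY file. The surface must be closed and
#' consistently oriented; volume is computed from signed tetrahedra and
#' containment by ray-crossing parity, so the region can be sampled,
#' volume-checked, and used like any parametric compartment.
#'
#' @param path mesh file (`.obj` or `.ply`).
#' @return object of class `region_mesh` with `vertices` (n x 3) and `faces`
#'   (m x 3, 1-based).
#' @export
read_mesh_region <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vt <- grep("^v\\s", lines, value = TRUE)
    fc <- grep("^f\\s", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vt, "\\s+"), function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fc, "\\s+"), function(x) {
      ix <- as.integer(sub("/.*", "", x[-1]))
      if (length(ix) < 3) stop("faces must have >= 3 vertices")
      cbind(ix[1], ix[2:(length(ix) - 1)], ix[3:length(ix)])  # fan triangulation
    }))
  } else if (ext == "ply") {
    if (!grepl("^ply", lines[1])) stop("not a PLY file")
    if (!any(grepl("format ascii", lines))) stop("only ASCII PLY is supported")
    nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub(".*face\\s+", "", grep("element face", lines, value = TRUE)[1]))
    hdr <- which(lines == "end_header")
    v <- do.call(rbind, lapply(strsplit(trimws(lines[(hdr + 1):(hdr + nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(lines[(hdr + nv + 1):(hdr + nv + nf)]), "\\s+"),
                               function(x) {
      k <- as.integer(x[1]); ix <- as.integer(x[2:(1 + k)]) + 1L
      cbind(ix[1], ix[2:(k - 1)], ix[3:k])
    }))
  } else stop("unsupported mesh format: ", ext)
  mesh_region(v, f)
}

#' @rdname read_mesh_region
#' @param vertices `n x 3` numeric matrix (um).
#' @param faces `m x 3` integer matrix of 1-based vertex indices.
#' @export
mesh_region <- function(vertices, faces) {
  if (max(faces) > nrow(vertices) || min(faces) < 1) stop("face index out of range")
  structure(list(vertices = vertices, faces = faces,
                 center = colMeans(vertices),
                 bbox_lo = apply(vertices, 2, min),
                 bbox_hi = apply(vertices, 2, max)),
            class = c("region_mesh", "region"))
}

#' @export
compartment_volume.region_mesh <- function(region) {
  v <- region$vertices; f <- region$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c3 <- v[f[, 3], , drop = FALSE]
  # sum of signed tetrahedron volumes against the origin
  vol <- sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
             a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
             a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
  abs(vol)
}

#' @export
region_contains.region_mesh <- function(region, point) {
  x <- as_point_matrix(point)
  vapply(seq_len(nrow(x)), function(i) mesh_parity(region, x[i, ]), logical(1))
}

# ray-crossing parity along a fixed slightly-irrational direction (avoids
# edge/vertex degeneracies for axis-aligned meshes)
mesh_parity <- function(region, p) {
  d <- c(0.57735027, 0.52573111, 0.62480425)
  v <- region$vertices; f <- region$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  # Moller-Trumbore, vectorized over faces
  h1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
  h2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
  h3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
  det <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(det) > 1e-12
  s1 <- p[1] - a[, 1]; s2 <- p[2] - a[, 2]; s3 <- p[3] - a[, 3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / det
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  vv <- (d[1] * q1 + d[2] * q2 + d[3] * q3) / det
  tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / det
  hits <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 1e-9
  sum(hits) %% 2L == 1L
}

#' @export
sample_uniform_point.region_mesh <- function(region, n = 1L) {
  lo <- region$bbox_lo; hi <- region$bbox_hi
  out <- matrix(NA_real_, 0, 3); tries <- 0L
  vol_frac <- max(compartment_volume(region) / prod(hi - lo), 1e-4)
  while (nrow(out) < n) {
    m <- max(16L, ceiling((n - nrow(out)) / vol_frac * 1.2))
    cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]), runif(m, lo[3], hi[3]))
    keep <- region_contains(region, cand)
    out <- rbind(out, cand[keep, , drop = FALSE])
    tries <- tries + 1L
    if (tries > 200L) stop("pathological region: mesh rejection sampling failed")
  }
  out[seq_len(n), , drop = FALSE]
}
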