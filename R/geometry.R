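# Geometry primitives shared by the synthetic generator and the region
# module. Two geometry flavours are used: rotated ellipses (parametric,
# from the generator) and polygons (vertex matrices, from ImageJ ROI
# import). Both rasterize to logical masks on the image grid; masks are
# the canonical representation for containment and area measurement.

#' Create an ellipse geometry
#'
#' @param cr,cc center (row, col), 1-based pixel coordinates.
#' @param a,b semi-axes in pixels; `a` lies along `theta`.
#' @param theta rotation in radians (angle of the `a` axis measured in the
#'   (col, row) plane).
#' @return An object of class `ellipse_geom`.
#' @export
ellipse_geom <- function(cr, cc, a, b, theta = 0) {
  stopifnot(a > 0, b > 0)
  structure(list(cr = cr, cc = cc, a = a, b = b, theta = theta),
            class = "ellipse_geom")
}

#' Create a polygon geometry
#'
#' @param r,c numeric vectors of vertex coordinates (1-based pixel
#'   coordinates, row and col). The polygon is closed implicitly.
#' @return An object of class `polygon_geom`.
#' @export
polygon_geom <- function(r, c) {
  stopifnot(length(r) == length(c), length(r) >= 3)
  structure(list(r = as.numeric(r), c = as.numeric(c)),
            class = "polygon_geom")
}

# Normalized squared ellipse coordinate: <= 1 inside, 1 on the boundary.
ellipse_qform <- function(geom, r, c) {
  dr <- r - geom$cr
  dc <- c - geom$cc
  ct <- cos(geom$theta); st <- sin(geom$theta)
  u <- (dc * ct + dr * st) / geom$a
  v <- (-dc * st + dr * ct) / geom$b
  u * u + v * v
}

#' Test points for geometry membership
#'
#' @param geom an `ellipse_geom` or `polygon_geom`.
#' @param r,c coordinate vectors.
#' @return Logical vector, `TRUE` where (r, c) lies inside (boundary
#'   counts as inside).
#' @export
geom_contains <- function(geom, r, c) {
  UseMethod("geom_contains")
}

#' @export
geom_contains.ellipse_geom <- function(geom, r, c) {
  ellipse_qform(geom, r, c) <= 1
}

#' @export
geom_contains.polygon_geom <- function(geom, r, c) {
  # even-odd rule; points exactly on an edge are treated as inside via
  # the half-open crossing convention plus an explicit vertex check
  n <- length(geom$r)
  px <- geom$c; py <- geom$r
  inside <- logical(length(r))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- ((yi > r) != (yj > r)) &
      (c < (xj - xi) * (r - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a geometry to a logical mask
#'
#' A pixel belongs to the mask when its integer center lies inside the
#' geometry. Pixels outside the image bounds are clipped.
#'
#' @param geom geometry object.
#' @param shape integer `c(nrow, ncol)` of the target image.
#' @return Logical matrix of dimension `shape`.
#' @export
rasterize_geom <- function(geom, shape) {
  UseMethod("rasterize_geom")
}

#' @export
rasterize_geom.ellipse_geom <- function(geom, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  ext <- max(geom$a, geom$b)
  r0 <- max(1L, floor(geom$cr - ext)); r1 <- min(shape[1], ceiling(geom$cr + ext))
  c0 <- max(1L, floor(geom$cc - ext)); c1 <- min(shape[2], ceiling(geom$cc + ext))
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  q <- ellipse_qform(geom,
                     matrix(rr, length(rr), length(cc)),
                     matrix(cc, length(rr), length(cc), byrow = TRUE))
  m[rr, cc] <- q <= 1
  m
}

#' @export
rasterize_geom.polygon_geom <- function(geom, shape) {
  # scanline fill on pixel-center rows
  m <- matrix(FALSE, shape[1], shape[2])
  py <- geom$r; px <- geom$c
  n <- length(py)
  r0 <- max(1L, floor(min(py))); r1 <- min(shape[1], ceiling(max(py)))
  if (r0 > r1) return(m)
  for (row in r0:r1) {
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      yi <- py[i]; yj <- py[j]
      if ((yi > row) != (yj > row)) {
        xs <- c(xs, px[i] + (row - yi) / (yj - yi) * (px[j] - px[i]))
      }
      j <- i
    }
    if (length(xs) >= 2) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c0 <- max(1L, ceiling(xs[k])); c1 <- min(shape[2], floor(xs[k + 1]))
        if (c0 <= c1) m[row, c0:c1] <- TRUE
      }
    }
  }
  m
}

#' Approximate a geometry by a closed polygon
#'
#' Used for ROI export and for converting ellipses to vertex form.
#'
#' @param geom geometry object.
#' @param n_vertices number of vertices for curved geometries.
#' @return A `polygon_geom`.
#' @export
as_polygon <- function(geom, n_vertices = 96) {
  UseMethod("as_polygon")
}

#' @export
as_polygon.polygon_geom <- function(geom, n_vertices = 96) geom

#' @export
as_polygon.ellipse_geom <- function(geom, n_vertices = 96) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ct <- cos(geom$theta); st <- sin(geom$theta)
  u <- geom$a * cos(t); v <- geom$b * sin(t)
  polygon_geom(r = geom$cr + u * st + v * ct,
               c = geom$cc + u * ct - v * st)
}
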