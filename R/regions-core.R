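# RegionSet: follicle and germinal-center (GC) compartments of one
# image, held as per-region pixel sets plus label matrices for O(1)
# centroid lookup. GC pixels are always a subset of their parent
# follicle's pixels, so a GC label lookup implies follicle membership
# and boundary ties resolve inward (GC over follicle over outside).

new_region_set <- function(follicle_px, gc_px, gc_parent, shape,
                           pixel_size = 0.5, source = "auto",
                           geoms = NULL, gc_contained_frac = NULL) {
  stopifnot(length(gc_px) == length(gc_parent))
  fl <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(follicle_px)) fl[follicle_px[[i]]] <- i
  gl <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(gc_px)) gl[gc_px[[i]]] <- i
  follicles <- data.frame(
    follicle_id = seq_along(follicle_px),
    area_px = vapply(follicle_px, length, integer(1)))
  gcs <- data.frame(
    gc_id = seq_along(gc_px),
    parent_follicle_id = as.integer(gc_parent),
    area_px = vapply(gc_px, length, integer(1)))
  if (!is.null(gc_contained_frac)) gcs$contained_frac <- gc_contained_frac
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 source = source,
                 follicles = follicles, gcs = gcs,
                 follicle_px = follicle_px, gc_px = gc_px,
                 follicle_labels = fl, gc_labels = gl,
                 geoms = geoms),
            class = "region_set")
}

#' Build a RegionSet from geometries
#'
#' Rasterizes follicle and GC geometries onto the image grid. Each GC is
#' clipped to its parent follicle so the nesting invariant (GC pixels
#' are a subset of follicle pixels) holds exactly.
#'
#' @param follicles list of geometries ([ellipse_geom()] /
#'   [polygon_geom()]), one per follicle.
#' @param gcs list of GC geometries.
#' @param gc_parent integer vector mapping each GC to its parent
#'   follicle index (`NA` for orphans, which are kept but not clipped).
#' @param shape image shape `c(nrow, ncol)`.
#' @param pixel_size micrometers per pixel.
#' @param source provenance tag, `"manual_roi"` or `"auto"`.
#' @return A `region_set`.
#' @export
region_set <- function(follicles, gcs, gc_parent, shape,
                       pixel_size = 0.5, source = "auto") {
  f_px <- lapply(follicles, function(g) which(rasterize_geom(g, shape)))
  frac <- numeric(length(gcs))
  g_px <- vector("list", length(gcs))
  for (i in seq_along(gcs)) {
    raw <- which(rasterize_geom(gcs[[i]], shape))
    if (!is.na(gc_parent[i])) {
      clipped <- intersect(raw, f_px[[gc_parent[i]]])
      frac[i] <- if (length(raw)) length(clipped) / length(raw) else 0
      g_px[[i]] <- clipped
    } else {
      frac[i] <- 0
      g_px[[i]] <- raw
    }
  }
  new_region_set(f_px, g_px, gc_parent, shape, pixel_size, source,
                 geoms = list(follicles = follicles, gcs = gcs),
                 gc_contained_frac = frac)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> [%s] %d follicles, %d GCs on %dx%d px\n",
              x$source, nrow(x$follicles), nrow(x$gcs),
              x$shape[1], x$shape[2]))
  invisible(x)
}
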