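# Follicle / germinal-center region handling: import of manually drawn
# ImageJ ROIs (the reference procedure), automatic region proposal from
# CD19/BCL6 masks (for unattended synthetic runs), morphometry, and
# allocation of called cells to compartments.

#' Import follicle/GC regions from ImageJ ROI files
#'
#' Reads a `.roi` file or `.zip` archive of ROIs, classifies each ROI
#' as follicle or GC by its name prefix, and infers GC parentage by
#' maximal containment of the rasterized GC pixels in a follicle. A GC
#' contained (at the 99% level) in no follicle is kept as a flagged
#' orphan (`parent_follicle_id = NA`) with a warning; a GC fully
#' contained in more than one follicle is an error.
#'
#' @param roi_file path to `.roi` or `.zip`.
#' @param image_shape image shape `c(nrow, ncol)` the ROIs refer to.
#' @param pixel_size micrometers per pixel.
#' @param follicle_prefix,gc_prefix case-insensitive name prefixes
#'   distinguishing the two region classes.
#' @return A `region_set` with `source = "manual_roi"`.
#' @export
import_regions <- function(roi_file, image_shape, pixel_size = 0.5,
                           follicle_prefix = "follicle", gc_prefix = "gc") {
  rois <- read_ij_rois(roi_file)
  if (length(rois) == 0) {
    warning("empty ROI archive: ", roi_file)
    return(new_region_set(list(), list(), integer(), image_shape,
                          pixel_size, source = "manual_roi"))
  }
  nms <- tolower(vapply(rois, `[[`, character(1), "name"))
  is_f <- startsWith(nms, tolower(follicle_prefix))
  is_g <- startsWith(nms, tolower(gc_prefix))
  if (any(!is_f & !is_g))
    stop("ROI name(s) match neither prefix '", follicle_prefix, "' nor '",
         gc_prefix, "': ", paste(nms[!is_f & !is_g], collapse = ", "))
  f_geoms <- lapply(rois[is_f], `[[`, "geom")
  g_geoms <- lapply(rois[is_g], `[[`, "geom")
  f_px <- lapply(f_geoms, function(g) which(rasterize_geom(g, image_shape)))
  g_px_raw <- lapply(g_geoms, function(g) which(rasterize_geom(g, image_shape)))
  parent <- rep(NA_integer_, length(g_geoms))
  frac <- numeric(length(g_geoms))
  g_px <- vector("list", length(g_geoms))
  for (i in seq_along(g_geoms)) {
    contain <- vapply(f_px, function(fp)
      if (length(g_px_raw[[i]])) mean(g_px_raw[[i]] %in% fp) else 0, numeric(1))
    inside <- which(contain >= 0.99)
    if (length(inside) > 1)
      stop("ambiguous GC parentage: GC ", i, " contained in follicles ",
           paste(inside, collapse = ", "))
    if (length(inside) == 1) {
      parent[i] <- inside
      frac[i] <- contain[inside]
      g_px[[i]] <- intersect(g_px_raw[[i]], f_px[[inside]])
    } else {
      warning("GC ", i, " is contained in no follicle (max containment ",
              sprintf("%.2f", max(c(contain, 0))), "); flagged as orphan")
      frac[i] <- max(c(contain, 0))
      g_px[[i]] <- g_px_raw[[i]]
    }
  }
  new_region_set(f_px, g_px, parent, image_shape, pixel_size,
                 source = "manual_roi",
                 geoms = list(follicles = f_geoms, gcs = g_geoms),
                 gc_contained_frac = frac)
}

#' Propose follicle/GC regions from CD19 and BCL6 masks
#'
#' Automated stand-in for manual region drawing, so synthetic samples
#' can be analysed unattended: follicles are morphologically closed,
#' hole-filled CD19 components above a minimum area; GCs are closed,
#' hole-filled BCL6-dense components that intersect a follicle, clipped
#' to it. BCL6 blobs outside all follicles (e.g. extrafollicular T_FK
#' clusters) are never promoted to GCs.
#'
#' @param cd19_mask,bcl6_mask `signal_mask` objects (or logical
#'   matrices) of identical shape.
#' @param min_follicle_area_px minimum follicle component area.
#' @param smoothing_px closing radius in pixels used to bridge the
#'   gaps between individual stained cells.
#' @param min_gc_area_px minimum GC component area.
#' @param grow_px final outward dilation of each region in pixels,
#'   compensating for the margin between the outermost cell bodies and
#'   the anatomical region boundary.
#' @param pixel_size micrometers per pixel.
#' @return A `region_set` with `source = "auto"`.
#' @export
auto_regions <- function(cd19_mask, bcl6_mask, min_follicle_area_px = 4000,
                         smoothing_px = 20, min_gc_area_px = 400,
                         grow_px = 4, pixel_size = 0.5) {
  m19 <- if (inherits(cd19_mask, "signal_mask")) cd19_mask$mask else cd19_mask != 0
  m6 <- if (inherits(bcl6_mask, "signal_mask")) bcl6_mask$mask else bcl6_mask != 0
  if (!identical(dim(m19), dim(m6))) stop("mask shapes differ")
  shape <- dim(m19)
  close_fill <- function(m, radius) {
    if (!any(m)) return(m)
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, "disc")
    closed <- EBImage::closing(m, brush)
    EBImage::fillHull(closed) > 0
  }
  grow <- function(px) {
    if (grow_px <= 0 || !length(px)) return(px)
    m <- matrix(FALSE, shape[1], shape[2])
    m[px] <- TRUE
    which(EBImage::dilate(m, EBImage::makeBrush(2L * as.integer(grow_px) + 1L,
                                                "disc")) > 0)
  }
  fol <- close_fill(m19, smoothing_px)
  Lf <- label_components(fol, 8)
  if (max(Lf) > 0) {
    areas <- tabulate(Lf[Lf > 0], nbins = max(Lf))
    keep <- which(areas >= min_follicle_area_px)
    f_px <- lapply(keep, function(k) grow(which(Lf == k)))
  } else f_px <- list()
  # rebuild a follicle label lookup over retained follicles only
  fl <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(f_px)) fl[f_px[[i]]] <- i

  gc <- close_fill(m6, smoothing_px)
  Lg <- label_components(gc, 8)
  g_px <- list(); parent <- integer(0)
  if (max(Lg) > 0) {
    for (k in seq_len(max(Lg))) {
      px <- which(Lg == k)
      if (length(px) < min_gc_area_px) next
      hits <- fl[px]
      hits <- hits[hits > 0]
      if (!length(hits)) next  # extrafollicular BCL6 blob: not a GC
      pf <- as.integer(names(which.max(table(hits))))
      px <- grow(px)
      g_px[[length(g_px) + 1L]] <- px[fl[px] == pf]  # clip to follicle
      parent <- c(parent, pf)
    }
  }
  new_region_set(f_px, g_px, parent, shape, pixel_size, source = "auto")
}

#' Measure follicle/GC morphometry
#'
#' Areas are pixel counts scaled by `pixel_size^2`; coverage fractions
#' are computed on the union of regions (overlaps are not
#' double-counted).
#'
#' @param regions a `region_set`.
#' @param image_shape shape to compute coverage against (defaults to
#'   the region set's own shape).
#' @return A `region_morphometry` list: `n_follicles`, `n_gcs`,
#'   `follicle_area_px2`/`gc_area_px2` (per-region vectors),
#'   `mean_follicle_area_px2`, `mean_gc_area_px2`,
#'   `mean_follicle_area_um2`, `mean_gc_area_um2`,
#'   `follicle_coverage`, `gc_coverage`.
#' @export
measure_regions <- function(regions, image_shape = regions$shape) {
  npx <- prod(image_shape)
  f_area <- regions$follicles$area_px
  g_area <- regions$gcs$area_px
  f_union <- length(unique(unlist(regions$follicle_px)))
  g_union <- length(unique(unlist(regions$gc_px)))
  um2 <- regions$pixel_size^2
  structure(list(
    n_follicles = nrow(regions$follicles),
    n_gcs = nrow(regions$gcs),
    follicle_area_px2 = f_area,
    gc_area_px2 = g_area,
    mean_follicle_area_px2 = if (length(f_area)) mean(f_area) else 0,
    mean_gc_area_px2 = if (length(g_area)) mean(g_area) else 0,
    mean_follicle_area_um2 = (if (length(f_area)) mean(f_area) else 0) * um2,
    mean_gc_area_um2 = (if (length(g_area)) mean(g_area) else 0) * um2,
    follicle_coverage = f_union / npx,
    gc_coverage = g_union / npx),
    class = "region_morphometry")
}

#' Allocate cells to GC / follicle / extrafollicular compartments
#'
#' Assignment is by centroid containment: a centroid inside a GC is
#' `"GC"`, else inside a follicle `"follicle"`, else
#' `"extrafollicular"`. GC pixels are a subset of their parent
#' follicle's pixels, so boundary ties resolve to the inner compartment
#' and every GC-assigned cell also carries its parent `follicle_id`
#' (GC cells count toward follicular tallies).
#'
#' @param calls a `subtype_calls` object, or a data frame with
#'   `cell_id`, `centroid_r`, `centroid_c`.
#' @param regions a `region_set`.
#' @return Data frame: `cell_id`, `compartment`, `follicle_id`,
#'   `gc_id`.
#' @export
assign_cells <- function(calls, regions) {
  df <- if (inherits(calls, "subtype_calls")) calls$calls else calls
  n <- nrow(df)
  out <- data.frame(cell_id = df$cell_id,
                    compartment = character(n),
                    follicle_id = NA_integer_,
                    gc_id = NA_integer_)
  ri <- pmin(pmax(round(df$centroid_r), 1L), regions$shape[1])
  ci <- pmin(pmax(round(df$centroid_c), 1L), regions$shape[2])
  idx <- cbind(ri, ci)
  g <- regions$gc_labels[idx]
  f <- regions$follicle_labels[idx]
  in_gc <- g > 0
  out$compartment <- ifelse(in_gc, "GC",
                            ifelse(f > 0, "follicle", "extrafollicular"))
  out$gc_id[in_gc] <- g[in_gc]
  out$follicle_id[in_gc] <- regions$gcs$parent_follicle_id[g[in_gc]]
  fol_only <- !in_gc & f > 0
  out$follicle_id[fol_only] <- f[fol_only]
  out
}
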