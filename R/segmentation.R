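# Per-channel thresholding into binary signal masks and single-marker
# cell detection by connected components with the 20-200 px area filter.

#' Threshold one channel into a binary signal mask
#'
#' Thresholds are per channel and per sample (laser gain differed
#' between tissues, so no global threshold is meaningful). The default
#' is Otsu's method on a 256-bin histogram; `manual` and `quantile`
#' overrides are available. The threshold value is recorded for audit.
#' An all-equal channel yields an empty mask with a warning under Otsu.
#'
#' @param img an [mc_image].
#' @param channel channel name.
#' @param method `"otsu"`, `"manual"` or `"quantile"`.
#' @param manual_value threshold intensity, required iff
#'   `method = "manual"`.
#' @param prob upper-tail probability for `method = "quantile"`.
#' @param max_fg_frac Otsu guard for sparsely stained channels: cells
#'   occupy a small minority of tissue area, so when the mask would
#'   cover more than this fraction of pixels the threshold is re-fit by
#'   Otsu on the pixels above the current threshold (at most 3 rounds).
#' @return A `signal_mask`: logical matrix `mask` (`intensity >
#'   threshold`), `threshold_value`, `method`, `channel`.
#' @export
threshold_channel <- function(img, channel,
                              method = c("otsu", "manual", "quantile"),
                              manual_value = NULL, prob = 0.99,
                              max_fg_frac = 0.25) {
  method <- match.arg(method)
  if (!channel %in% names(img$channels))
    stop("channel not found: ", channel)
  if (method == "manual" && is.null(manual_value))
    stop("'manual_value' required when method = 'manual'")
  if (method != "manual" && !is.null(manual_value))
    stop("'manual_value' given but method is not 'manual'")
  x <- img$channels[[channel]]
  rng <- range(x)
  th <- switch(method,
    manual = manual_value,
    quantile = unname(quantile(x, prob)),
    otsu = {
      if (rng[1] == rng[2]) {
        warning("channel '", channel,
                "' is constant; Otsu undefined, returning empty mask")
        rng[2]  # mask = x > max(x) is empty
      } else {
        otsu_on <- function(v) {
          r <- range(v)
          if (r[1] == r[2]) return(r[2])
          scaled <- (v - r[1]) / (r[2] - r[1])
          EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                        range = c(0, 1), levels = 256L) * (r[2] - r[1]) + r[1]
        }
        th <- otsu_on(as.vector(x))
        for (round in 1:3) {
          if (mean(x > th) <= max_fg_frac) break
          th <- otsu_on(x[x > th])
        }
        th
      }
    })
  structure(list(channel = channel, mask = x > th,
                 threshold_value = as.numeric(th), method = method),
            class = "signal_mask")
}

#' Construct a signal mask from a logical matrix
#'
#' Convenience constructor for masks built directly (tests, imported
#' masks).
#'
#' @param mask logical matrix.
#' @param channel channel name label.
#' @param threshold_value recorded threshold (default `NA`).
#' @param method provenance label.
#' @return A `signal_mask`.
#' @export
signal_mask <- function(mask, channel = "mask", threshold_value = NA_real_,
                        method = "manual") {
  stopifnot(is.matrix(mask))
  structure(list(channel = channel, mask = mask != 0,
                 threshold_value = threshold_value, method = method),
            class = "signal_mask")
}

#' Label connected components of a binary mask
#'
#' 4-connected labeling is delegated to `EBImage::bwlabel`;
#' 8-connectivity merges 4-connected labels that touch diagonally
#' (components of the label adjacency graph).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, matching common particle
#'   analysis behavior).
#' @return Integer label matrix; 0 is background, labels are
#'   consecutive from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  L <- EBImage::bwlabel(mask != 0)
  storage.mode(L) <- "integer"
  n <- max(L)
  if (connectivity == 4 || n <= 1) return(L)
  nr <- nrow(L); nc <- ncol(L)
  a1 <- L[-nr, -nc]; b1 <- L[-1, -1]    # down-right diagonal
  a2 <- L[-nr, -1];  b2 <- L[-1, -nc]   # down-left diagonal
  e1 <- a1 > 0 & b1 > 0 & a1 != b1
  e2 <- a2 > 0 & b2 > 0 & a2 != b2
  edges <- rbind(cbind(a1[e1], b1[e1]), cbind(a2[e2], b2[e2]))
  if (nrow(edges) == 0) return(L)
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)
  map <- seq_len(n)
  vid <- as.integer(igraph::V(g)$name)
  map[vid] <- n + comp$membership   # temporary ids above old range
  relab <- map[L[L > 0]]
  # renumber consecutively, preserving first-occurrence (raster) order
  u <- unique(relab)
  L[L > 0] <- match(relab, u)
  L
}

#' Detect single-marker cell objects in a signal mask
#'
#' Connected components of the mask become candidate cells; components
#' with area strictly below `min_area_px` or strictly above
#' `max_area_px` are excluded but reported in a discard ledger
#' (bounds are inclusive: areas of exactly 20 and exactly 200 px are
#' kept under the defaults).
#'
#' @param mask a `signal_mask` or logical matrix.
#' @param min_area_px,max_area_px inclusive area bounds in pixels.
#' @param connectivity 4 or 8.
#' @param img optional [mc_image]; when given, per-channel mean
#'   intensities are measured for each retained cell.
#' @return A `cell_detection`: `cells` data frame (`cell_id`,
#'   `area_px`, `centroid_r`, `centroid_c`, per-channel
#'   `mean_<channel>` when `img` is given), `pixels` (list of linear
#'   pixel indices per retained cell), `discarded` ledger
#'   (`component_id`, `area_px`, `reason`), `labels`, `shape`,
#'   `channel`.
#' @export
detect_cells <- function(mask, min_area_px = 20, max_area_px = 200,
                         connectivity = 8, img = NULL) {
  if (!(min_area_px > 0 && min_area_px <= max_area_px))
    stop("need 0 < min_area_px <= max_area_px")
  channel <- if (inherits(mask, "signal_mask")) mask$channel else "mask"
  m <- if (inherits(mask, "signal_mask")) mask$mask else mask != 0
  L <- label_components(m, connectivity)
  n <- max(L)
  empty_cells <- data.frame(cell_id = integer(), area_px = integer(),
                            centroid_r = numeric(), centroid_c = numeric())
  if (n == 0) {
    return(structure(list(cells = empty_cells, pixels = list(),
                          discarded = data.frame(component_id = integer(),
                                                 area_px = integer(),
                                                 reason = character()),
                          labels = L, shape = dim(m), channel = channel),
                     class = "cell_detection"))
  }
  idx <- which(L > 0)
  lab <- L[idx]
  area <- tabulate(lab, nbins = n)
  rows <- (idx - 1L) %% nrow(m) + 1L
  cols <- (idx - 1L) %/% nrow(m) + 1L
  cr <- as.numeric(rowsum(rows, lab)) / area
  cc <- as.numeric(rowsum(cols, lab)) / area
  keep <- area >= min_area_px & area <= max_area_px
  reason <- ifelse(area < min_area_px, "too_small", "too_large")
  discarded <- data.frame(component_id = which(!keep),
                          area_px = area[!keep],
                          reason = reason[!keep])
  kept <- which(keep)
  cells <- data.frame(cell_id = seq_along(kept),
                      area_px = area[kept],
                      centroid_r = cr[kept], centroid_c = cc[kept])
  pix <- split(idx, lab)[as.character(kept)]
  names(pix) <- NULL
  if (!is.null(img)) {
    for (ch in names(img$channels)) {
      v <- img$channels[[ch]]
      cells[[paste0("mean_", ch)]] <-
        vapply(pix, function(p) mean(v[p]), numeric(1))
    }
  }
  structure(list(cells = cells, pixels = pix, discarded = discarded,
                 labels = L, shape = dim(m), channel = channel),
            class = "cell_detection")
}

#' @export
print.cell_detection <- function(x, ...) {
  cat(sprintf("<cell_detection> channel %s: %d cells retained, %d discarded\n",
              x$channel, nrow(x$cells), nrow(x$discarded)))
  invisible(x)
}
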