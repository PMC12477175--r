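# Treg identification by fractional FOXP3 overlap and detection of
# direct T_FK--Treg cell contacts.

#' Identify FOXP3+ Tregs among CD4+ cells
#'
#' A CD4 cell is a Treg when at least `min_overlap_frac` of its own
#' pixels are FOXP3-positive (inclusive threshold; the reference rule
#' is "at least 25% overlay", so a cell with exactly 25% qualifies).
#' The denominator is always the CD4 cell's own area.
#'
#' @param cd4_cells a `cell_detection` from [detect_cells()] on the CD4
#'   mask.
#' @param foxp3_mask a `signal_mask` (or logical matrix) of the same
#'   shape.
#' @param min_overlap_frac minimum FOXP3-positive pixel fraction.
#' @return A `cell_detection` restricted to Tregs, with a
#'   `foxp3_overlap_frac` column added to `cells`.
#' @export
identify_tregs <- function(cd4_cells, foxp3_mask, min_overlap_frac = 0.25) {
  m <- if (inherits(foxp3_mask, "signal_mask")) foxp3_mask$mask else foxp3_mask != 0
  if (!identical(dim(m), as.integer(cd4_cells$shape)) &&
      !identical(dim(m), cd4_cells$shape))
    stop("FOXP3 mask shape differs from the CD4 detection shape")
  frac <- vapply(cd4_cells$pixels, function(p) mean(m[p]), numeric(1))
  if (!length(frac)) frac <- numeric(0)
  keep <- which(frac >= min_overlap_frac)
  out <- cd4_cells
  out$cells <- cd4_cells$cells[keep, , drop = FALSE]
  out$cells$foxp3_overlap_frac <- frac[keep]
  out$pixels <- cd4_cells$pixels[keep]
  out$channel <- "CD4+FOXP3"
  out
}

# Chebyshev (chessboard) distance between two pixel index sets.
# Adjacent pixels (including diagonals) are at distance 1; the boundary
# gap in background pixels is therefore d - 1.
chebyshev_set_distance <- function(px_a, px_b, nrow) {
  ra <- (px_a - 1L) %% nrow; ca <- (px_a - 1L) %/% nrow
  rb <- (px_b - 1L) %% nrow; cb <- (px_b - 1L) %/% nrow
  best <- Inf
  for (i in seq_along(ra)) {
    d <- pmax(abs(rb - ra[i]), abs(cb - ca[i]))
    m <- min(d)
    if (m < best) best <- m
    if (best == 0) break
  }
  best
}

#' Detect direct T_FK--Treg contacts
#'
#' Two cells are in direct contact when the boundary gap between their
#' pixel sets is at most `max_gap_px` background pixels (chessboard
#' metric, so diagonal touching counts; gap 0 means adjacent or
#' overlapping pixels). Candidate pairs are found by dilating each
#' T_FK pixel set with a box brush of Chebyshev radius `max_gap_px + 1`
#' and testing overlap with the Treg label image; the reported
#' `boundary_gap_px` is the exact set distance minus one, clamped at 0.
#'
#' @param tfk a `subtype_calls` object (its T_FK calls are used) or a
#'   data frame + pixel list pair as produced by [call_subtypes()].
#' @param tregs a `cell_detection` of Treg objects (see
#'   [identify_tregs()]).
#' @param max_gap_px maximum allowed boundary gap in pixels.
#' @return A `contact_result`: `pairs` data frame (`tfk_id`, `treg_id`,
#'   `boundary_gap_px`), `n_tfk_total`, `n_treg_total`,
#'   `pct_tfk_in_contact` (`NA` with `undefined = TRUE` when no T_FK
#'   exist).
#' @export
detect_contacts <- function(tfk, tregs, max_gap_px = 1) {
  if (inherits(tfk, "subtype_calls")) {
    sel <- which(tfk$calls$subtype == "T_FK")
    tfk_df <- tfk$calls[sel, , drop = FALSE]
    tfk_px <- tfk$pixels[sel]
  } else {
    tfk_df <- tfk$calls
    tfk_px <- tfk$pixels
  }
  nrow_img <- tregs$shape[1]
  shape <- tregs$shape
  # treg label canvas for overlap lookup
  TL <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(tregs$pixels)) TL[tregs$pixels[[i]]] <- i
  rad <- as.integer(max_gap_px) + 1L
  pairs <- data.frame(tfk_id = integer(), treg_id = integer(),
                      boundary_gap_px = numeric())
  for (i in seq_along(tfk_px)) {
    px <- tfk_px[[i]]
    r <- (px - 1L) %% shape[1] + 1L
    c <- (px - 1L) %/% shape[1] + 1L
    # dilation by a (2*rad+1) box == all pixels within Chebyshev rad
    r0 <- max(1L, min(r) - rad); r1 <- min(shape[1], max(r) + rad)
    c0 <- max(1L, min(c) - rad); c1 <- min(shape[2], max(c) + rad)
    local <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    local[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
    dil <- EBImage::dilate(local, matrix(TRUE, 2L * rad + 1L, 2L * rad + 1L))
    hits <- unique(TL[r0:r1, c0:c1][dil > 0])
    hits <- sort(hits[hits > 0])
    for (j in hits) {
      d <- chebyshev_set_distance(px, tregs$pixels[[j]], shape[1])
      gap <- max(0, d - 1)
      if (gap <= max_gap_px)
        pairs[nrow(pairs) + 1L, ] <- list(tfk_df$cell_id[i],
                                          tregs$cells$cell_id[j], gap)
    }
  }
  n_tfk <- nrow(tfk_df)
  pct <- if (n_tfk > 0) 100 * length(unique(pairs$tfk_id)) / n_tfk else NA_real_
  structure(list(pairs = pairs,
                 n_tfk_total = n_tfk,
                 n_treg_total = nrow(tregs$cells),
                 pct_tfk_in_contact = pct,
                 undefined = n_tfk == 0,
                 max_gap_px = max_gap_px),
            class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("<contact_result> %d pairs among %d T_FK and %d Tregs (%s%% in contact)\n",
              nrow(x$pairs), x$n_tfk_total, x$n_treg_total,
              if (x$undefined) "NA" else sprintf("%.1f", x$pct_tfk_in_contact)))
  invisible(x)
}
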