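# Multi-marker phenotyping: pairwise colocalization ROIs with the
# 20-200 px area filter, subtype calling (GC-B, T_FH, T_FK, Treg-like),
# and intensity-profile confirmation of killer-T_FH candidates.

#' Pairwise colocalization ROIs of two signal masks
#'
#' Connected components of the pixelwise AND of two binary marker masks
#' are candidate double-positive cells. Components with area outside
#' `[min_area_px, max_area_px]` (inclusive; ROIs strictly larger than
#' 200 px or strictly smaller than 20 px are discarded under the
#' defaults) are marked `retained = FALSE` with a reason; all ROIs are
#' returned.
#'
#' @param mask_a,mask_b `signal_mask` objects (or logical matrices) of
#'   identical shape.
#' @param min_area_px,max_area_px inclusive area window in pixels.
#' @param connectivity 4 or 8.
#' @return A `pheno_rois` object: `rois` data frame (`roi_id`,
#'   `area_px`, `centroid_r`, `centroid_c`, `retained`,
#'   `discard_reason`), `pixels` (list of linear indices per ROI, in
#'   `roi_id` order), `marker_set`, `labels`, `shape`.
#' @export
colocalize <- function(mask_a, mask_b, min_area_px = 20, max_area_px = 200,
                       connectivity = 8) {
  ch_a <- if (inherits(mask_a, "signal_mask")) mask_a$channel else "A"
  ch_b <- if (inherits(mask_b, "signal_mask")) mask_b$channel else "B"
  ma <- if (inherits(mask_a, "signal_mask")) mask_a$mask else mask_a != 0
  mb <- if (inherits(mask_b, "signal_mask")) mask_b$mask else mask_b != 0
  if (!identical(dim(ma), dim(mb)))
    stop("mask shapes differ: ", paste(dim(ma), collapse = "x"), " vs ",
         paste(dim(mb), collapse = "x"))
  both <- ma & mb
  L <- label_components(both, connectivity)
  n <- max(L)
  if (n == 0) {
    rois <- data.frame(roi_id = integer(), area_px = integer(),
                       centroid_r = numeric(), centroid_c = numeric(),
                       retained = logical(), discard_reason = character())
    return(structure(list(rois = rois, pixels = list(),
                          marker_set = c(ch_a, ch_b), labels = L,
                          shape = dim(ma)),
                     class = "pheno_rois"))
  }
  idx <- which(L > 0)
  lab <- L[idx]
  area <- tabulate(lab, nbins = n)
  rows <- (idx - 1L) %% nrow(ma) + 1L
  cols <- (idx - 1L) %/% nrow(ma) + 1L
  retained <- area >= min_area_px & area <= max_area_px
  reason <- rep(NA_character_, n)
  reason[area < min_area_px] <- "too_small"
  reason[area > max_area_px] <- "too_large"
  rois <- data.frame(roi_id = seq_len(n), area_px = area,
                     centroid_r = as.numeric(rowsum(rows, lab)) / area,
                     centroid_c = as.numeric(rowsum(cols, lab)) / area,
                     retained = retained, discard_reason = reason)
  pix <- split(idx, lab)
  names(pix) <- NULL
  structure(list(rois = rois, pixels = pix, marker_set = c(ch_a, ch_b),
                 labels = L, shape = dim(ma)),
            class = "pheno_rois")
}

#' @export
print.pheno_rois <- function(x, ...) {
  cat(sprintf("<pheno_rois> %s: %d ROIs (%d retained)\n",
              paste(x$marker_set, collapse = " & "), nrow(x$rois),
              sum(x$rois$retained)))
  invisible(x)
}

panel_required <- list(
  localization = c("CD19", "CD4", "BCL6", "TIA1"),
  treg_contact = c("FOXP3", "CD4", "BCL6", "TIA1"))

# fraction of a pixel set positive in a mask
mask_fraction <- function(pixels, mask) {
  vapply(pixels, function(p) mean(mask[p]), numeric(1))
}

#' Call cell subtypes from a marker panel
#'
#' Germinal-center B cells are retained CD19+BCL6+ colocalization ROIs.
#' CD4+BCL6+ ROIs are split by TIA-1 co-occurrence: a ROI is a killer
#' T-follicular cell (T_FK) when at least `tia1_overlap_frac` of its
#' pixels are TIA-1 positive, else a T-follicular helper (T_FH); so
#' T_FH + T_FK counts always sum to the retained CD4+BCL6+ ROI count.
#' In the `treg_contact` panel (FOXP3 replaces CD19), CD4+BCL6+ ROIs
#' with at least `foxp3_exclude_frac` FOXP3-positive pixels are
#' T_FR-like regulatory cells: they are excluded from the T_FH/T_FK
#' split and reported as subtype `"T_FR"`.
#'
#' @param panel named list of `signal_mask` objects covering the
#'   channels the panel kind requires (`localization`: CD19, CD4, BCL6,
#'   TIA1; `treg_contact`: FOXP3, CD4, BCL6, TIA1).
#' @param panel_kind `"localization"` or `"treg_contact"`.
#' @param tia1_overlap_frac minimum TIA-1-positive pixel fraction for a
#'   CD4+BCL6+ ROI to be called T_FK (inclusive).
#' @param foxp3_exclude_frac minimum FOXP3-positive fraction that
#'   reroutes a CD4+BCL6+ ROI to `"T_FR"` (treg_contact panel only).
#' @param min_area_px,max_area_px area window passed to [colocalize()].
#' @param connectivity 4 or 8.
#' @return A `subtype_calls` object: `calls` data frame (`cell_id`,
#'   `subtype`, `centroid_r`, `centroid_c`, `area_px`, `tia1_frac`,
#'   `roi_id`, `marker_pair`), `pixels` (per call), `panel_kind`, and
#'   the underlying `pheno_rois` in `evidence`.
#' @export
call_subtypes <- function(panel,
                          panel_kind = c("localization", "treg_contact"),
                          tia1_overlap_frac = 0.5,
                          foxp3_exclude_frac = 0.25,
                          min_area_px = 20, max_area_px = 200,
                          connectivity = 8) {
  panel_kind <- match.arg(panel_kind)
  req <- panel_required[[panel_kind]]
  missing <- setdiff(req, names(panel))
  if (length(missing))
    stop("panel is missing required channel(s): ",
         paste(missing, collapse = ", "))
  get_mask <- function(ch) {
    m <- panel[[ch]]
    if (inherits(m, "signal_mask")) m$mask else m != 0
  }
  evidence <- list()
  calls <- data.frame(cell_id = integer(), subtype = character(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      area_px = integer(), tia1_frac = numeric(),
                      roi_id = integer(), marker_pair = character())
  pixels <- list()
  add_calls <- function(rois, keep_idx, subtype, tia1_frac, pair) {
    if (!length(keep_idx)) return()
    k <- nrow(calls)
    sel <- rois$rois[keep_idx, ]
    calls <<- rbind(calls, data.frame(
      cell_id = k + seq_along(keep_idx), subtype = subtype,
      centroid_r = sel$centroid_r, centroid_c = sel$centroid_c,
      area_px = sel$area_px, tia1_frac = tia1_frac,
      roi_id = sel$roi_id, marker_pair = pair))
    pixels[(k + 1):(k + length(keep_idx))] <<- rois$pixels[keep_idx]
  }

  if (panel_kind == "localization") {
    gcb <- colocalize(panel[["CD19"]], panel[["BCL6"]],
                      min_area_px, max_area_px, connectivity)
    evidence$CD19_BCL6 <- gcb
    add_calls(gcb, which(gcb$rois$retained), "GC-B", NA_real_, "CD19&BCL6")
  }
  tcell <- colocalize(panel[["CD4"]], panel[["BCL6"]],
                      min_area_px, max_area_px, connectivity)
  evidence$CD4_BCL6 <- tcell
  ret <- which(tcell$rois$retained)
  tia1 <- get_mask("TIA1")
  frac <- mask_fraction(tcell$pixels[ret], tia1)
  if (panel_kind == "treg_contact" && length(ret)) {
    foxp3 <- get_mask("FOXP3")
    ffrac <- mask_fraction(tcell$pixels[ret], foxp3)
    tfr <- ffrac >= foxp3_exclude_frac
    add_calls(tcell, ret[tfr], "T_FR", frac[tfr], "CD4&BCL6")
    ret <- ret[!tfr]
    frac <- frac[!tfr]
  }
  is_tfk <- frac >= tia1_overlap_frac
  add_calls(tcell, ret[!is_tfk], "T_FH", frac[!is_tfk], "CD4&BCL6")
  add_calls(tcell, ret[is_tfk], "T_FK", frac[is_tfk], "CD4&BCL6")

  calls$cell_id <- seq_len(nrow(calls))
  structure(list(calls = calls, pixels = pixels, panel_kind = panel_kind,
                 evidence = evidence,
                 params = list(tia1_overlap_frac = tia1_overlap_frac,
                               foxp3_exclude_frac = foxp3_exclude_frac,
                               min_area_px = min_area_px,
                               max_area_px = max_area_px)),
            class = "subtype_calls")
}

#' @export
print.subtype_calls <- function(x, ...) {
  tab <- table(x$calls$subtype)
  cat(sprintf("<subtype_calls> [%s] %s\n", x$panel_kind,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Confirm a T_FK candidate with an intensity profile
#'
#' Samples every channel along a horizontal line of half-length
#' `half_length_px` through the candidate's centroid (clipped at image
#' borders). The candidate passes when each required channel (CD4,
#' BCL6, TIA1) attains its line maximum inside the candidate's pixel
#' span and that maximum exceeds the channel threshold, while CD19
#' (when present in the image) does not peak above its threshold inside
#' the span.
#'
#' @param img the [mc_image] the calls were made on.
#' @param calls a `subtype_calls` object.
#' @param cell_id id of a T_FK call within `calls`.
#' @param thresholds named numeric vector of per-channel thresholds
#'   (typically the recorded `threshold_value`s of the signal masks).
#' @param half_length_px line half-length in pixels.
#' @return An `intensity_profile`: `candidate_id`, `row`, `cols`,
#'   `values` (channel x position matrix), `span` (column range of the
#'   candidate pixels), `passed`.
#' @export
profile_candidate <- function(img, calls, cell_id, thresholds,
                              half_length_px = 15) {
  row <- calls$calls[calls$calls$cell_id == cell_id, ]
  if (nrow(row) != 1) stop("cell_id not found: ", cell_id)
  if (row$subtype != "T_FK")
    stop("profile confirmation applies to T_FK candidates; got ", row$subtype)
  shape <- image_shape(img)
  pr <- max(1L, min(shape[1], round(row$centroid_r)))
  c0 <- max(1L, round(row$centroid_c) - round(half_length_px))
  c1 <- min(shape[2], round(row$centroid_c) + round(half_length_px))
  cols <- c0:c1
  values <- do.call(rbind, lapply(img$channels, function(m) m[pr, cols]))
  rownames(values) <- names(img$channels)
  pix <- calls$pixels[[which(calls$calls$cell_id == cell_id)]]
  pcols <- (pix - 1L) %/% shape[1] + 1L
  span <- range(pcols)
  in_span <- cols >= span[1] & cols <= span[2]
  required <- c("CD4", "BCL6", "TIA1")
  required <- required[required %in% rownames(values)]
  passed <- all(vapply(required, function(ch) {
    v <- values[ch, ]
    any(in_span) &&
      max(v[in_span]) >= max(v) &&
      max(v[in_span]) > thresholds[[ch]]
  }, logical(1)))
  if (passed && "CD19" %in% rownames(values) && "CD19" %in% names(thresholds)) {
    v <- values["CD19", ]
    if (any(in_span) && max(v[in_span]) > thresholds[["CD19"]])
      passed <- FALSE
  }
  structure(list(candidate_id = cell_id, row = pr, cols = cols,
                 values = values, span = span, passed = passed),
            class = "intensity_profile")
}
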