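# End-to-end analysis of one acquisition: preprocessing, per-channel
# masks, subtype calls, compartment allocation, Treg/contact analysis
# and the per-sample summary row.

#' Analyse one multi-channel image
#'
#' Runs the full quantification chain: background correction (and
#' optional Richardson-Lucy deconvolution), per-channel Otsu masks,
#' colocalization subtype calling with the 20-200 px area filter,
#' intensity-profile confirmation of T_FK candidates, follicle/GC
#' allocation and morphometry, and -- when a FOXP3 channel is present --
#' Treg identification with T_FK contact detection.
#'
#' @param img an [mc_image] containing at least CD4, BCL6 and TIA1
#'   channels, plus CD19 and/or FOXP3.
#' @param regions optional `region_set` (e.g. imported manual ROIs or
#'   the generator's ground-truth regions); when `NULL`, regions are
#'   proposed with [auto_regions()] (requires a CD19 channel).
#' @param background_radius_px rolling-ball radius; `0` skips
#'   background correction.
#' @param smooth_sigma Gaussian denoising sigma (pixels) applied to all
#'   channels after background correction and before thresholding;
#'   `0` disables. Suppresses shot-noise specks that would otherwise
#'   survive the area filter.
#' @param run_deconvolution apply Richardson-Lucy after background
#'   correction.
#' @param psf_sigma_px,iterations deconvolution parameters.
#' @param min_area_px,max_area_px colocalization ROI area window.
#' @param tia1_overlap_frac T_FH/T_FK split threshold.
#' @param treg_overlap_frac FOXP3 overlap threshold for Tregs.
#' @param max_gap_px contact gap tolerance in pixels.
#' @param confirm_profiles run [profile_candidate()] on every T_FK
#'   call and record the result.
#' @param sample_id,group_label metadata for the summary row
#'   (defaulting to the image's own).
#' @return An `image_analysis` list: `masks`, `calls`, `b_cells`
#'   (CD19+BCL6- detection), `regions`, `locations`, `morphometry`,
#'   `tregs`, `contacts`, `summary`.
#' @export
analyze_image <- function(img, regions = NULL,
                          background_radius_px = 50,
                          smooth_sigma = 1,
                          run_deconvolution = FALSE,
                          psf_sigma_px = 2, iterations = 10,
                          min_area_px = 20, max_area_px = 200,
                          tia1_overlap_frac = 0.5,
                          treg_overlap_frac = 0.25,
                          max_gap_px = 1,
                          confirm_profiles = TRUE,
                          sample_id = img$sample_id,
                          group_label = img$group_label) {
  steps <- character(0)
  if (background_radius_px > 0) steps <- c(steps, "background")
  if (run_deconvolution) steps <- c(steps, "deconvolve")
  if (length(steps))
    img <- preprocess(img, steps, background_radius_px, psf_sigma_px, iterations)
  if (smooth_sigma > 0) {
    k <- gaussian_kernel(smooth_sigma)
    img$channels <- lapply(img$channels, function(m)
      EBImage::filter2(m, k, boundary = "replicate"))
  }

  chans <- intersect(PANEL_CHANNELS, names(img$channels))
  masks <- lapply(chans, function(ch) threshold_channel(img, ch))
  names(masks) <- chans

  panel_kind <- if ("CD19" %in% chans) "localization" else "treg_contact"
  calls <- call_subtypes(masks, panel_kind,
                         tia1_overlap_frac = tia1_overlap_frac,
                         min_area_px = min_area_px, max_area_px = max_area_px)

  thresholds <- vapply(masks, `[[`, numeric(1), "threshold_value")
  if (confirm_profiles && nrow(calls$calls)) {
    passed <- rep(NA, nrow(calls$calls))
    for (i in which(calls$calls$subtype == "T_FK")) {
      prof <- profile_candidate(img, calls, calls$calls$cell_id[i], thresholds)
      passed[i] <- prof$passed
    }
    calls$calls$profile_passed <- passed
  }

  b_cells <- NULL
  n_b <- NA_integer_
  if ("CD19" %in% chans) {
    cd19_cells <- detect_cells(masks$CD19, min_area_px, max_area_px, img = img)
    bcl6_frac <- if (length(cd19_cells$pixels))
      mask_fraction(cd19_cells$pixels, masks$BCL6$mask) else numeric(0)
    keep <- which(bcl6_frac < 0.5)  # single-positive B (CD19+BCL6-)
    b_cells <- cd19_cells
    b_cells$cells <- cd19_cells$cells[keep, , drop = FALSE]
    b_cells$pixels <- cd19_cells$pixels[keep]
    n_b <- length(keep)
  }

  if (is.null(regions)) {
    if (!"CD19" %in% chans)
      stop("no regions given and no CD19 channel for auto_regions()")
    regions <- auto_regions(masks$CD19, masks$BCL6,
                            pixel_size = img$pixel_size)
  }
  locations <- assign_cells(calls, regions)
  morphometry <- measure_regions(regions)

  tregs <- NULL; contacts <- NULL
  if ("FOXP3" %in% chans) {
    cd4_cells <- detect_cells(masks$CD4, min_area_px, max_area_px)
    tregs <- identify_tregs(cd4_cells, masks$FOXP3, treg_overlap_frac)
    contacts <- detect_contacts(calls, tregs, max_gap_px)
  }

  summary <- summarize_sample(calls, locations, morphometry, contacts,
                              sample_id = sample_id,
                              group_label = group_label, n_b = n_b)
  structure(list(masks = masks, calls = calls, b_cells = b_cells,
                 regions = regions, locations = locations,
                 morphometry = morphometry, tregs = tregs,
                 contacts = contacts, summary = summary),
            class = "image_analysis")
}

#' @export
print.image_analysis <- function(x, ...) {
  print(x$calls)
  print(x$summary[, c("sample_id", "n_gcb", "n_tfh", "n_tfk",
                      "pct_tfk_of_tfh", "pct_tfk_in_gcs")])
  invisible(x)
}

#' Simulate and analyse one synthetic sample, writing CSV outputs
#'
#' Deterministic end-to-end run: [simulate_tissue()] under the config's
#' seed, [analyze_image()] (using the generator's true regions by
#' default, mirroring the manual-ROI procedure), and CSV export of
#' calls, locations, contact pairs, region morphometry and the sample
#' summary. Identical config + seed give byte-identical CSV files.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory for `calls.csv`, `locations.csv`,
#'   `contacts.csv`, `regions.csv`, `summary.csv` (created if absent);
#'   `NULL` skips writing.
#' @param region_source `"truth"` (generator regions) or `"auto"`
#'   ([auto_regions()] from the CD19/BCL6 masks).
#' @param ... further arguments to [analyze_image()].
#' @return The `image_analysis`, with the `synth_tissue` attached as
#'   `$tissue`.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                         region_source = c("truth", "auto"), ...) {
  region_source <- match.arg(region_source)
  tissue <- simulate_tissue(config)
  regions <- if (region_source == "truth") tissue$regions else NULL
  res <- analyze_image(tissue$image, regions = regions, ...)
  res$tissue <- tissue
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
    wr(res$calls$calls, "calls.csv")
    wr(res$locations, "locations.csv")
    if (!is.null(res$contacts)) wr(res$contacts$pairs, "contacts.csv")
    wr(rbind(
      data.frame(region = "follicle", id = res$regions$follicles$follicle_id,
                 parent = NA_integer_, area_px = res$regions$follicles$area_px),
      data.frame(region = "gc", id = res$regions$gcs$gc_id,
                 parent = res$regions$gcs$parent_follicle_id,
                 area_px = res$regions$gcs$area_px)), "regions.csv")
    wr(res$summary, "summary.csv")
  }
  res
}
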