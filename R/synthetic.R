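# Synthetic lymphoid tissue: follicles with nested germinal centers,
# marker-specific cell blobs, PSF blur, background gradient and noise,
# with a complete ground-truth table. The generator exists so every
# downstream stage (segmentation, phenotyping, allocation, contacts)
# can be validated against known truth.

CELL_TYPES <- c("B", "GC-B", "T_FH", "T_FK", "Treg", "other")
PANEL_CHANNELS <- c("CD19", "CD4", "BCL6", "TIA1", "FOXP3")

#' Default per-type channel amplitudes of the synthetic renderer
#'
#' B cells are CD19+; GC-B add BCL6; T_FH are CD4+BCL6+; T_FK add
#' TIA-1; Tregs are CD4+FOXP3+; bystander cells carry CD4 only.
#'
#' @return Named list: cell type -> named amplitude vector.
#' @export
default_marker_intensity <- function() {
  list(
    "B"     = c(CD19 = 1),
    "GC-B"  = c(CD19 = 1, BCL6 = 1),
    "T_FH"  = c(CD4 = 1, BCL6 = 1),
    "T_FK"  = c(CD4 = 1, BCL6 = 1, TIA1 = 1),
    "Treg"  = c(CD4 = 1, FOXP3 = 1),
    "other" = c(CD4 = 1))
}

#' Default compartment placement probabilities of the generator
#'
#' @return Matrix (cell type x `GC`, `follicle`, `extrafollicular`),
#'   rows summing to 1.
#' @export
default_placement_probs <- function() {
  # rows: cell type; columns: GC, follicle (non-GC), extrafollicular.
  # GC-B are germinal-center resident by definition; mantle B cells stay
  # follicular; helper/killer T_FH home to GCs; Tregs and bystanders are
  # mostly interfollicular.
  p <- rbind(
    "B"     = c(0.00, 0.70, 0.30),
    "GC-B"  = c(1.00, 0.00, 0.00),
    "T_FH"  = c(0.80, 0.15, 0.05),
    "T_FK"  = c(0.50, 0.30, 0.20),
    "Treg"  = c(0.10, 0.30, 0.60),
    "other" = c(0.05, 0.25, 0.70))
  colnames(p) <- c("GC", "follicle", "extrafollicular")
  p
}

#' Configuration of the synthetic tissue generator
#'
#' Defaults describe one 1024x1024 px field of a secondary lymphoid
#' tissue section at 0.5 um/px: a few round-ish follicles whose germinal
#' centers occupy half the follicle radius, a mixed population of B,
#' GC-B, T_FH, T_FK, Treg and bystander cells rendered as ~4 px radius
#' marker blobs, a mild low-frequency background and a 1.5 px Gaussian
#' PSF.
#'
#' @param image_shape image size `c(nrow, ncol)` in pixels.
#' @param pixel_size micrometers per pixel.
#' @param n_follicles number of follicles to place.
#' @param gc_fraction fraction of each follicle radius occupied by its
#'   GC, strictly inside (0, 1).
#' @param follicle_radius_px `c(mean, sd)` of the follicle major
#'   semi-axis in pixels; minor axis ratio drawn from `axis_ratio_range`.
#' @param axis_ratio_range range of minor/major axis ratio.
#' @param cell_counts named counts per cell type
#'   (`B, GC-B, T_FH, T_FK, Treg, other`), all `>= 0`.
#' @param region_placement_probs matrix (cell type x
#'   `GC, follicle, extrafollicular`) of placement probabilities, each
#'   row summing to 1.
#' @param cell_radius_px `c(mean, sd)` of cell radius in pixels.
#' @param marker_intensity named list mapping cell type to a named
#'   vector of per-channel blob amplitudes.
#' @param noise_sd additive Gaussian noise standard deviation
#'   (intensity units; blob amplitude defaults to 1).
#' @param background_amplitude peak amplitude of the low-frequency
#'   background gradient.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels
#'   (`>= 0`; 0 disables blur).
#' @param planted_contact_pairs number of T_FK--Treg pairs placed with
#'   touching boundaries (center distance equal to the radius sum).
#' @param separation_px extra clearance, beyond the radius sum, enforced
#'   between non-contact cells so that blurred blobs stay separable.
#' @param allow_overlap disable the non-overlap constraint (stress
#'   tests only).
#' @param seed RNG seed used by [simulate_tissue()].
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(image_shape = c(1024L, 1024L),
                         pixel_size = 0.5,
                         n_follicles = 3L,
                         gc_fraction = 0.6,
                         follicle_radius_px = c(mean = 140, sd = 10),
                         axis_ratio_range = c(0.7, 1.0),
                         cell_counts = c("B" = 90, "GC-B" = 60, "T_FH" = 60,
                                         "T_FK" = 20, "Treg" = 40, "other" = 30),
                         region_placement_probs = default_placement_probs(),
                         cell_radius_px = c(mean = 4, sd = 0.5),
                         marker_intensity = default_marker_intensity(),
                         noise_sd = 0,
                         background_amplitude = 0.1,
                         psf_sigma_px = 1.5,
                         planted_contact_pairs = 0L,
                         separation_px = 6,
                         allow_overlap = FALSE,
                         seed = 1L) {
  counts <- setNames(rep(0, length(CELL_TYPES)), CELL_TYPES)
  counts[names(cell_counts)] <- cell_counts
  if (any(counts < 0)) stop("cell counts must be >= 0")
  if (!(gc_fraction > 0 && gc_fraction < 1))
    stop("'gc_fraction' must lie in (0, 1)")
  if (psf_sigma_px < 0) stop("'psf_sigma_px' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (n_follicles < 0) stop("'n_follicles' must be >= 0")
  p <- region_placement_probs
  if (!all(CELL_TYPES %in% rownames(p)))
    stop("placement probabilities must cover all cell types")
  if (any(abs(rowSums(p[CELL_TYPES, , drop = FALSE]) - 1) > 1e-9))
    stop("placement probabilities must sum to 1 per cell type")
  if (planted_contact_pairs > min(counts["T_FK"], counts["Treg"]))
    stop("'planted_contact_pairs' exceeds available T_FK or Treg counts")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 n_follicles = as.integer(n_follicles),
                 gc_fraction = gc_fraction,
                 follicle_radius_px = follicle_radius_px,
                 axis_ratio_range = axis_ratio_range,
                 cell_counts = counts,
                 region_placement_probs = p,
                 cell_radius_px = cell_radius_px,
                 marker_intensity = marker_intensity,
                 noise_sd = noise_sd,
                 background_amplitude = background_amplitude,
                 psf_sigma_px = psf_sigma_px,
                 planted_contact_pairs = as.integer(planted_contact_pairs),
                 separation_px = separation_px,
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Place non-overlapping follicles with nested germinal centers
#'
#' Samples `n_follicles` ellipses (axis ratio in `axis_ratio_range`,
#' random orientation) fully inside the image, pairwise disjoint, each
#' with a concentric GC ellipse scaled by `gc_fraction`. Consumes the
#' global RNG stream; seed via [simulate_tissue()] or `set.seed()`.
#'
#' @param config a [synth_config()].
#' @param max_tries placement attempts per follicle before giving up.
#' @param max_restarts whole-configuration restarts after a dead-end
#'   partial placement.
#' @return A `region_set` with one GC per follicle.
#' @export
place_regions <- function(config, max_tries = 500L, max_restarts = 10L) {
  shape <- config$image_shape
  n <- config$n_follicles
  for (restart in seq_len(max_restarts)) {
    res <- try(place_regions_once(config, max_tries), silent = TRUE)
    if (!inherits(res, "try-error")) return(res)
  }
  stop(sprintf("capacity error: could not place %d follicles in a %dx%d image after %d restarts",
               n, shape[1], shape[2], max_restarts))
}

place_regions_once <- function(config, max_tries) {
  shape <- config$image_shape
  n <- config$n_follicles
  fols <- vector("list", n)
  gcs <- vector("list", n)
  placed <- matrix(numeric(0), 0, 3)  # cr, cc, major semi-axis
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      a <- max(20, rnorm(1, config$follicle_radius_px[["mean"]],
                         config$follicle_radius_px[["sd"]]))
      b <- a * runif(1, config$axis_ratio_range[1], config$axis_ratio_range[2])
      theta <- runif(1, 0, 2 * pi)
      margin <- a + 3
      if (2 * margin >= shape[1] || 2 * margin >= shape[2]) next
      cr <- runif(1, margin, shape[1] - margin)
      cc <- runif(1, margin, shape[2] - margin)
      # conservative disjointness: bounding circles separated
      if (nrow(placed) > 0) {
        d <- sqrt((placed[, 1] - cr)^2 + (placed[, 2] - cc)^2)
        if (any(d < placed[, 3] + a + 4)) next
      }
      fols[[i]] <- ellipse_geom(cr, cc, a, b, theta)
      gcs[[i]] <- ellipse_geom(cr, cc, a * config$gc_fraction,
                               b * config$gc_fraction, theta)
      placed <- rbind(placed, c(cr, cc, a))
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("placement dead-end at follicle %d of %d", i, n))
  }
  region_set(fols, gcs, gc_parent = seq_len(n), shape = shape,
             pixel_size = config$pixel_size, source = "auto")
}

# sample one centroid in the requested compartment; mask lookup at the
# rounded centroid must agree so that true_region labels are exactly
# reproducible from the rasterized regions
sample_centroid <- function(compartment, regions, shape, radius, max_tries = 2000L) {
  fl <- regions$follicle_labels
  gl <- regions$gc_labels
  fgeoms <- regions$geoms$follicles
  ggeoms <- regions$geoms$gcs
  edge <- radius + 3
  for (t in seq_len(max_tries)) {
    if (compartment == "GC") {
      if (length(ggeoms) == 0) stop("capacity error: no GC to place cell in")
      k <- sample.int(length(ggeoms), 1)
      g <- ggeoms[[k]]
      cr <- runif(1, g$cr - g$a, g$cr + g$a)
      cc <- runif(1, g$cc - g$a, g$cc + g$a)
      if (ellipse_qform(g, cr, cc) > 0.92) next
      ri <- round(cr); ci <- round(cc)
      if (gl[ri, ci] != k) next
    } else if (compartment == "follicle") {
      if (length(fgeoms) == 0) stop("capacity error: no follicle to place cell in")
      k <- sample.int(length(fgeoms), 1)
      f <- fgeoms[[k]]; g <- ggeoms[[k]]
      cr <- runif(1, f$cr - f$a, f$cr + f$a)
      cc <- runif(1, f$cc - f$a, f$cc + f$a)
      if (ellipse_qform(f, cr, cc) > 0.92) next
      if (ellipse_qform(g, cr, cc) < 1.15) next
      ri <- round(cr); ci <- round(cc)
      if (fl[ri, ci] != k || gl[ri, ci] != 0) next
    } else {  # extrafollicular
      cr <- runif(1, edge, shape[1] - edge)
      cc <- runif(1, edge, shape[2] - edge)
      ri <- round(cr); ci <- round(cc)
      if (fl[ri, ci] != 0) next
      near <- vapply(fgeoms, function(f) ellipse_qform(f, cr, cc) < 1.1,
                     logical(1))
      if (any(near)) next
    }
    if (cr < edge || cr > shape[1] - edge || cc < edge || cc > shape[2] - edge)
      next
    return(c(cr, cc, k = if (compartment == "extrafollicular") NA_integer_ else k))
  }
  stop(sprintf("capacity error: could not place a cell in compartment '%s'",
               compartment))
}

compartment_of <- function(regions, cr, cc) {
  ri <- round(cr); ci <- round(cc)
  g <- regions$gc_labels[ri, ci]
  if (g != 0) return(list(region = "GC", follicle = regions$gcs$parent_follicle_id[g]))
  f <- regions$follicle_labels[ri, ci]
  if (f != 0) return(list(region = "follicle", follicle = f))
  list(region = "extrafollicular", follicle = NA_integer_)
}

#' Place cells with known phenotype, compartment and contacts
#'
#' Draws each cell's compartment from the per-type placement
#' probabilities, samples a centroid inside that compartment, and
#' enforces a minimum center distance of `r_i + r_j + separation_px`
#' between distinct cells. `planted_contact_pairs` T_FK--Treg pairs are
#' instead placed with exactly touching boundaries (center distance
#' equal to the radius sum). Consumes the global RNG stream.
#'
#' @param config a [synth_config()].
#' @param regions the `region_set` from [place_regions()].
#' @return A `ground_truth` object: `cells` (data frame with `cell_id`,
#'   `type`, `centroid_r`, `centroid_c`, `radius_px`, `true_region`,
#'   `follicle_id`), `regions`, and `contacts` (`tfk_id`, `treg_id`).
#' @export
place_cells <- function(config, regions) {
  shape <- config$image_shape
  counts <- config$cell_counts
  probs <- config$region_placement_probs
  sep <- if (config$allow_overlap) -Inf else config$separation_px
  cells <- data.frame(cell_id = integer(), type = character(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      radius_px = numeric(), true_region = character(),
                      follicle_id = integer())
  pos <- matrix(numeric(0), 0, 3)  # cr, cc, radius
  contacts <- data.frame(tfk_id = integer(), treg_id = integer())
  next_id <- 1L

  too_close <- function(cr, cc, radius, skip = integer()) {
    if (nrow(pos) == 0) return(FALSE)
    d2 <- (pos[, 1] - cr)^2 + (pos[, 2] - cc)^2
    lim <- (pos[, 3] + radius + sep)^2
    keep <- setdiff(seq_len(nrow(pos)), skip)
    any(d2[keep] < lim[keep])
  }
  # truncate to the measurable window: disks must stay inside the
  # 20-200 px area filter after PSF blur and thresholding
  draw_radius <- function()
    min(5.5, max(3.2, rnorm(1, config$cell_radius_px[["mean"]],
                            config$cell_radius_px[["sd"]])))
  add_cell <- function(type, cr, cc, radius) {
    comp <- compartment_of(regions, cr, cc)
    cells[nrow(cells) + 1L, ] <<- list(next_id, type, cr, cc, radius,
                                       comp$region, comp$follicle)
    pos <<- rbind(pos, c(cr, cc, radius))
    id <- next_id
    next_id <<- next_id + 1L
    id
  }
  place_one <- function(type, max_tries = 1500L) {
    radius <- draw_radius()
    compartment <- sample(colnames(probs), 1, prob = probs[type, ])
    for (t in seq_len(max_tries)) {
      p <- sample_centroid(compartment, regions, shape, radius)
      if (!too_close(p[1], p[2], radius)) return(add_cell(type, p[1], p[2], radius))
    }
    stop(sprintf("capacity error: could not place %s cell without overlap", type))
  }

  # contact pairs first: a T_FK placed normally, its Treg partner at
  # touching distance
  n_pairs <- config$planted_contact_pairs
  for (k in seq_len(n_pairs)) {
    placed <- FALSE
    for (t in seq_len(300L)) {
      r1 <- draw_radius()
      compartment <- sample(colnames(probs), 1, prob = probs["T_FK", ])
      p <- try(sample_centroid(compartment, regions, shape, r1), silent = TRUE)
      if (inherits(p, "try-error")) next
      if (too_close(p[1], p[2], r1)) next
      r2 <- draw_radius()
      phi <- runif(36, 0, 2 * pi)
      for (a in phi) {
        cr2 <- p[1] + (r1 + r2) * sin(a)
        cc2 <- p[2] + (r1 + r2) * cos(a)
        edge <- r2 + 3
        if (cr2 < edge || cr2 > shape[1] - edge ||
            cc2 < edge || cc2 > shape[2] - edge) next
        if (too_close(cr2, cc2, r2)) next
        tfk <- add_cell("T_FK", p[1], p[2], r1)
        treg <- add_cell("Treg", cr2, cc2, r2)
        contacts[nrow(contacts) + 1L, ] <- list(tfk, treg)
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed)
      stop("capacity error: could not place a touching T_FK-Treg pair")
  }

  remaining <- counts
  remaining["T_FK"] <- remaining["T_FK"] - n_pairs
  remaining["Treg"] <- remaining["Treg"] - n_pairs
  for (type in CELL_TYPES) {
    for (i in seq_len(remaining[[type]])) place_one(type)
  }
  structure(list(cells = cells, regions = regions, contacts = contacts),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(factor(x$cells$type, levels = CELL_TYPES))
  cat("<ground_truth>", nrow(x$cells), "cells (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "),",
      nrow(x$contacts), "planted contact pairs\n")
  invisible(x)
}

#' Render a ground truth into a multi-channel image
#'
#' Forward model: each cell adds a hard disk of its type's amplitude to
#' every channel where its marker map is positive; each channel is then
#' convolved with a normalized Gaussian PSF, a low-frequency background
#' ramp is added, and Gaussian noise (sd `noise_sd`) is applied with
#' clipping at zero. Consumes the global RNG stream (noise only).
#'
#' @param truth a `ground_truth` from [place_cells()].
#' @param config the [synth_config()] used to generate it.
#' @return An [mc_image] with channels `CD19, CD4, BCL6, TIA1, FOXP3`.
#' @export
render_image <- function(truth, config) {
  shape <- config$image_shape
  unknown <- setdiff(unique(truth$cells$type), names(config$marker_intensity))
  if (length(unknown))
    stop("unknown cell type(s) in truth: ", paste(unknown, collapse = ", "))
  chans <- lapply(PANEL_CHANNELS, function(ch) matrix(0, shape[1], shape[2]))
  names(chans) <- PANEL_CHANNELS
  for (i in seq_len(nrow(truth$cells))) {
    cell <- truth$cells[i, ]
    amp <- config$marker_intensity[[cell$type]]
    amp <- amp[amp > 0]
    if (!length(amp)) next
    R <- ceiling(cell$radius_px)
    rr <- max(1L, floor(cell$centroid_r - R)):min(shape[1], ceiling(cell$centroid_r + R))
    cc <- max(1L, floor(cell$centroid_c - R)):min(shape[2], ceiling(cell$centroid_c + R))
    d2 <- outer((rr - cell$centroid_r)^2, (cc - cell$centroid_c)^2, "+")
    disk <- d2 <= cell$radius_px^2
    for (ch in names(amp)) {
      block <- chans[[ch]][rr, cc]
      chans[[ch]][rr, cc] <- block + amp[[ch]] * disk
    }
  }
  if (config$psf_sigma_px > 0) {
    psf <- gaussian_kernel(config$psf_sigma_px)
    chans <- lapply(chans, function(m)
      EBImage::filter2(m, psf, boundary = "replicate"))
  }
  if (config$background_amplitude > 0) {
    ramp <- config$background_amplitude *
      outer(seq(0, 1, length.out = shape[1]),
            seq(0, 1, length.out = shape[2]), function(a, b) (a + b) / 2)
    chans <- lapply(chans, function(m) m + ramp)
  }
  if (config$noise_sd > 0) {
    chans <- lapply(chans, function(m)
      m + matrix(rnorm(length(m), 0, config$noise_sd), nrow(m), ncol(m)))
  }
  chans <- lapply(chans, function(m) pmax(m, 0))
  mc_image(chans, pixel_size = config$pixel_size,
           sample_id = "synthetic", group_label = "other",
           provenance = "tfkscope synthetic tissue")
}

#' Generate one complete synthetic sample
#'
#' Seeds the RNG from `config$seed` and runs [place_regions()],
#' [place_cells()] and [render_image()]. Identical configs (including
#' seed) give bit-identical output.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_tissue`: `image` ([mc_image]),
#'   `truth` (`ground_truth`), `regions` (`region_set`), `config`.
#' @export
simulate_tissue <- function(config = synth_config()) {
  set.seed(config$seed)
  regions <- place_regions(config)
  truth <- place_cells(config, regions)
  image <- render_image(truth, config)
  structure(list(image = image, truth = truth, regions = regions,
                 config = config),
            class = "synth_tissue")
}

#' Write ground truth tables and image to disk
#'
#' Writes `cells.csv`, `regions.csv`, `contacts.csv` and
#' `image.tif` (multi-page 16-bit TIFF) into `dir`.
#'
#' @param tissue a `synth_tissue` from [simulate_tissue()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tissue <- function(tissue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tissue$truth$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  regs <- rbind(
    data.frame(region = "follicle", id = tissue$regions$follicles$follicle_id,
               parent = NA_integer_, area_px = tissue$regions$follicles$area_px),
    data.frame(region = "gc", id = tissue$regions$gcs$gc_id,
               parent = tissue$regions$gcs$parent_follicle_id,
               area_px = tissue$regions$gcs$area_px))
  write.csv(regs, file.path(dir, "regions.csv"), row.names = FALSE)
  write.csv(tissue$truth$contacts, file.path(dir, "contacts.csv"),
            row.names = FALSE)
  write_image(tissue$image, file.path(dir, "image.tif"),
              max_value = max(1, vapply(tissue$image$channels, max, numeric(1))))
  invisible(dir)
}
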