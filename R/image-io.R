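# Multi-channel image container and the preprocessing chain used before
# segmentation: background correction first, then (optional)
# Richardson-Lucy deconvolution — in that order.

#' Multi-channel fluorescence image
#'
#' Container for one acquisition: a named, ordered set of 2D intensity
#' channels sharing a single shape, plus pixel calibration and sample
#' metadata. Between 1 and 5 channels are allowed (four marker channels
#' plus an optional nuclear channel).
#'
#' @param channels named list of non-negative numeric matrices, all of
#'   identical dimension. Names must be unique.
#' @param pixel_size pixel edge length in micrometers per pixel.
#' @param sample_id sample identifier.
#' @param group_label group membership, one of `"LN"`, `"FL_1-2"`,
#'   `"FL_2-3A"`, `"other"`.
#' @param provenance free-text acquisition notes.
#' @return An object of class `mc_image`.
#' @export
mc_image <- function(channels, pixel_size = 0.5, sample_id = "sample",
                     group_label = c("other", "LN", "FL_1-2", "FL_2-3A"),
                     provenance = "") {
  group_label <- match.arg(group_label)
  if (!is.list(channels) || length(channels) < 1L || length(channels) > 5L)
    stop("'channels' must be a named list of 1 to 5 matrices")
  nms <- names(channels)
  if (is.null(nms) || any(nms == ""))
    stop("'channels' must be a named list")
  if (anyDuplicated(nms))
    stop("channel names must be unique")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L)
    stop("all channels must share one shape")
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    # tolerate FFT round-off: clamp negligible negatives to zero
    m[m < 0 & m > -1e-8] <- 0
    m
  })
  if (any(vapply(channels, function(m) any(m < 0), logical(1))))
    stop("channel intensities must be non-negative")
  structure(list(channels = channels,
                 pixel_size = pixel_size,
                 sample_id = sample_id,
                 group_label = group_label,
                 provenance = provenance),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<mc_image> %s [%s] %dx%d px, %.3g um/px\n  channels: %s\n",
              x$sample_id, x$group_label, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Image shape helper
#' @param img an `mc_image`.
#' @return Integer `c(nrow, ncol)`.
#' @export
image_shape <- function(img) dim(img$channels[[1]])

#' Read a multi-page TIFF as a multi-channel image
#'
#' Each TIFF page becomes one channel, bound to `channel_names` in page
#' order. Intensities are kept in the floating representation returned
#' by the TIFF reader (integer TIFFs map to `[0, 1]`).
#'
#' @param path TIFF file path.
#' @param channel_names character vector, one name per page.
#' @param pixel_size calibration to use when the file carries none
#'   (micrometers per pixel).
#' @inheritParams mc_image
#' @return An `mc_image`.
#' @export
read_image <- function(path, channel_names, pixel_size = 0.5,
                       sample_id = basename(path), group_label = "other") {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) != length(channel_names))
    stop(sprintf("page/name count mismatch: file has %d pages, %d names given",
                 length(pages), length(channel_names)))
  # honour an x-resolution tag in pixels/um if present on the first page
  res <- attr(pages[[1]], "x.resolution")
  unit <- attr(pages[[1]], "resolution.unit")
  if (!is.null(res) && is.numeric(res) && res > 0 && identical(unit, "none"))
    pixel_size <- 1 / res
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental RGB pages
    attributes(p) <- list(dim = dim(p))
    p
  })
  names(chans) <- channel_names
  mc_image(chans, pixel_size = pixel_size, sample_id = sample_id,
           group_label = group_label, provenance = path)
}

#' Write a multi-channel image as a multi-page 16-bit TIFF
#'
#' Channels are quantized to 16 bits; values are divided by `max_value`
#' and clipped to `[0, 1]` before writing. Channel names are stored in
#' the per-page image description.
#'
#' @param img an `mc_image`.
#' @param path output file path.
#' @param max_value intensity mapped to the top of the 16-bit range.
#'   Defaults to 1 when all intensities are within `[0, 1]`, else to the
#'   image maximum.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, max_value = NULL) {
  mx <- max(vapply(img$channels, max, numeric(1)), 0)
  if (is.null(max_value)) max_value <- if (mx <= 1) 1 else mx
  pages <- lapply(names(img$channels), function(nm) {
    m <- pmin(pmax(img$channels[[nm]] / max_value, 0), 1)
    attr(m, "description") <- nm
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Rolling-ball style background subtraction
#'
#' Estimates, per channel, a smooth background as the grayscale
#' morphological opening with a disc structuring element of the given
#' radius, subtracts it, and clips at zero. A constant channel maps to
#' all zeros. The radius must exceed the typical cell radius so that
#' cells are not absorbed into the background estimate.
#'
#' @param img an `mc_image`.
#' @param radius_px background disc radius in pixels (> 0).
#' @return A new `mc_image` with corrected channels.
#' @export
subtract_background <- function(img, radius_px = 50) {
  if (!is.numeric(radius_px) || radius_px <= 0)
    stop("'radius_px' must be positive")
  r <- as.integer(radius_px)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  out <- img
  out$channels <- lapply(img$channels, function(m) {
    # replicate-pad so erosion at the borders does not see zeros;
    # scale into [0, 1], where EBImage grayscale morphology operates
    nr <- nrow(m); nc <- ncol(m)
    mx <- max(m, 1e-12)
    padded <- m[c(rep(1L, r), 1:nr, rep(nr, r)),
                c(rep(1L, r), 1:nc, rep(nc, r))] / mx
    bg <- EBImage::opening(padded, brush)[r + 1:nr, r + 1:nc] * mx
    pmax(m - bg, 0)
  })
  out
}

# Odd-sized normalized Gaussian kernel covering +-4 sigma.
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  k / sum(k)
}

#' Richardson-Lucy deconvolution with a Gaussian PSF
#'
#' Restores each channel by iterating the Richardson-Lucy update with a
#' normalized Gaussian point-spread function. Output is non-negative
#' and, for interior sources, flux-preserving. `psf_sigma_px = 0` is
#' defined as the identity (no kernel to invert).
#'
#' @param img an `mc_image` with finite intensities.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (>= 0).
#' @param iterations number of Richardson-Lucy iterations (>= 1).
#' @return A restored `mc_image`.
#' @export
deconvolve <- function(img, psf_sigma_px = 2, iterations = 10) {
  if (iterations < 1) stop("'iterations' must be >= 1")
  if (psf_sigma_px < 0) stop("'psf_sigma_px' must be >= 0")
  if (psf_sigma_px == 0) return(img)
  bad <- vapply(img$channels, function(m) any(!is.finite(m)), logical(1))
  if (any(bad))
    stop("non-finite pixels in channel(s): ",
         paste(names(img$channels)[bad], collapse = ", "))
  psf <- gaussian_kernel(psf_sigma_px)
  eps <- 1e-12
  out <- img
  out$channels <- lapply(img$channels, function(obs) {
    est <- matrix(mean(obs), nrow(obs), ncol(obs))
    for (i in seq_len(iterations)) {
      blurred <- EBImage::filter2(est, psf, boundary = "replicate")
      ratio <- obs / (blurred + eps)
      est <- est * EBImage::filter2(ratio, psf, boundary = "replicate")
    }
    pmax(est, 0)
  })
  out
}

#' Run the preprocessing chain in the prescribed order
#'
#' Background correction precedes deconvolution; requesting the reverse
#' order is refused unless `allow_reorder = TRUE`, because segmentation
#' thresholds downstream assume a background-corrected input.
#'
#' @param img an `mc_image`.
#' @param steps character vector drawn from
#'   `c("background", "deconvolve")`, executed in the given order.
#' @param background_radius_px radius for [subtract_background()].
#' @param psf_sigma_px,iterations parameters for [deconvolve()].
#' @param allow_reorder set `TRUE` to permit deconvolution before
#'   background correction.
#' @return The preprocessed `mc_image`.
#' @export
preprocess <- function(img, steps = c("background"),
                       background_radius_px = 50,
                       psf_sigma_px = 2, iterations = 10,
                       allow_reorder = FALSE) {
  steps <- match.arg(steps, c("background", "deconvolve"),
                     several.ok = TRUE)
  ib <- match("background", steps)
  id <- match("deconvolve", steps)
  if (!is.na(ib) && !is.na(id) && id < ib && !allow_reorder)
    stop("deconvolution before background correction is refused; ",
         "set allow_reorder = TRUE to override")
  for (s in steps) {
    img <- switch(s,
      background = subtract_background(img, background_radius_px),
      deconvolve = deconvolve(img, psf_sigma_px, iterations))
  }
  img
}
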