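# Minimal reader/writer for the ImageJ .roi binary format (big-endian).
# Supported types: rectangle, oval, polygon, freehand/traced (treated
# as polygons). Layout: bytes 0-3 magic "Iout", 4-5 version, 6 roi
# type, 8-15 top/left/bottom/right (shorts), 16-17 n coordinates,
# then (for polygon types) n shorts of x offsets relative to 'left'
# followed by n shorts of y offsets relative to 'top', after the
# 64-byte header. ImageJ coordinates are 0-based with the origin at
# the top-left pixel corner; on import they are shifted to this
# package's 1-based pixel-center convention.

IJ_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L, freeline = 4L,
              polyline = 5L, noroi = 6L, freehand = 7L, traced = 8L,
              angle = 9L, point = 10L)

read_short <- function(raw, off) {  # unsigned big-endian short, 1-based offset
  as.integer(raw[off]) * 256L + as.integer(raw[off + 1L])
}
read_sshort <- function(raw, off) { # signed
  v <- read_short(raw, off)
  if (v >= 32768L) v - 65536L else v
}

#' Read a single ImageJ .roi file
#'
#' @param path path to a `.roi` file, or a raw vector of its bytes.
#' @return A list: `name`, `type` (`"rect"`, `"oval"`, `"polygon"`),
#'   and `geom` (a [polygon_geom()]; rectangles and ovals are converted,
#'   coordinates 1-based pixel centers).
#' @export
read_ij_roi <- function(path) {
  raw <- if (is.raw(path)) path else readBin(path, "raw", file.size(path))
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ ROI file (missing 'Iout' magic)")
  type_code <- as.integer(raw[7])
  top <- read_sshort(raw, 9); left <- read_sshort(raw, 11)
  bottom <- read_sshort(raw, 13); right <- read_sshort(raw, 15)
  n <- read_short(raw, 17)
  name <- if (!is.raw(path)) sub("\\.roi$", "", basename(path)) else "roi"
  if (type_code == IJ_TYPES[["rect"]]) {
    # pixel block rows top+1 .. bottom, cols left+1 .. right
    geom <- polygon_geom(r = c(top, top, bottom, bottom) + 0.5,
                         c = c(left, right, right, left) + 0.5)
    type <- "rect"
  } else if (type_code == IJ_TYPES[["oval"]]) {
    geom <- as_polygon(ellipse_geom(cr = (top + bottom) / 2 + 0.5,
                                    cc = (left + right) / 2 + 0.5,
                                    a = (right - left) / 2,
                                    b = (bottom - top) / 2, theta = 0))
    type <- "oval"
  } else if (type_code %in% IJ_TYPES[c("polygon", "freehand", "traced")]) {
    if (n < 3) stop("polygon ROI with fewer than 3 vertices")
    xs <- vapply(seq_len(n), function(i) read_sshort(raw, 65L + 2L * (i - 1L)),
                 integer(1)) + left
    ys <- vapply(seq_len(n), function(i) read_sshort(raw, 65L + 2L * (n + i - 1L)),
                 integer(1)) + top
    geom <- polygon_geom(r = ys + 0.5, c = xs + 0.5)
    type <- "polygon"
  } else {
    stop("unsupported ImageJ ROI type code: ", type_code)
  }
  list(name = name, type = type, geom = geom)
}

#' Write a geometry as an ImageJ .roi file
#'
#' Writes polygons (and ellipses, converted to polygons) in the ImageJ
#' ROI binary format, so region sets can be audited in ImageJ/Fiji and
#' fixtures can be generated in code.
#'
#' @param geom an [ellipse_geom()] or [polygon_geom()].
#' @param path output `.roi` path.
#' @return `path`, invisibly.
#' @export
write_ij_roi <- function(geom, path) {
  poly <- as_polygon(geom)
  xs <- as.integer(round(poly$c - 0.5))
  ys <- as.integer(round(poly$r - 0.5))
  left <- min(xs); top <- min(ys)
  n <- length(xs)
  put_short <- function(v) {
    v <- as.integer(v)
    if (v < 0) v <- v + 65536L
    as.raw(c(v %/% 256L, v %% 256L))
  }
  header <- raw(64)
  header[1:4] <- charToRaw("Iout")
  header[5:6] <- put_short(228L)
  header[7] <- as.raw(IJ_TYPES[["polygon"]])
  header[9:10] <- put_short(top)
  header[11:12] <- put_short(left)
  header[13:14] <- put_short(max(ys))
  header[15:16] <- put_short(max(xs))
  header[17:18] <- put_short(n)
  body <- c(do.call(c, lapply(xs - left, put_short)),
            do.call(c, lapply(ys - top, put_short)))
  writeBin(c(header, body), path)
  invisible(path)
}

# Read all .roi entries of a file: either one .roi or a .zip archive.
# Returns list of read_ij_roi() results with names from entry names.
read_ij_rois <- function(path) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    tmp <- file.path(tempfile("ijrois"), "x")
    dir.create(dirname(tmp), recursive = TRUE, showWarnings = FALSE)
    entries <- unzip(path, exdir = dirname(tmp))
    entries <- entries[grepl("\\.roi$", entries, ignore.case = TRUE)]
    lapply(sort(entries), read_ij_roi)
  } else {
    list(read_ij_roi(path))
  }
}
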