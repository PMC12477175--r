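# ImageJ ROI import, automatic region proposal, morphometry and
# compartment allocation.

test_that("ImageJ ROI writer/reader round-trips polygons and known bytes", {
  g <- polygon_geom(r = c(10.5, 10.5, 40.5, 40.5), c = c(5.5, 30.5, 30.5, 5.5))
  p <- tempfile(fileext = ".roi")
  write_ij_roi(g, p)
  back <- read_ij_roi(p)
  expect_equal(back$geom$r, g$r)
  expect_equal(back$geom$c, g$c)

  # hand-assembled rectangle ROI per the documented byte layout:
  # magic, version 228, type rect (1), top=2 left=3 bottom=10 right=8
  raw <- raw(64)
  raw[1:4] <- charToRaw("Iout")
  raw[5:6] <- as.raw(c(0, 228))
  raw[7] <- as.raw(1)
  raw[9:16] <- as.raw(c(0, 2, 0, 3, 0, 10, 0, 8))
  rect <- read_ij_roi(raw)
  expect_equal(rect$type, "rect")
  mask <- rasterize_geom(rect$geom, c(20, 20))
  # ImageJ rect spans pixel rows top+1..bottom, cols left+1..right
  expect_equal(sum(mask), 8 * 5)
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] %in% 3:10))
  expect_true(all(which(mask, arr.ind = TRUE)[, 2] %in% 4:8))

  expect_error(read_ij_roi(as.raw(rep(0, 64))), "magic")
})

test_that("ROI archives import with follicle/GC parentage", {
  dir <- tempfile(); dir.create(dir)
  shape <- c(200L, 200L)
  f1 <- ellipse_geom(60, 60, 40, 35)
  f2 <- ellipse_geom(150, 140, 35, 30)
  g1 <- ellipse_geom(60, 60, 18, 15)
  g2 <- ellipse_geom(150, 140, 15, 13)
  write_ij_roi(f1, file.path(dir, "follicle_1.roi"))
  write_ij_roi(f2, file.path(dir, "follicle_2.roi"))
  write_ij_roi(g1, file.path(dir, "gc_1.roi"))
  write_ij_roi(g2, file.path(dir, "gc_2.roi"))
  zipfile <- tempfile(fileext = ".zip")
  make_zip(list.files(dir, full.names = TRUE), zipfile)
  rs <- import_regions(zipfile, shape)
  expect_equal(nrow(rs$follicles), 2)
  expect_equal(nrow(rs$gcs), 2)
  expect_equal(rs$source, "manual_roi")
  # parentage by containment: each GC sits in the follicle at its center
  centers <- rbind(c(60, 60), c(150, 140))
  for (i in 1:2) {
    pf <- rs$gcs$parent_follicle_id[i]
    expect_equal(rs$follicle_labels[centers[i, 1], centers[i, 2]], pf)
    expect_true(all(rs$gc_px[[i]] %in% rs$follicle_px[[pf]]))
  }
})

test_that("orphan GCs are flagged, not dropped; bad names are errors", {
  dir <- tempfile(); dir.create(dir)
  write_ij_roi(ellipse_geom(40, 40, 25, 20), file.path(dir, "follicle_1.roi"))
  write_ij_roi(ellipse_geom(150, 150, 12, 10), file.path(dir, "gc_far.roi"))
  zipfile <- tempfile(fileext = ".zip")
  make_zip(list.files(dir, full.names = TRUE), zipfile)
  expect_warning(rs <- import_regions(zipfile, c(200L, 200L)), "orphan")
  expect_equal(nrow(rs$gcs), 1)
  expect_true(is.na(rs$gcs$parent_follicle_id[1]))

  write_ij_roi(ellipse_geom(40, 40, 5, 5), file.path(dir, "mystery.roi"))
  zipfile2 <- tempfile(fileext = ".zip")
  make_zip(list.files(dir, full.names = TRUE), zipfile2)
  expect_error(import_regions(zipfile2, c(200L, 200L)), "neither prefix")
})

test_that("auto regions recover planted geometry from dense staining", {
  cfg <- synth_config(cell_counts = c("B" = 400, "GC-B" = 120, "T_FH" = 30,
                                      "T_FK" = 10, "Treg" = 20, "other" = 20),
                      seed = 40L)
  tis <- simulate_tissue(cfg)
  img <- preprocess(tis$image)
  m19 <- threshold_channel(img, "CD19")
  m6 <- threshold_channel(img, "BCL6")
  ar <- auto_regions(m19, m6)
  expect_equal(nrow(ar$follicles), nrow(tis$regions$follicles))
  expect_equal(nrow(ar$gcs), nrow(tis$regions$gcs))
  iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (i in seq_along(tis$regions$follicle_px)) {
    best <- max(vapply(ar$follicle_px, iou, numeric(1),
                       a = tis$regions$follicle_px[[i]]))
    expect_gte(best, 0.8)
  }
  for (i in seq_along(tis$regions$gc_px)) {
    best <- max(vapply(ar$gc_px, iou, numeric(1), a = tis$regions$gc_px[[i]]))
    expect_gte(best, 0.8)
  }
})

test_that("auto regions degenerate rules hold", {
  empty <- matrix(FALSE, 80, 80)
  rs <- auto_regions(empty, empty, min_follicle_area_px = 10)
  expect_equal(nrow(rs$follicles), 0)
  expect_equal(nrow(rs$gcs), 0)
  # a BCL6 blob outside all follicles is not promoted to a GC
  cd19 <- matrix(FALSE, 80, 80); cd19[10:40, 10:40] <- TRUE
  bcl6 <- matrix(FALSE, 80, 80); bcl6[60:75, 60:75] <- TRUE
  rs2 <- auto_regions(cd19, bcl6, min_follicle_area_px = 100,
                      smoothing_px = 2, min_gc_area_px = 10, grow_px = 0)
  expect_equal(nrow(rs2$follicles), 1)
  expect_equal(nrow(rs2$gcs), 0)
})

test_that("morphometry counts pixels and never double-counts overlap", {
  # one 100-px follicle with a 25-px GC on a 1000-px image
  shape <- c(25L, 40L)
  f <- polygon_geom(r = c(5.5, 5.5, 15.5, 15.5), c = c(5.5, 15.5, 15.5, 5.5))
  g <- polygon_geom(r = c(8.5, 8.5, 13.5, 13.5), c = c(8.5, 13.5, 13.5, 8.5))
  rs <- region_set(list(f), list(g), gc_parent = 1L, shape = shape)
  expect_equal(rs$follicles$area_px, 100)
  expect_equal(rs$gcs$area_px, 25)
  m <- measure_regions(rs)
  expect_equal(m$follicle_coverage, 100 / 1000)
  expect_equal(m$gc_coverage, 25 / 1000)
  expect_equal(m$mean_follicle_area_um2, 100 * 0.25)

  # empty set -> all zeros
  m0 <- measure_regions(tfkscope:::new_region_set(list(), list(), integer(),
                                                  shape = c(10L, 10L)))
  expect_equal(m0$n_follicles, 0)
  expect_equal(m0$follicle_coverage, 0)
  expect_equal(m0$mean_gc_area_px2, 0)

  # two overlapping 100-px follicles sharing 50 px -> union of 150
  f1 <- polygon_geom(r = c(5.5, 5.5, 15.5, 15.5), c = c(5.5, 15.5, 15.5, 5.5))
  f2 <- polygon_geom(r = c(5.5, 5.5, 15.5, 15.5), c = c(10.5, 20.5, 20.5, 10.5))
  rs2 <- region_set(list(f1, f2), list(), gc_parent = integer(), shape = shape)
  m2 <- measure_regions(rs2)
  expect_equal(m2$follicle_coverage, 150 / 1000)
  # union coverage never exceeds the sum of the parts
  expect_lte(m2$follicle_coverage, sum(rs2$follicles$area_px) / 1000)
})

test_that("cells partition into compartments with inward boundary ties", {
  shape <- c(100L, 100L)
  f <- ellipse_geom(50, 50, 30, 30)
  g <- ellipse_geom(50, 50, 12, 12)
  rs <- region_set(list(f), list(g), gc_parent = 1L, shape = shape)
  calls <- data.frame(cell_id = 1:4,
                      centroid_r = c(50, 50, 50, 5),
                      centroid_c = c(50, 75, 62.4, 5))
  loc <- assign_cells(calls, rs)
  expect_equal(loc$compartment, c("GC", "follicle", "GC", "extrafollicular"))
  # GC cell carries its parent follicle id (counts toward the follicle)
  expect_equal(loc$follicle_id[1], 1L)
  expect_equal(loc$gc_id[1], 1L)
  expect_true(is.na(loc$follicle_id[4]))
  # partition: exactly one compartment each
  expect_true(all(loc$compartment %in% c("GC", "follicle", "extrafollicular")))
})

test_that("allocation recovers planted compartments on synthetic tissue", {
  cfg <- small_config(seed = 41L)
  tis <- simulate_tissue(cfg)
  tr <- tis$truth$cells
  loc <- assign_cells(data.frame(cell_id = tr$cell_id,
                                 centroid_r = tr$centroid_r,
                                 centroid_c = tr$centroid_c), tis$regions)
  expect_gte(mean(loc$compartment == tr$true_region), 0.99)
  # nesting: per follicle, GC-assigned <= follicle-assigned totals
  for (f in tis$regions$follicles$follicle_id) {
    in_f <- sum(loc$follicle_id == f, na.rm = TRUE)
    in_gc_of_f <- sum(loc$follicle_id == f & loc$compartment == "GC",
                      na.rm = TRUE)
    expect_lte(in_gc_of_f, in_f)
  }
  # order invariance of morphometry
  rs_rev <- tis$regions
  rs_rev$follicle_px <- rev(rs_rev$follicle_px)
  rs_rev$follicles <- rs_rev$follicles[rev(seq_len(nrow(rs_rev$follicles))), ]
  expect_equal(measure_regions(rs_rev)$follicle_coverage,
               measure_regions(tis$regions)$follicle_coverage)
})
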