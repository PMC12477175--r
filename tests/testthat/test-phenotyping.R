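# Colocalization ROIs, subtype calling and intensity-profile
# confirmation.

blob_mask <- function(shape, blocks) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (b in blocks) m[b$r, b$c] <- TRUE
  m
}

test_that("colocalize boundary and degenerate behavior", {
  a <- blob_mask(c(40, 40), list(list(r = 1:5, c = 1:5)))
  b <- blob_mask(c(40, 40), list(list(r = 20:24, c = 20:24)))
  expect_equal(nrow(colocalize(a, b)$rois), 0)                 # disjoint

  both <- blob_mask(c(40, 40), list(list(r = 10:14, c = 10:14)))  # 25 px
  res <- colocalize(both, both)
  expect_equal(nrow(res$rois), 1)
  expect_equal(res$rois$area_px, 25)
  expect_true(res$rois$retained)

  small_large <- blob_mask(c(60, 60), list(list(r = 1:5, c = 1:2),      # 10 px
                                           list(r = 30:54, c = 30:41))) # 300 px
  res2 <- colocalize(small_large, small_large)
  expect_equal(nrow(res2$rois), 2)
  expect_false(any(res2$rois$retained))
  expect_setequal(res2$rois$discard_reason, c("too_small", "too_large"))

  expect_error(colocalize(a, matrix(FALSE, 10, 10)), "shapes differ")
})

test_that("colocalize matches the AND + flood-fill oracle on random masks", {
  set.seed(30)
  for (trial in 1:50) {
    nr <- sample(16:64, 1); nc <- sample(16:64, 1)
    a <- matrix(runif(nr * nc) < 0.5, nr, nc)
    b <- matrix(runif(nr * nc) < 0.5, nr, nc)
    res <- colocalize(a, b, min_area_px = 3, max_area_px = 40)
    ref_lab <- flood_fill_label(a & b, 8)
    ref_sets <- component_sets(ref_lab)
    got_sets <- lapply(res$pixels, sort)
    # identical pixel sets (order-free)
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(ref_sets, paste, character(1), collapse = ","))
    # areas and retained flags agree with the oracle's component sizes
    ref_area <- lengths(ref_sets)
    expect_setequal(res$rois$area_px, ref_area)
    expect_equal(sum(res$rois$retained), sum(ref_area >= 3 & ref_area <= 40))
    # conservation: retained + discarded = total components
    expect_equal(nrow(res$rois), length(ref_sets))
  }
})

test_that("colocalize is symmetric in its arguments", {
  set.seed(31)
  a <- matrix(runif(900) < 0.5, 30, 30)
  b <- matrix(runif(900) < 0.5, 30, 30)
  r1 <- colocalize(a, b, 1, 900)
  r2 <- colocalize(b, a, 1, 900)
  expect_identical(lapply(r1$pixels, sort), lapply(r2$pixels, sort))
  expect_identical(r1$rois$area_px, r2$rois$area_px)
})

test_that("subtype logic splits CD4+BCL6+ ROIs by TIA-1 fraction", {
  sh <- c(60, 60)
  cd4 <- blob_mask(sh, list(list(r = 5:10, c = 5:10),      # cell 1: 36 px
                            list(r = 30:35, c = 30:35)))   # cell 2: 36 px
  bcl6 <- cd4
  tia1 <- blob_mask(sh, list(list(r = 30:35, c = 30:35)))  # covers cell 2 only
  cd19 <- matrix(FALSE, sh[1], sh[2])
  panel <- list(CD19 = cd19, CD4 = cd4, BCL6 = bcl6, TIA1 = tia1)
  calls <- call_subtypes(panel, "localization")
  tab <- table(calls$calls$subtype)
  expect_equal(unname(tab[["T_FH"]]), 1)
  expect_equal(unname(tab[["T_FK"]]), 1)
  # 0% TIA-1 overlap -> T_FH by definition
  tfh <- calls$calls[calls$calls$subtype == "T_FH", ]
  expect_equal(tfh$tia1_frac, 0)
  # T_FH + T_FK = retained CD4+BCL6+ ROI count
  expect_equal(sum(calls$calls$subtype %in% c("T_FH", "T_FK")),
               sum(calls$evidence$CD4_BCL6$rois$retained))
})

test_that("missing required channels and empty panels are handled", {
  m <- matrix(FALSE, 20, 20)
  expect_error(call_subtypes(list(CD4 = m, BCL6 = m), "localization"),
               "CD19")
  panel <- list(CD19 = m, CD4 = m, BCL6 = m, TIA1 = m)
  calls <- call_subtypes(panel, "localization")
  expect_equal(nrow(calls$calls), 0)
})

test_that("FOXP3-overlapping CD4+BCL6+ ROIs are rerouted to T_FR in the treg panel", {
  sh <- c(40, 40)
  cell <- list(r = 10:15, c = 10:15)
  cd4 <- blob_mask(sh, list(cell)); bcl6 <- cd4
  tia1 <- matrix(FALSE, 40, 40)
  foxp3 <- blob_mask(sh, list(list(r = 10:15, c = 10:12)))  # 50% of the ROI
  calls <- call_subtypes(list(FOXP3 = foxp3, CD4 = cd4, BCL6 = bcl6,
                              TIA1 = tia1), "treg_contact")
  expect_equal(calls$calls$subtype, "T_FR")
  # below the exclusion fraction it stays in the T_FH/T_FK split
  foxp3b <- blob_mask(sh, list(list(r = 10:15, c = 10)))    # ~17%
  calls2 <- call_subtypes(list(FOXP3 = foxp3b, CD4 = cd4, BCL6 = bcl6,
                               TIA1 = tia1), "treg_contact")
  expect_equal(calls2$calls$subtype, "T_FH")
})

test_that("subtype recovery is exact on a small synthetic sample", {
  cfg <- small_config(seed = 32L)
  tis <- simulate_tissue(cfg)
  res <- analyze_image(tis$image, regions = tis$regions,
                       background_radius_px = 30)
  truth_tab <- table(tis$truth$cells$type)
  got_tab <- table(res$calls$calls$subtype)
  expect_equal(unname(got_tab[["GC-B"]]), unname(truth_tab[["GC-B"]]))
  expect_equal(unname(got_tab[["T_FH"]]), unname(truth_tab[["T_FH"]]))
  expect_equal(unname(got_tab[["T_FK"]]), unname(truth_tab[["T_FK"]]))
})

test_that("intensity profiles confirm planted T_FK and reject B-cell impostors", {
  sh <- c(50, 80)
  mk <- function(blocks) {
    m <- matrix(0, sh[1], sh[2])
    for (b in blocks) m[b$r, b$c] <- 1
    m
  }
  tfk <- list(r = 20:27, c = 20:27)
  bcell <- list(r = 20:27, c = 50:57)
  img <- mc_image(list(CD19 = mk(list(bcell)),
                       CD4 = mk(list(tfk, bcell)),   # impostor: CD19 cell leaking CD4/BCL6
                       BCL6 = mk(list(tfk, bcell)),
                       TIA1 = mk(list(tfk, bcell))))
  masks <- lapply(names(img$channels), function(ch)
    threshold_channel(img, ch, "manual", manual_value = 0.5))
  names(masks) <- names(img$channels)
  calls <- call_subtypes(masks, "localization", min_area_px = 20,
                         max_area_px = 200)
  tfk_calls <- calls$calls[calls$calls$subtype == "T_FK", ]
  expect_equal(nrow(tfk_calls), 2)
  th <- c(CD19 = 0.5, CD4 = 0.5, BCL6 = 0.5, TIA1 = 0.5)
  passed <- vapply(tfk_calls$cell_id, function(id)
    profile_candidate(img, calls, id, th)$passed, logical(1))
  # the true T_FK (no CD19) passes; the impostor over the B cell fails
  genuine <- tfk_calls$centroid_c < 40
  expect_true(all(passed[genuine]))
  expect_false(any(passed[!genuine]))
})

test_that("profiles at the image corner are clipped but returned", {
  sh <- c(30, 30)
  m <- matrix(0, sh[1], sh[2]); m[1:6, 1:6] <- 1
  img <- mc_image(list(CD19 = matrix(0, sh[1], sh[2]),
                       CD4 = m, BCL6 = m, TIA1 = m))
  masks <- lapply(names(img$channels), function(ch)
    threshold_channel(img, ch, "manual", manual_value = 0.5))
  names(masks) <- names(img$channels)
  calls <- call_subtypes(masks, "localization", min_area_px = 10)
  expect_equal(calls$calls$subtype, "T_FK")
  prof <- profile_candidate(img, calls,
                            calls$calls$cell_id[calls$calls$subtype == "T_FK"][1],
                            c(CD4 = 0.5, BCL6 = 0.5, TIA1 = 0.5),
                            half_length_px = 15)
  expect_true(min(prof$cols) >= 1)
  expect_s3_class(prof, "intensity_profile")
  expect_true(prof$passed)
})
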