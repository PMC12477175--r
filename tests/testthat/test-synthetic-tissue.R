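# Generator: region placement, cell placement, rendering, determinism.

test_that("degenerate configurations give empty output", {
  set.seed(1)
  cfg <- synth_config(image_shape = c(128L, 128L), n_follicles = 0L,
                      cell_counts = c("B" = 0))
  regs <- place_regions(cfg)
  expect_equal(nrow(regs$follicles), 0)
  expect_equal(nrow(regs$gcs), 0)
  truth <- place_cells(cfg, regs)
  expect_equal(nrow(truth$cells), 0)
  expect_equal(nrow(truth$contacts), 0)
})

test_that("follicles contain their GC and are pairwise disjoint", {
  set.seed(2)
  cfg <- synth_config(image_shape = c(1024L, 1024L), n_follicles = 5L,
                      follicle_radius_px = c(mean = 90, sd = 8),
                      gc_fraction = 0.5)
  regs <- place_regions(cfg)
  expect_equal(nrow(regs$follicles), 5)
  expect_equal(nrow(regs$gcs), 5)
  for (i in 1:5) {
    # GC strictly inside its follicle: pixel subset and smaller area
    expect_true(all(regs$gc_px[[i]] %in% regs$follicle_px[[i]]))
    expect_lt(regs$gcs$area_px[i], regs$follicles$area_px[i])
  }
  # rasterized pairwise intersections are empty
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(regs$follicle_px[[i]], regs$follicle_px[[j]]), 0)
  # everything inside image bounds by construction of the rasterizer;
  # check the geometries too
  for (g in regs$geoms$follicles) {
    ext <- max(g$a, g$b)
    expect_gte(g$cr - ext, 0); expect_lte(g$cr + ext, 1024)
    expect_gte(g$cc - ext, 0); expect_lte(g$cc + ext, 1024)
  }
})

test_that("requesting more follicles than fit raises a capacity error", {
  set.seed(3)
  cfg <- synth_config(image_shape = c(300L, 300L), n_follicles = 6L,
                      follicle_radius_px = c(mean = 100, sd = 5))
  expect_error(place_regions(cfg), "capacity")
})

test_that("degenerate placement probabilities pin the compartment", {
  set.seed(4)
  probs <- default_probs <- synth_config()$region_placement_probs
  probs["GC-B", ] <- c(1, 0, 0)
  cfg <- small_config(cell_counts = c("GC-B" = 10),
                      region_placement_probs = probs)
  regs <- place_regions(cfg)
  truth <- place_cells(cfg, regs)
  expect_equal(truth$cells$true_region, rep("GC", 10))
})

test_that("planted contact pairs touch exactly and others keep clearance", {
  set.seed(5)
  cfg <- small_config(planted_contact_pairs = 4L)
  regs <- place_regions(cfg)
  truth <- place_cells(cfg, regs)
  expect_equal(nrow(truth$contacts), 4)
  cells <- truth$cells
  for (k in 1:4) {
    a <- cells[cells$cell_id == truth$contacts$tfk_id[k], ]
    b <- cells[cells$cell_id == truth$contacts$treg_id[k], ]
    expect_equal(a$type, "T_FK"); expect_equal(b$type, "Treg")
    d <- sqrt((a$centroid_r - b$centroid_r)^2 + (a$centroid_c - b$centroid_c)^2)
    expect_lt(abs(d - (a$radius_px + b$radius_px)), 0.5)
  }
  # every non-planted pair respects the separation margin
  paired <- cbind(truth$contacts$tfk_id, truth$contacts$treg_id)
  for (i in seq_len(nrow(cells) - 1)) for (j in (i + 1):nrow(cells)) {
    ids <- c(cells$cell_id[i], cells$cell_id[j])
    if (any(apply(paired, 1, function(p) setequal(p, ids)))) next
    d <- sqrt((cells$centroid_r[i] - cells$centroid_r[j])^2 +
                (cells$centroid_c[i] - cells$centroid_c[j])^2)
    expect_gte(d, cells$radius_px[i] + cells$radius_px[j])
  }
})

test_that("true_region labels agree with the rasterized regions", {
  set.seed(6)
  cfg <- small_config()
  regs <- place_regions(cfg)
  truth <- place_cells(cfg, regs)
  for (i in seq_len(nrow(truth$cells))) {
    ri <- round(truth$cells$centroid_r[i]); ci <- round(truth$cells$centroid_c[i])
    expected <- if (regs$gc_labels[ri, ci] > 0) "GC"
      else if (regs$follicle_labels[ri, ci] > 0) "follicle"
      else "extrafollicular"
    expect_equal(truth$cells$true_region[i], expected)
  }
})

test_that("rendering honours the marker map", {
  set.seed(7)
  cfg <- small_config(noise_sd = 0, background_amplitude = 0)
  regs <- place_regions(cfg)
  truth <- place_cells(cfg, regs)
  img <- render_image(truth, cfg)
  pos_at <- function(ch, cell) {
    img$channels[[ch]][round(cell$centroid_r), round(cell$centroid_c)] > 1e-6
  }
  marker_map <- list("T_FK" = c("CD4", "BCL6", "TIA1"),
                     "Treg" = c("CD4", "FOXP3"),
                     "GC-B" = c("CD19", "BCL6"))
  for (type in names(marker_map)) {
    for (i in which(truth$cells$type == type)) {
      cell <- truth$cells[i, ]
      for (ch in names(img$channels)) {
        if (ch %in% marker_map[[type]]) expect_true(pos_at(ch, cell))
        else expect_false(pos_at(ch, cell))
      }
    }
  }
})

test_that("empty scene with no noise or background renders to zero", {
  set.seed(8)
  cfg <- synth_config(image_shape = c(64L, 64L), n_follicles = 0L,
                      cell_counts = c("B" = 0), noise_sd = 0,
                      background_amplitude = 0)
  truth <- place_cells(cfg, place_regions(cfg))
  img <- render_image(truth, cfg)
  for (ch in img$channels) expect_true(all(ch == 0))
})

test_that("PSF blur preserves integrated intensity within 1%", {
  cfg <- synth_config(image_shape = c(128L, 128L), n_follicles = 0L,
                      cell_counts = c("T_FK" = 0), noise_sd = 0,
                      background_amplitude = 0, psf_sigma_px = 2)
  truth <- structure(list(
    cells = data.frame(cell_id = 1L, type = "T_FK", centroid_r = 64,
                       centroid_c = 64, radius_px = 4,
                       true_region = "extrafollicular",
                       follicle_id = NA_integer_),
    regions = NULL, contacts = data.frame()), class = "ground_truth")
  blurred <- render_image(truth, cfg)
  cfg0 <- cfg; cfg0$psf_sigma_px <- 0
  sharp <- render_image(truth, cfg0)
  for (ch in c("CD4", "BCL6", "TIA1")) {
    expect_lt(abs(sum(blurred$channels[[ch]]) - sum(sharp$channels[[ch]])) /
                sum(sharp$channels[[ch]]), 0.01)
  }
})

test_that("unknown cell type in truth is an error", {
  cfg <- synth_config(image_shape = c(64L, 64L), n_follicles = 0L)
  truth <- structure(list(
    cells = data.frame(cell_id = 1L, type = "NKcell", centroid_r = 30,
                       centroid_c = 30, radius_px = 4,
                       true_region = "extrafollicular",
                       follicle_id = NA_integer_),
    regions = NULL, contacts = data.frame()), class = "ground_truth")
  expect_error(render_image(truth, cfg), "unknown cell type")
})

test_that("identical config and seed reproduce truth and image exactly", {
  cfg <- small_config(noise_sd = 0.1, seed = 99L)
  t1 <- simulate_tissue(cfg)
  t2 <- simulate_tissue(cfg)
  expect_identical(t1$truth$cells, t2$truth$cells)
  expect_identical(t1$truth$contacts, t2$truth$contacts)
  expect_identical(t1$image$channels, t2$image$channels)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(synth_config(cell_counts = c("B" = -1)), ">= 0")
  expect_error(synth_config(planted_contact_pairs = 99L), "contact_pairs")
  p <- default_placement_probs(); p["B", ] <- c(0.5, 0.2, 0.2)
  expect_error(synth_config(region_placement_probs = p), "sum to 1")
})
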