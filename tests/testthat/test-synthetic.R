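test_that("scenes are bit-identical under a fixed seed", {
  sp <- scene_spec(seed = 9, field_size = 256, n_macrophages = 4,
                   n_fibroblasts = 3, n_interior_puncta = 3,
                   recipient_positive_fraction = 2 / 3)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$cell$pixels, b$cell$pixels)
  expect_identical(a$donor$pixels, b$donor$pixels)
  expect_identical(a$recipient$pixels, b$recipient$pixels)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  r1 <- runif(3)
  set.seed(1234)
  invisible(generate_scene(scene_spec(seed = 9, field_size = 128,
                                      n_macrophages = 1,
                                      n_fibroblasts = 1)))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("zero-prevalence scenes contain and report zero protrusions", {
  sp <- scene_spec(seed = 15, field_size = 512, n_macrophages = 8,
                   n_fibroblasts = 0, protrusion_prevalence = 0)
  sc <- generate_scene(sp)
  expect_true(all(vapply(sc$ground_truth$cells,
                         function(g) length(g$protrusions) == 0L,
                         logical(1))))
  pa <- analyze_protrusions(sc$cell)
  expect_equal(percent_positive(pa)$percent, 0)
})

test_that("realized prevalence is the seeded per-cell Bernoulli draw", {
  sp <- scene_spec(seed = 7, field_size = 2048, n_macrophages = 100,
                   n_fibroblasts = 0, protrusion_prevalence = 0.4)
  sc <- generate_scene(sp)
  n_pos <- sum(vapply(sc$ground_truth$cells, `[[`, logical(1), "positive"))
  expect_gte(n_pos, 25)     # within plausible binomial range for n=100, p=0.4
  expect_lte(n_pos, 55)
  # repeatable draw
  sc2 <- generate_scene(sp)
  expect_equal(sum(vapply(sc2$ground_truth$cells, `[[`, logical(1),
                          "positive")), n_pos)
})

test_that("every ground-truth object appears in exactly one list", {
  sp <- scene_spec(seed = 25, field_size = 768, n_macrophages = 6,
                   n_fibroblasts = 5, n_interior_puncta = 6,
                   n_edge_puncta = 2, n_oversize_blobs = 1,
                   recipient_positive_fraction = 0.6)
  sc <- generate_scene(sp)
  for (g in sc$ground_truth$cells) {
    overlap <- intersect(g$body, unlist(g$protrusions))
    expect_equal(length(overlap), 0L)
  }
  all_puncta <- unlist(lapply(sc$ground_truth$recipients, function(g)
    lapply(c(g$interior, g$edge, g$oversize), `[[`, "pixels")))
  expect_equal(anyDuplicated(all_puncta), 0L)
})

test_that("ground-truth ribbons measure back to their analytic geometry", {
  shape <- c(200L, 200L)
  ps <- 0.5
  for (L in c(40, 80, 120)) {
    w <- 4
    # half-integer center row: the stroke edges align with pixel boundaries,
    # so the discrete shape matches the analytic capsule
    px <- rasterize_ribbon(c(100.5, 30), c(100.5, 30 + L), width = w,
                           shape = shape)
    m <- matrix(FALSE, shape[1], shape[2]); m[px] <- TRUE
    d <- measure_region(m, pixel_size = ps)
    # straight capsule: caliper length = chord + width (round caps)
    expect_lt(abs(d$length_um - (L + w) * ps), 1.0 * ps + 1e-9)
    expect_lt(abs(d$area_um2 - (L * w + pi / 4 * w^2) * ps^2) /
                ((L * w + pi / 4 * w^2) * ps^2), 0.05)
  }
  # bent ribbons keep caliper length close to the chord
  px <- rasterize_ribbon(c(60, 20), c(60, 140), ctrl = c(78, 80),
                         width = 4, shape = shape)
  m <- matrix(FALSE, shape[1], shape[2]); m[px] <- TRUE
  d <- measure_region(m, pixel_size = ps)
  expect_gt(d$length_um, 0.9 * 120 * ps)
})

test_that("donor-free controls are pure background", {
  sp <- scene_spec(seed = 33, field_size = 256)
  ctrl <- generate_control(sp)
  expect_lt(max(ctrl$pixels), sp$foreground)
  expect_equal(ctrl$channel_tag, "donor")
  # control percentile is stable across seeds
  p999 <- vapply(1:20, function(s) {
    unname(quantile(generate_control(scene_spec(seed = s,
                                                field_size = 256))$pixels,
                    0.999, type = 1))
  }, numeric(1))
  expect_lt(diff(range(p999)) / mean(p999), 0.10)
})

test_that("a control run through the transfer pipeline accepts nothing", {
  sc <- generate_scene(scene_spec(seed = 41, field_size = 512,
                                  n_macrophages = 0, n_fibroblasts = 5,
                                  recipient_positive_fraction = 0))
  ctrl <- generate_control(scene_spec(seed = 500, field_size = 512))
  cfg <- transfer_config(background = estimate_background(ctrl, "percentile",
                                                          99.9))
  rois <- recipient_rois(sc$recipient, cfg)
  expect_equal(length(rois), 5L)
  ta <- classify_recipients(rois, sc$donor, cfg)
  expect_equal(sum(ta$recipients$n_puncta), 0L)
  expect_equal(ta$summary$percent, 0)
})

test_that("impossible geometry errors name the offending object", {
  sp <- scene_spec(seed = 1, field_size = 96, n_macrophages = 40,
                   n_fibroblasts = 0)
  expect_error(generate_scene(sp), "macrophage")
})

test_that("scenes written to disk round-trip with their ground truth", {
  sc <- generate_scene(scene_spec(seed = 51, field_size = 320,
                                  n_macrophages = 2, n_fibroblasts = 2,
                                  recipient_positive_fraction = 0.5,
                                  n_interior_puncta = 2))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(dir, c("cell.tif", "donor.tif",
                                               "recipient.tif",
                                               "ground_truth.json")))))
  back <- load_image(file.path(dir, "cell.tif"), sc$cell$pixel_size, "cell")
  expect_identical(back$pixels, sc$cell$pixels)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(length(gt$cells), 2L)
  expect_equal(length(gt$recipients), 2L)
})
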