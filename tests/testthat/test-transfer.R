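# Hand-built noiseless transfer fixtures: exact counts by construction.
make_transfer_fixture <- function() {
  shape <- c(220L, 220L)
  ps <- 0.5
  rec <- matrix(FALSE, shape[1], shape[2])
  bodies <- list(tntquant:::rasterize_disk(c(60, 60), 25, shape),    # 1963 px
                 tntquant:::rasterize_disk(c(60, 160), 25, shape),
                 tntquant:::rasterize_disk(c(160, 110), 30, shape))
  for (b in bodies) rec[b] <- TRUE
  don <- matrix(FALSE, shape[1], shape[2])
  interior1 <- tntquant:::rasterize_disk(c(60, 60), 3, shape)        # ~7 µm²
  interior3a <- tntquant:::rasterize_disk(c(150, 100), 3, shape)
  interior3b <- tntquant:::rasterize_disk(c(172, 125), 2, shape)
  edge2 <- tntquant:::rasterize_disk(c(60, 185), 3, shape)           # straddles
  oversize3 <- tntquant:::rasterize_disk(c(160, 95) + 15, 8, shape)  # ~50 µm²
  outside <- tntquant:::rasterize_disk(c(20, 200), 3, shape)
  for (p in list(interior1, interior3a, interior3b, edge2, oversize3,
                 outside)) don[p] <- TRUE
  list(recipient = flat_image(rec, ps, channel = "recipient"),
       donor = flat_image(don, ps, channel = "donor"),
       donor_mask = don, shape = shape)
}

default_cfg <- function(...) {
  transfer_config(background = estimate_background(NULL, "manual",
                                                   param = 500), ...)
}

test_that("blank channels yield no ROIs and a missing summary", {
  blank <- calibrated_image(matrix(0, 50, 50), 0.5, "recipient")
  cfg <- default_cfg()
  rois <- recipient_rois(blank, cfg)
  expect_equal(length(rois), 0L)
  ta <- classify_recipients(rois, calibrated_image(matrix(0, 50, 50), 0.5,
                                                   "donor"), cfg)
  expect_true(is.na(ta$summary$percent))
  expect_equal(ta$summary$n, 0L)
})

test_that("recipient ROIs respect the µm² minimum, not the pixel count", {
  fx <- make_transfer_fixture()
  cfg <- default_cfg()
  rois <- recipient_rois(fx$recipient, cfg)
  expect_equal(length(rois), 3L)
  # debris below 100 µm² is dropped
  rec2 <- fx$recipient
  small <- tntquant:::rasterize_disk(c(200, 30), 5, fx$shape)  # ~20 µm²
  rec2$pixels[small] <- 1000
  expect_equal(length(recipient_rois(rec2, cfg)), 3L)
  # same raster at double resolution (half pixel size): same ROI count
  up <- rec2$pixels[rep(seq_len(220), each = 2), rep(seq_len(220), each = 2)]
  rois_up <- recipient_rois(calibrated_image(up, 0.25, "recipient"), cfg)
  expect_equal(length(rois_up), 3L)
})

test_that("interior, edge and oversize donor signal is triaged exactly", {
  fx <- make_transfer_fixture()
  cfg <- default_cfg()
  rois <- recipient_rois(fx$recipient, cfg)
  ta <- classify_recipients(rois, fx$donor, cfg)
  r <- ta$recipients
  expect_equal(sum(r$n_puncta), 3L)            # 1 in cell A, 2 in cell C
  expect_equal(sum(r$excluded_boundary), 1L)   # the straddling punctum
  expect_equal(sum(r$excluded_oversize), 1L)
  # identify ROIs by centroid: A ~ (60,60), B ~ (60,160), C ~ (160,110)
  whois <- function(rc) which.min(vapply(rois$regions, function(g)
    sum((g$centroid - rc)^2), numeric(1)))
  expect_true(r$positive[whois(c(60, 60))])
  expect_false(r$positive[whois(c(60, 160))])
  expect_true(r$positive[whois(c(160, 110))])
  expect_equal(ta$summary$percent, 100 * 2 / 3)
  # per-ROI detail via detect_puncta agrees for the edge-punctum cell
  det <- detect_puncta(fx$donor, rois$regions[[whois(c(60, 160))]], cfg)
  expect_equal(length(det$accepted), 0L)
  expect_equal(det$excluded_boundary, 1L)
})

test_that("donor signal outside every ROI never changes results", {
  fx <- make_transfer_fixture()
  cfg <- default_cfg()
  rois <- recipient_rois(fx$recipient, cfg)
  base <- classify_recipients(rois, fx$donor, cfg)
  more <- fx$donor
  extra <- tntquant:::rasterize_disk(c(200, 200), 4, fx$shape)
  more$pixels[extra] <- 1000
  again <- classify_recipients(rois, more, cfg)
  expect_equal(again$recipients, base$recipients)
  expect_equal(again$summary$percent, base$summary$percent)
})

test_that("accepted puncta lie strictly inside the eroded ROI interior", {
  fx <- make_transfer_fixture()
  cfg <- default_cfg(boundary_width = 2L)
  rois <- recipient_rois(fx$recipient, cfg)
  ta <- classify_recipients(rois, fx$donor, cfg)
  for (i in seq_along(rois$regions)) {
    roimask <- tntquant:::region_mask(rois$regions[[i]], fx$shape)
    interior <- erode_mask(roimask, morphology_config("square3x3", 1L),
                           passes = 2L)
    for (p in ta$results[[i]]$accepted$regions)
      expect_true(all(interior[p$pixels]))
  }
})

test_that("loosening the size cap and narrowing the margin are monotone", {
  fx <- make_transfer_fixture()
  rois <- recipient_rois(fx$recipient, default_cfg())
  n_for <- function(...) {
    ta <- classify_recipients(rois, fx$donor, default_cfg(...))
    sum(ta$recipients$n_puncta)
  }
  expect_lte(n_for(punctum_max_area = 10), n_for(punctum_max_area = 25))
  expect_lte(n_for(punctum_max_area = 25), n_for(punctum_max_area = 60))
  expect_gte(n_for(boundary_width = 0L), n_for(boundary_width = 1L))
  expect_gte(n_for(boundary_width = 1L), n_for(boundary_width = 4L))
})

test_that("generator scenes reproduce their ground-truth transfer counts", {
  sp <- scene_spec(seed = 21, field_size = 768, n_macrophages = 0,
                   n_fibroblasts = 6, n_interior_puncta = 8,
                   n_edge_puncta = 2, n_oversize_blobs = 1,
                   recipient_positive_fraction = 0.5)
  sc <- generate_scene(sp)
  ctrl <- generate_control(scene_spec(seed = 600, field_size = 512))
  cfg <- transfer_config(background = estimate_background(ctrl, "percentile",
                                                          99.9))
  rois <- recipient_rois(sc$recipient, cfg)
  expect_equal(length(rois), 6L)
  ta <- classify_recipients(rois, sc$donor, cfg)
  gt <- sc$ground_truth$recipients
  expect_equal(sum(ta$recipients$n_puncta),
               sum(lengths(lapply(gt, `[[`, "interior"))))
  expect_equal(sum(ta$recipients$excluded_boundary), 2L)
  expect_equal(sum(ta$recipients$excluded_oversize), 1L)
  expect_equal(ta$summary$percent,
               100 * mean(vapply(gt, `[[`, logical(1), "positive")))
})

test_that("config invariants are enforced", {
  bg <- estimate_background(NULL, "manual", param = 10)
  expect_error(transfer_config(), "background")
  expect_error(transfer_config(bg, punctum_max_area = 200,
                               recipient_min_area = 100), "smaller")
  expect_error(transfer_config(bg, punctum_max_area = -5), "positive")
})
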