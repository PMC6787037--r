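test_that("a rasterized disk reads as circular and isotropic", {
  m <- disk_mask(50L)
  d <- measure_region(m, pixel_size = 0.5)
  expect_gte(d$circularity, 0.95)
  expect_lte(d$circularity, 1.02)
  expect_gte(d$aspect_ratio, 1.0)
  expect_lte(d$aspect_ratio, 1.05)
})

test_that("solid rectangles match their closed forms", {
  for (s in c(0.5, 1.0)) {
    for (wh in list(c(10L, 4L), c(30L, 6L), c(25L, 25L), c(60L, 3L))) {
      w <- wh[1]; h <- wh[2]
      d <- measure_region(rect_mask(w, h), pixel_size = s)
      expect_equal(d$area_um2, w * h * s^2)
      expect_lt(abs(d$length_um - s * sqrt(w^2 + h^2)), s * 1.0)
      expect_lt(abs(d$box_area_ratio - 1), 0.02)
    }
  }
})

test_that("descriptors match brute-force oracles on random polyominoes", {
  set.seed(31)
  for (i in 1:40) {
    # random connected blob: dilate a few seeds, then take one component
    m <- matrix(runif(24 * 24) < 0.04, 24, 24)
    m <- oracle_dilate(m, se_offsets("square3x3"))
    lab <- oracle_label(m, 8L)
    if (max(lab) == 0) next
    m <- lab == 1L
    if (sum(m) < 2 || sum(m) > 500) next
    rows <- ((which(m) - 1L) %% nrow(m)) + 1L
    cols <- ((which(m) - 1L) %/% nrow(m)) + 1L
    d <- measure_region(m, pixel_size = 0.5)
    expect_equal(d$length_um, 0.5 * oracle_feret(rows, cols))
    expect_equal(d$aspect_ratio, oracle_aspect(rows, cols))
    expect_equal(d$circularity,
                 sum(m) / (pi / 4 * oracle_feret(rows, cols)^2))
  }
})

test_that("descriptors are scale-equivariant in pixel_size", {
  m <- ellipse_mask(30, 12, theta = 0.6)
  d1 <- measure_region(m, pixel_size = 0.5)
  d2 <- measure_region(m, pixel_size = 1.0)
  expect_equal(d2$length_um, 2 * d1$length_um)
  expect_equal(d2$area_um2, 4 * d1$area_um2)
  expect_equal(d2$circularity, d1$circularity)
  expect_equal(d2$aspect_ratio, d1$aspect_ratio)
  expect_equal(d2$box_area_ratio, d1$box_area_ratio)
})

test_that("circularity and aspect ratio are rotation-tolerant on ellipses", {
  angles <- seq(0, pi / 2, length.out = 7)
  d <- do.call(rbind, lapply(angles, function(th)
    measure_region(ellipse_mask(50, 20, theta = th), pixel_size = 0.5)))
  expect_lt(diff(range(d$circularity)) / mean(d$circularity), 0.03)
  expect_lt(diff(range(d$aspect_ratio)) / mean(d$aspect_ratio), 0.03)
})

test_that("elongating a rectangle raises aspect ratio and lowers circularity", {
  lens <- c(10L, 20L, 40L, 80L, 120L)
  d <- do.call(rbind, lapply(lens, function(L)
    measure_region(rect_mask(L, 6L), pixel_size = 0.5)))
  expect_true(all(diff(d$aspect_ratio) > 0))
  expect_true(all(diff(d$circularity) < 0))
})

test_that("hull-based Feret equals the all-pairs oracle", {
  set.seed(37)
  for (i in 1:25) {
    m <- matrix(runif(20 * 20) < 0.3, 20, 20)
    if (sum(m) < 2 || sum(m) > 500) next
    rows <- ((which(m) - 1L) %% 20L) + 1L
    cols <- ((which(m) - 1L) %/% 20L) + 1L
    expect_equal(tntquant:::feret_diameter_px(rows, cols),
                 oracle_feret(rows, cols))
  }
})

test_that("single-pixel regions are flagged and excluded from summaries", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  d <- measure_region(m, pixel_size = 0.5)
  expect_true(d$degenerate)
  expect_equal(d$area_um2, 0.25)
  expect_true(is.na(d$length_um))
  s <- summarize_descriptors(rbind(d, measure_region(rect_mask(8, 4),
                                                     pixel_size = 0.5)))
  expect_true(all(s$n == 1))     # only the rectangle survives
})

test_that("cut lines split regions as drawn", {
  # diametral cut through a disk: two near-equal halves
  m <- disk_mask(20L)
  n <- nrow(m)
  cut <- list(polyline = rbind(c(1, (n + 1) / 2), c(n, (n + 1) / 2)))
  rs <- apply_cut_lines(m, list(cut), pixel_size = 0.5)
  expect_equal(length(rs), 2L)
  areas <- sort(vapply(rs$regions, function(r) r$area_um2, numeric(1)))
  expect_lt(diff(areas) / mean(areas), 0.12)
  roles <- vapply(rs$regions, function(r) r$role, character(1))
  expect_setequal(roles, c("body", "protrusion-candidate"))

  # empty cut list: identity
  rs0 <- apply_cut_lines(m, list(), pixel_size = 0.5)
  expect_equal(length(rs0), 1L)
  expect_equal(rs0$regions[[1]]$role, "body")

  # a cut that removes nothing connected: still one component
  miss <- list(polyline = rbind(c(1, 1), c(1, n)))
  expect_equal(length(apply_cut_lines(m, list(miss), pixel_size = 0.5)), 1L)
})

test_that("cutting a ribbon neck recovers the ground-truth protrusion area", {
  fx <- cell_with_ribbon(body_r = 20L, rib_len = 60, rib_w = 6,
                         angle = 0)
  # cut across the ribbon just outside the body
  ctr <- fx$shape / 2
  x <- ctr[2] + 20 + 2
  cut <- list(polyline = rbind(c(ctr[1] - 8, x), c(ctr[1] + 8, x)),
              width = 1)
  rs <- apply_cut_lines(fx$mask, list(cut), pixel_size = 0.5)
  expect_equal(length(rs), 2L)
  cand <- Filter(function(r) r$role == "protrusion-candidate", rs$regions)
  expect_equal(length(cand), 1L)
  gt_area <- length(fx$ribbon) * 0.25
  expect_lt(abs(cand[[1]]$area_um2 - gt_area) / gt_area, 0.08)
})

test_that("summaries report mean and sample SD per group without pruning", {
  set.seed(41)
  areas <- rnorm(200, 380, 145)
  d <- data.frame(area_um2 = areas, length_um = 1, circularity = 0.5,
                  circularity_capped = 0.5, aspect_ratio = 2,
                  box_area_ratio = 2, n_px = 10, degenerate = FALSE)
  s <- summarize_descriptors(d, vars = "area_um2")
  expect_equal(s$mean, mean(areas))
  expect_equal(s$sd, sd(areas))
  expect_equal(s$n, 200L)
  # recovered within 3 standard errors of the generating mean
  expect_lt(abs(s$mean - 380), 3 * 145 / sqrt(200))
  # identical groups give identical summaries
  s2 <- summarize_descriptors(rbind(d, d), group = rep(c("a", "b"),
                                                       each = 200),
                              vars = "area_um2")
  expect_equal(s2$mean[1], s2$mean[2])
  expect_equal(s2$sd[1], s2$sd[2])
})
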