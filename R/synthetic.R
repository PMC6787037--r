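#' Synthetic co-culture scene specification
#'
#' Parameters of the seeded scene generator.  A scene emulates a wide-field
#' two-population co-culture micrograph: eGFP-labeled macrophage bodies
#' (rasterized ellipses, 150-600 µm²), a fraction of which bear one thin
#' TNT-like ribbon (stroked quadratic Bezier, default width 2 µm, length
#' 45 ± 15 µm truncated at >= 15 µm); DsRed-labeled fibroblast bodies
#' (ellipses >= the recipient area filter); and donor puncta (disks,
#' 2-20 µm²) placed in the interior, at the boundary, or — as oversize
#' blobs — inside recipient cells.  Images are object intensity plus
#' Gaussian background noise (optionally Poisson photon noise) on a 16-bit
#' scale.  Every placed object is recorded in the ground truth.
#'
#' Geometry defaults echo the scale of real macrophage protrusion data
#' (mean length ~45 µm, width ~2 µm, puncta up to 20 µm²) so that default
#' scenes exercise all size/shape filters near their thresholds.
#'
#' @param seed integer RNG seed (mandatory; scenes are bit-reproducible).
#' @param field_size raster size in pixels, `c(rows, cols)` or a scalar.
#' @param pixel_size µm per pixel (default 0.5).
#' @param n_macrophages,n_fibroblasts object counts.
#' @param protrusion_prevalence per-cell probability of bearing a ribbon.
#' @param protrusion_length_um `c(mean, sd)` of ribbon length in µm.
#' @param protrusion_min_length_um truncation floor for ribbon length.
#' @param protrusion_width_um ribbon width in µm.
#' @param ribbon_bend Bezier control-point offset as a fraction of length
#'   (bounded so the caliper length stays >= 0.9 of arc length); 0 gives
#'   straight ribbons.
#' @param macrophage_area_um2,fibroblast_area_um2 body-area ranges in µm².
#' @param recipient_positive_fraction fraction of fibroblasts receiving
#'   interior donor puncta.
#' @param n_interior_puncta total interior puncta across positive
#'   recipients (NULL: draw per recipient from `puncta_per_positive`).
#' @param puncta_per_positive integer range of puncta per positive
#'   recipient when `n_interior_puncta` is NULL.
#' @param punctum_area_um2 punctum area range in µm².
#' @param n_edge_puncta number of boundary-straddling puncta (recipients
#'   cycled through).
#' @param n_oversize_blobs number of oversize interior blobs.
#' @param oversize_area_um2 area of each oversize blob (default 40 µm²).
#' @param background `c(mean, sd)` of the Gaussian background in detector
#'   units.
#' @param foreground object intensity added above background.
#' @param photon_noise add Poisson noise on top (default FALSE).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(seed,
                       field_size = c(1024L, 1024L),
                       pixel_size = 0.5,
                       n_macrophages = 30L,
                       n_fibroblasts = 20L,
                       protrusion_prevalence = 0.4,
                       protrusion_length_um = c(mean = 45, sd = 15),
                       protrusion_min_length_um = 15,
                       protrusion_width_um = 2,
                       ribbon_bend = 0.15,
                       macrophage_area_um2 = c(150, 600),
                       fibroblast_area_um2 = c(400, 1500),
                       recipient_positive_fraction = 0.5,
                       n_interior_puncta = NULL,
                       puncta_per_positive = c(1L, 4L),
                       punctum_area_um2 = c(2, 20),
                       n_edge_puncta = 0L,
                       n_oversize_blobs = 0L,
                       oversize_area_um2 = 40,
                       background = c(mean = 100, sd = 10),
                       foreground = 1000,
                       photon_noise = FALSE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("'seed' is mandatory")
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  check_pixel_size(pixel_size)
  if (protrusion_prevalence < 0 || protrusion_prevalence > 1)
    stop("protrusion_prevalence must lie in [0, 1]")
  if (recipient_positive_fraction < 0 || recipient_positive_fraction > 1)
    stop("recipient_positive_fraction must lie in [0, 1]")
  stopifnot(protrusion_width_um > 0, protrusion_min_length_um > 0,
            all(macrophage_area_um2 > 0), all(fibroblast_area_um2 > 0),
            all(punctum_area_um2 > 0), oversize_area_um2 > 0,
            foreground > 0, background[2] >= 0, ribbon_bend >= 0,
            ribbon_bend <= 0.25)
  structure(as.list(environment()), class = "scene_spec")
}

# ---- raster primitives ----------------------------------------------------

# Linear indices of a filled rotated ellipse (pixel-center rasterization).
rasterize_ellipse <- function(center, a, b, theta, shape) {
  r0 <- max(1L, floor(center[1] - a - 1)); r1 <- min(shape[1], ceiling(center[1] + a + 1))
  c0 <- max(1L, floor(center[2] - a - 1)); c1 <- min(shape[2], ceiling(center[2] + a + 1))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- rep(rr - center[1], times = length(cc))
  dx <- rep(cc - center[2], each = length(rr))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  rows <- rep(rr, times = length(cc))[inside]
  cols <- rep(cc, each = length(rr))[inside]
  (cols - 1L) * shape[1] + rows
}

# Linear indices of a filled disk.
rasterize_disk <- function(center, radius, shape) {
  rasterize_ellipse(center, radius, radius, 0, shape)
}

#' Rasterize a stroked ribbon (quadratic Bezier with round caps)
#'
#' Pixels whose centers lie within `(width - 1)/2` of the curve from `p0` to
#' `p1` with control point `ctrl`, so the stroke spans exactly `width` pixels
#' across.  With `ctrl` on the segment the shape is a straight capsule whose
#' caliper length is the chord length plus the width (the two round caps).
#'
#' @param p0,p1 endpoints, `c(row, col)` in pixels.
#' @param ctrl Bezier control point (defaults to the midpoint: straight).
#' @param width stroke width in pixels.
#' @param shape raster dimensions.
#' @return Integer vector of linear pixel indices.
#' @export
rasterize_ribbon <- function(p0, p1, ctrl = (p0 + p1) / 2, width, shape) {
  chord <- sqrt(sum((p1 - p0)^2))
  n <- max(8L, ceiling(chord + 2 * sqrt(sum((ctrl - (p0 + p1) / 2)^2))))
  t <- seq(0, 1, length.out = n)
  py <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * ctrl[1] + t^2 * p1[1]
  px <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * ctrl[2] + t^2 * p1[2]
  # pixel-center geometry: centers within (width-1)/2 of the curve span
  # exactly `width` pixels across the stroke
  rad <- (width - 1) / 2
  r0 <- max(1L, floor(min(py) - rad - 1)); r1 <- min(shape[1], ceiling(max(py) + rad + 1))
  c0 <- max(1L, floor(min(px) - rad - 1)); c1 <- min(shape[2], ceiling(max(px) + rad + 1))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  gy <- rep(rr, times = length(cc))
  gx <- rep(cc, each = length(rr))
  # min squared distance from each grid point to the polyline through the
  # curve samples (exact point-to-segment distance, no sampling artifacts)
  d2 <- rep(Inf, length(gy))
  for (i in seq_len(n - 1L)) {
    ay <- py[i]; ax <- px[i]
    vy <- py[i + 1L] - ay; vx <- px[i + 1L] - ax
    len2 <- vy^2 + vx^2
    tt <- if (len2 > 0) pmin(pmax(((gy - ay) * vy + (gx - ax) * vx) / len2,
                                  0), 1) else 0
    di <- (gy - (ay + tt * vy))^2 + (gx - (ax + tt * vx))^2
    lt <- di < d2
    d2[lt] <- di[lt]
  }
  inside <- d2 <= rad^2 + 1e-9
  (gx[inside] - 1L) * shape[1] + gy[inside]
}

# Interior pixels of a pixel-index body at a given Chebyshev depth, via
# erosion of a cropped window (erosion is local, so crops are exact).
body_interior_of <- function(body_px, depth, nr) {
  rows <- ((body_px - 1L) %% nr) + 1L
  cols <- ((body_px - 1L) %/% nr) + 1L
  r0 <- min(rows); c0 <- min(cols)
  crop <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  crop[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  offs <- morphology_config("square3x3", 1L)$offsets
  for (i in seq_len(depth)) crop <- erode_once(crop, offs)
  w <- which(crop)
  if (length(w) == 0L) return(integer(0))
  cr <- ((w - 1L) %% nrow(crop)) + r0
  cc <- ((w - 1L) %/% nrow(crop)) + c0
  (cc - 1L) * nr + cr
}

# Occupancy bookkeeping: stamp indices plus a Chebyshev margin (dilation on
# a cropped window, so large margins stay cheap).
mark_occupied <- function(occ, idx, margin, shape) {
  nr <- shape[1]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  r0 <- max(1L, min(rows) - margin); r1 <- min(shape[1], max(rows) + margin)
  c0 <- max(1L, min(cols) - margin); c1 <- min(shape[2], max(cols) + margin)
  crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  crop[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  cfg <- morphology_config("square3x3", 1L)
  for (i in seq_len(margin)) crop <- dilate_once(crop, cfg$offsets)
  occ[r0:r1, c0:c1] <- occ[r0:r1, c0:c1] | crop
  occ
}

with_scene_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

# ---- scene generation -----------------------------------------------------

#' Generate a synthetic co-culture scene with exact ground truth
#'
#' Deterministic given the spec's seed.  Macrophage bodies (and their
#' ribbons) share the cell channel; fibroblast bodies form the recipient
#' channel; puncta plus background form the donor channel.  Objects within a
#' channel are placed with a safety margin so they never touch; a geometry
#' that cannot be placed raises an error naming the first offending object.
#'
#' @param spec a [scene_spec()].
#' @return Object of class `synthetic_scene`: list with `cell`, `donor`,
#'   `recipient` ([calibrated_image()]s), `pair` (a `channel_pair`),
#'   `ground_truth` and `spec`.  Ground truth holds, per macrophage, the
#'   body/protrusion pixel indices, the positive flag and the drawn ribbon
#'   geometry; per fibroblast, the body pixels and its interior / edge /
#'   oversize puncta (pixel indices and areas).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, {
    shape <- as.integer(spec$field_size)
    ps <- spec$pixel_size
    cell_mask <- matrix(FALSE, shape[1], shape[2])
    donor_mask <- matrix(FALSE, shape[1], shape[2])
    recip_mask <- matrix(FALSE, shape[1], shape[2])

    # --- macrophages + ribbons on the cell channel
    max_len_px <- (spec$protrusion_length_um[1] + 4 * spec$protrusion_length_um[2]) / ps
    occ <- matrix(FALSE, shape[1], shape[2])
    gt_cells <- vector("list", spec$n_macrophages)
    for (i in seq_len(spec$n_macrophages)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        A <- stats::runif(1, spec$macrophage_area_um2[1],
                          spec$macrophage_area_um2[2]) / ps^2
        q <- stats::runif(1, 1, 1.8)
        b <- sqrt(A / (pi * q)); a <- b * q
        th <- stats::runif(1, 0, pi)
        ctr <- c(stats::runif(1, a + 3, shape[1] - a - 2),
                 stats::runif(1, a + 3, shape[2] - a - 2))
        body <- rasterize_ellipse(ctr, a, b, th, shape)
        if (length(body) == 0L || any(occ[body])) next
        has_ribbon <- stats::runif(1) < spec$protrusion_prevalence
        ribbon <- integer(0); rib_len <- NA_real_
        if (has_ribbon) {
          ok_rib <- FALSE
          for (rtry in seq_len(60L)) {
            L <- stats::rnorm(1, spec$protrusion_length_um[1],
                              spec$protrusion_length_um[2])
            if (L < spec$protrusion_min_length_um || L / ps > max_len_px) next
            Lpx <- L / ps
            w <- spec$protrusion_width_um / ps
            phi <- stats::runif(1, 0, 2 * pi)
            # boundary point of the ellipse at parameter phi, then outward
            bp <- ctr + c(sin(th) * a * cos(phi) + cos(th) * b * sin(phi),
                          cos(th) * a * cos(phi) - sin(th) * b * sin(phi))
            d <- bp - ctr; d <- d / sqrt(sum(d^2))
            p0 <- bp - 3 * d
            p1 <- p0 + (Lpx + 3) * d
            if (any(p1 < w + 2) || p1[1] > shape[1] - w - 2 ||
                p1[2] > shape[2] - w - 2) next
            perp <- c(-d[2], d[1]) * sample(c(-1, 1), 1)
            ctrl <- (p0 + p1) / 2 + spec$ribbon_bend * Lpx * perp
            rib <- rasterize_ribbon(p0, p1, ctrl, w, shape)
            rib <- setdiff(rib, body)
            if (length(rib) == 0L || any(occ[rib])) next
            ribbon <- rib; rib_len <- L; ok_rib <- TRUE
            break
          }
          if (!ok_rib) next
        }
        cell_mask[body] <- TRUE
        cell_mask[ribbon] <- TRUE
        occ <- mark_occupied(occ, c(body, ribbon), 3L, shape)
        gt_cells[[i]] <- list(body = body, protrusions =
                                if (length(ribbon)) list(ribbon) else list(),
                              positive = has_ribbon,
                              length_um = rib_len,
                              width_um = spec$protrusion_width_um)
        placed <- TRUE
        break
      }
      if (!placed) stop("cannot place macrophage ", i, " in the field")
    }

    # --- fibroblasts on the recipient channel
    pmax_rad <- sqrt(max(spec$punctum_area_um2) / pi) / ps
    fib_margin <- as.integer(ceiling(2 * pmax_rad + 4))
    occ_f <- matrix(FALSE, shape[1], shape[2])
    gt_rec <- vector("list", spec$n_fibroblasts)
    for (i in seq_len(spec$n_fibroblasts)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        A <- stats::runif(1, spec$fibroblast_area_um2[1],
                          spec$fibroblast_area_um2[2]) / ps^2
        q <- stats::runif(1, 1, 1.6)
        b <- sqrt(A / (pi * q)); a <- b * q
        th <- stats::runif(1, 0, pi)
        ctr <- c(stats::runif(1, a + 3, shape[1] - a - 2),
                 stats::runif(1, a + 3, shape[2] - a - 2))
        body <- rasterize_ellipse(ctr, a, b, th, shape)
        if (length(body) == 0L || any(occ_f[body])) next
        recip_mask[body] <- TRUE
        occ_f <- mark_occupied(occ_f, body, fib_margin, shape)
        gt_rec[[i]] <- list(body = body, interior = list(), edge = list(),
                            oversize = list(), positive = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("cannot place fibroblast ", i, " in the field")
    }

    # --- donor puncta
    nrec <- spec$n_fibroblasts
    if (nrec > 0L) {
      n_pos <- round(spec$recipient_positive_fraction * nrec)
      pos_idx <- if (n_pos > 0L) sort(sample.int(nrec, n_pos)) else integer(0)
      counts <- integer(nrec)
      if (!is.null(spec$n_interior_puncta)) {
        N <- spec$n_interior_puncta
        if (N < length(pos_idx))
          stop("n_interior_puncta smaller than the number of positive recipients")
        if (length(pos_idx)) {
          counts[pos_idx] <- 1L
          extra <- N - length(pos_idx)
          if (extra > 0L) {
            # capacity-aware allocation: a stamped punctum blocks an
            # ~18x18 px neighbourhood of candidate centers (its size plus
            # the anti-merging spacing), so budget one punctum per ~350
            # pixels of the eroded interior
            w <- vapply(gt_rec[pos_idx], function(g)
              length(body_interior_of(g$body, 8L, shape[1])), numeric(1))
            cap <- pmax(1L, w %/% 200L)
            for (e in seq_len(extra)) {
              open <- which(counts[pos_idx] < cap)
              if (length(open) == 0L)
                stop("cannot fit ", N, " interior puncta: recipients full")
              pick <- if (length(open) == 1L) open else
                sample(open, 1L, prob = w[open])
              counts[pos_idx[pick]] <- counts[pos_idx[pick]] + 1L
            }
          }
        }
      } else if (length(pos_idx)) {
        counts[pos_idx] <- sample(seq(spec$puncta_per_positive[1],
                                      spec$puncta_per_positive[2]),
                                  length(pos_idx), replace = TRUE)
      }
      occ_p <- matrix(FALSE, shape[1], shape[2])
      nr <- shape[1]
      body_interior <- function(body_px, depth)
        body_interior_of(body_px, depth, nr)
      # place one disk with its center drawn from candidate pixels that are
      # not blocked by previously placed puncta; retries re-draw the area
      place_punctum <- function(j, kind, area_range = spec$punctum_area_um2,
                                fixed_area = NULL, on_boundary = FALSE) {
        body_px <- gt_rec[[j]]$body
        for (try in seq_len(80L)) {
          hi <- if (try > 20L && is.null(fixed_area))
            mean(area_range) else area_range[2]
          Apx <- if (!is.null(fixed_area)) fixed_area / ps^2
          else if (try > 50L) area_range[1] / ps^2
          else stats::runif(1, area_range[1], hi) / ps^2
          rad <- sqrt(Apx / pi)
          cand <- if (on_boundary) {
            setdiff(body_px, body_interior(body_px, 1L))
          } else {
            # clearance: punctum must stay >= boundary_width + ~4 px away
            # from the ROI edge so detector-noise bridges cannot reach the
            # boundary band
            body_interior(body_px, as.integer(ceiling(rad + 5)))
          }
          if (length(cand) == 0L) next
          ci <- cand[sample.int(length(cand), 1L)]
          ctr <- c(((ci - 1L) %% nr) + 1L, ((ci - 1L) %/% nr) + 1L)
          px <- rasterize_disk(ctr, rad, shape)
          # reject a draw whose pixels come within 4 px (Chebyshev) of an
          # existing punctum: supra-threshold noise cannot bridge that gap
          if (any(occ_p[px])) next
          return(px)
        }
        NULL
      }
      stamp <- function(px) {
        donor_mask[px] <<- TRUE
        occ_p <<- mark_occupied(occ_p, px, 4L, shape)
      }
      for (j in seq_len(nrec)) {
        for (k in seq_len(counts[j])) {
          px <- place_punctum(j, "interior")
          if (is.null(px))
            stop("cannot place interior punctum ", k, " in recipient ", j)
          stamp(px)
          gt_rec[[j]]$interior <- c(gt_rec[[j]]$interior,
                                    list(list(pixels = px,
                                              area_um2 = length(px) * ps^2)))
          gt_rec[[j]]$positive <- TRUE
        }
      }
      if (spec$n_edge_puncta > 0L) {
        targets <- rep_len(seq_len(nrec), spec$n_edge_puncta)
        for (k in seq_len(spec$n_edge_puncta)) {
          px <- place_punctum(targets[k], "edge", on_boundary = TRUE)
          if (is.null(px))
            stop("cannot place edge punctum ", k, " in recipient ",
                 targets[k])
          stamp(px)
          gt_rec[[targets[k]]]$edge <-
            c(gt_rec[[targets[k]]]$edge,
              list(list(pixels = px, area_um2 = length(px) * ps^2)))
        }
      }
      if (spec$n_oversize_blobs > 0L) {
        # biggest recipients first: oversize blobs need deep interiors
        areas <- vapply(gt_rec, function(g) length(g$body), numeric(1))
        order_big <- order(areas, decreasing = TRUE)
        for (k in seq_len(spec$n_oversize_blobs)) {
          px <- NULL
          for (j in rep_len(order_big, length(order_big) * 2L)) {
            px <- place_punctum(j, "oversize",
                                fixed_area = spec$oversize_area_um2)
            if (!is.null(px)) { target <- j; break }
          }
          if (is.null(px)) stop("cannot place oversize blob ", k)
          stamp(px)
          gt_rec[[target]]$oversize <-
            c(gt_rec[[target]]$oversize,
              list(list(pixels = px, area_um2 = length(px) * ps^2)))
        }
      }
    }

    # --- rendering
    render <- function(mask) {
      img <- stats::rnorm(length(mask), spec$background[1], spec$background[2])
      img[mask] <- img[mask] + spec$foreground
      if (spec$photon_noise) img <- stats::rpois(length(img), pmax(img, 0))
      m <- matrix(pmin(pmax(round(img), 0), 65535), shape[1], shape[2])
      m
    }
    cell_img <- calibrated_image(render(cell_mask), ps, "cell")
    donor_img <- calibrated_image(render(donor_mask), ps, "donor")
    recip_img <- calibrated_image(render(recip_mask), ps, "recipient")

    gt <- list(cells = gt_cells, recipients = gt_rec,
               field = list(shape = shape, pixel_size = ps,
                            seed = spec$seed))
    structure(list(cell = cell_img, donor = donor_img,
                   recipient = recip_img,
                   pair = structure(list(donor = donor_img,
                                         recipient = recip_img),
                                    class = "channel_pair"),
                   ground_truth = gt, spec = spec),
              class = "synthetic_scene")
  })
}

#' Generate a donor-free control image
#'
#' Background noise only, at the spec's calibration: the input for
#' [estimate_background()] and for false-positive control experiments.
#'
#' @param spec a [scene_spec()].
#' @return A donor-tagged [calibrated_image()] containing only background.
#' @export
generate_control <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_scene_seed(spec$seed, {
    shape <- as.integer(spec$field_size)
    img <- stats::rnorm(prod(shape), spec$background[1], spec$background[2])
    m <- matrix(pmin(pmax(round(img), 0), 65535), shape[1], shape[2])
    calibrated_image(m, spec$pixel_size, "donor")
  })
}

#' Write a synthetic scene to disk
#'
#' Emits the three channels as 16-bit TIFFs, ground-truth label images
#' (macrophage bodies+ribbons; fibroblast bodies; puncta) and a JSON
#' ground-truth summary.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(scene$cell, file.path(dir, "cell.tif"))
  write_image(scene$donor, file.path(dir, "donor.tif"))
  write_image(scene$recipient, file.path(dir, "recipient.tif"))
  shape <- scene$ground_truth$field$shape
  lab <- function(objs, field) {
    m <- matrix(0, shape[1], shape[2])
    for (i in seq_along(objs)) for (px in objs[[i]][[field]]) {
      if (is.list(px)) px <- px$pixels
      m[px] <- i
    }
    m
  }
  body_lab <- matrix(0, shape[1], shape[2])
  prot_lab <- matrix(0, shape[1], shape[2])
  for (i in seq_along(scene$ground_truth$cells)) {
    g <- scene$ground_truth$cells[[i]]
    body_lab[g$body] <- i
    for (px in g$protrusions) prot_lab[px] <- i
  }
  tiff::writeTIFF(body_lab / 65535, file.path(dir, "gt_macrophage_bodies.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(prot_lab / 65535, file.path(dir, "gt_protrusions.tif"),
                  bits.per.sample = 16L)
  gt_json <- list(
    field = scene$ground_truth$field,
    cells = lapply(scene$ground_truth$cells, function(g)
      list(positive = g$positive, n_protrusions = length(g$protrusions),
           body_area_um2 = length(g$body) * scene$cell$pixel_size^2,
           length_um = g$length_um)),
    recipients = lapply(scene$ground_truth$recipients, function(g)
      list(positive = g$positive,
           n_interior = length(g$interior), n_edge = length(g$edge),
           n_oversize = length(g$oversize),
           body_area_um2 = length(g$body) * scene$recipient$pixel_size^2)))
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
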