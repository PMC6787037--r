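# Maximum Feret diameter (caliper length) of a pixel set, in pixels.
# Computed over the pixel *corner* points (each pixel (r, c) contributes its
# four corners at r +/- 0.5, c +/- 0.5): the caliper of the rasterized shape
# as a union of unit squares.  The convex hull is taken first, then the exact
# maximum over all hull-vertex pairs, so no orientation sampling is involved.
# For a w x h axis-aligned rectangle this yields exactly sqrt(w^2 + h^2).
feret_diameter_px <- function(rows, cols) {
  n <- length(rows)
  if (n == 0L) return(NA_real_)
  pr <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  pc <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  pts <- unique(cbind(pr, pc))
  if (nrow(pts) > 2L) {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    pts <- pts[h, , drop = FALSE]
  }
  m <- nrow(pts)
  if (m == 1L) return(0)
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

# Equivalent-ellipse aspect ratio from second central moments of the pixel
# centers.  Each pixel contributes 1/12 to both diagonal moments (the
# variance of a unit square about its center), which keeps 1-px-wide regions
# finite.
ellipse_aspect_ratio <- function(rows, cols) {
  n <- length(rows)
  if (n < 2L) return(NA_real_)
  mu_rr <- sum((rows - mean(rows))^2) / n + 1 / 12
  mu_cc <- sum((cols - mean(cols))^2) / n + 1 / 12
  mu_rc <- sum((rows - mean(rows)) * (cols - mean(cols))) / n
  tr <- mu_rr + mu_cc
  det <- mu_rr * mu_cc - mu_rc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l2 <= 0) return(Inf)
  sqrt(l1 / l2)
}

#' Shape descriptors of a region
#'
#' Computes the descriptor set used to recognize thin protrusions:
#'
#' * `area_um2`: pixel count times the squared pixel size.
#' * `length_um`: maximum Feret diameter (caliper length), exact over the
#'   convex hull of the pixel corner points.
#' * `circularity`: region area divided by the area of a circle whose
#'   diameter equals the maximum Feret diameter; 1 for a disk, small for
#'   elongated objects.  Values slightly above 1 can arise from
#'   rasterization; [measure_region()] reports the raw value and a capped
#'   copy (`circularity_capped`, clamped to \[0, 1.05\]) for display.
#' * `aspect_ratio`: major/minor axis ratio of the ellipse with the same
#'   second central moments as the pixel set (>= 1).
#' * `box_area_ratio`: axis-aligned bounding-box area over region area
#'   (>= 1); large for elongated or bent shapes.
#'
#' Single-pixel regions have a defined area but undefined length, circularity
#' and aspect ratio; they are flagged `degenerate` and excluded from
#' summaries.
#'
#' @param region a region (list with `pixels`) from a `region_set`, or a
#'   logical matrix / [binary_mask()].
#' @param pixel_size calibration in micrometres per pixel (taken from a
#'   `binary_mask` input when omitted).
#' @param shape raster dimensions, required when `region` is a region whose
#'   pixel indices must be decoded; defaults are inferred where possible.
#' @return One-row data.frame with `area_um2`, `length_um`, `circularity`,
#'   `circularity_capped`, `aspect_ratio`, `box_area_ratio`, `n_px`,
#'   `degenerate`.
#' @export
measure_region <- function(region, pixel_size = NULL, shape = NULL) {
  if (inherits(region, "binary_mask")) {
    pixel_size <- region$pixel_size
    idx <- which(region$pixels)
    nr <- nrow(region$pixels)
  } else if (is.matrix(region)) {
    check_pixel_size(pixel_size)
    idx <- which(region != 0)
    nr <- nrow(region)
  } else {
    check_pixel_size(pixel_size)
    if (is.null(shape))
      stop("'shape' (source raster dimensions) is required for a region input")
    nr <- shape[1]
    idx <- region$pixels
  }
  if (length(idx) == 0L) stop("region has no pixels")
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  measure_pixels(rows, cols, pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measure_pixels <- function(rows, cols, pixel_size) {
  n <- length(rows)
  area <- n * pixel_size^2
  if (n < 2L) {
    return(data.frame(area_um2 = area, length_um = NA_real_,
                      circularity = NA_real_, circularity_capped = NA_real_,
                      aspect_ratio = NA_real_, box_area_ratio = NA_real_,
                      n_px = n, degenerate = TRUE))
  }
  feret_px <- feret_diameter_px(rows, cols)
  circ <- n / (pi / 4 * feret_px^2)
  bbox_px <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1)
  data.frame(area_um2 = area,
             length_um = feret_px * pixel_size,
             circularity = circ,
             circularity_capped = min(max(circ, 0), 1.05),
             aspect_ratio = ellipse_aspect_ratio(rows, cols),
             box_area_ratio = bbox_px / n,
             n_px = n, degenerate = FALSE)
}

#' Measure every region of a region set
#'
#' @param regions a `region_set`.
#' @return data.frame with one row per region (label plus all
#'   [measure_region()] descriptors).
#' @export
measure_regions <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  nr <- regions$source_shape[1]
  out <- lapply(regions$regions, function(r) {
    rows <- ((r$pixels - 1L) %% nr) + 1L
    cols <- ((r$pixels - 1L) %/% nr) + 1L
    cbind(label = r$label, measure_pixels(rows, cols, regions$pixel_size))
  })
  if (length(out) == 0L)
    return(cbind(label = integer(0),
                 measure_pixels(c(1, 2), c(1, 1), regions$pixel_size)[0, ]))
  do.call(rbind, out)
}

#' Cut-line separation of protrusions from a cell body
#'
#' Removes the pixels under each polyline from the region mask and re-labels
#' the remainder.  The largest surviving component is tagged `"body"`, all
#' others `"protrusion-candidate"` — mirroring the manual workflow of cutting
#' a protrusion off along the estimated normal membrane curvature and
#' measuring the separated piece.
#'
#' @param cell a region (list with `pixels`), [binary_mask()], or logical
#'   matrix.
#' @param cuts list of cut lines; each either a two-column matrix of (row,
#'   col) vertices or a list with `polyline` (such a matrix) and optional
#'   `width` in pixels (default 1).
#' @param shape,pixel_size as in [extract_residue()].
#' @param connectivity labeling connectivity for the pieces (default 8).
#' @return A `region_set` whose regions carry a `role` field; a cut that
#'   disconnects nothing returns the single original component.
#' @export
apply_cut_lines <- function(cell, cuts = list(), shape = NULL,
                            pixel_size = NULL, connectivity = 8L) {
  if (inherits(cell, "binary_mask")) {
    m <- cell$pixels; pixel_size <- cell$pixel_size
  } else if (is.matrix(cell)) {
    m <- cell; storage.mode(m) <- "logical"
    check_pixel_size(pixel_size)
  } else {
    if (is.null(shape)) stop("'shape' required for a region input")
    check_pixel_size(pixel_size)
    m <- region_mask(cell, shape)
  }
  for (cut in cuts) {
    if (is.list(cut) && !is.null(cut$polyline)) {
      poly <- cut$polyline; width <- cut$width %||% 1
    } else {
      poly <- cut; width <- 1
    }
    poly <- as.matrix(poly)
    if (nrow(poly) < 2L) stop("a cut line needs at least 2 vertices")
    if (any(poly[, 1] < 1 | poly[, 1] > nrow(m) |
            poly[, 2] < 1 | poly[, 2] > ncol(m)))
      stop("cut line leaves the raster")
    m[rasterize_polyline(poly, width, dim(m))] <- FALSE
  }
  labels <- label_components(m, connectivity)
  rs <- region_set_from_labels(labels, pixel_size, connectivity)
  if (length(rs$regions)) {
    areas <- vapply(rs$regions, function(r) r$area_um2, numeric(1))
    body <- which.max(areas)
    for (i in seq_along(rs$regions))
      rs$regions[[i]]$role <- if (i == body) "body" else "protrusion-candidate"
  }
  rs
}

# Linear indices of the pixels under a polyline stroked at the given width.
rasterize_polyline <- function(poly, width, shape) {
  pts <- NULL
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) * 4))
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, cbind(a[1] + t * (b[1] - a[1]),
                            a[2] + t * (b[2] - a[2])))
  }
  px <- unique(round(pts))
  if (width > 1) {
    rad <- (width - 1) / 2
    o <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                     dc = -ceiling(rad):ceiling(rad))
    o <- o[o$dr^2 + o$dc^2 <= (rad + 0.5)^2, ]
    px <- unique(do.call(rbind, lapply(seq_len(nrow(o)), function(i)
      cbind(px[, 1] + o$dr[i], px[, 2] + o$dc[i]))))
  }
  keep <- px[, 1] >= 1 & px[, 1] <= shape[1] &
    px[, 2] >= 1 & px[, 2] <= shape[2]
  px <- px[keep, , drop = FALSE]
  (px[, 2] - 1L) * shape[1] + px[, 1]
}

#' Group-wise descriptor summary
#'
#' Arithmetic mean and sample standard deviation (n − 1 denominator) of each
#' descriptor per group.  No outlier removal is applied.  Degenerate
#' (single-pixel) regions are dropped first; groups with a single member get
#' `sd = 0` and `single_n = TRUE`.
#'
#' @param descriptors data.frame from [measure_regions()] (or rbind of
#'   [measure_region()] rows).
#' @param group optional grouping labels (recycled to rows); default one
#'   group `"all"`.
#' @param vars descriptor columns to summarize.
#' @return data.frame with group, descriptor, n, mean, sd, single_n.
#' @export
summarize_descriptors <- function(descriptors, group = NULL,
                                  vars = c("area_um2", "length_um",
                                           "circularity", "aspect_ratio",
                                           "box_area_ratio")) {
  if (is.null(group)) group <- rep("all", nrow(descriptors))
  group <- rep_len(as.character(group), nrow(descriptors))
  keep <- !descriptors$degenerate
  descriptors <- descriptors[keep, , drop = FALSE]
  group <- group[keep]
  out <- NULL
  for (g in unique(group)) {
    d <- descriptors[group == g, , drop = FALSE]
    if (nrow(d) == 0L) next
    for (v in vars) {
      x <- d[[v]]
      x <- x[is.finite(x)]
      if (length(x) == 0L) next
      out <- rbind(out, data.frame(
        group = g, descriptor = v, n = length(x), mean = mean(x),
        sd = if (length(x) > 1L) stats::sd(x) else 0,
        single_n = length(x) == 1L))
    }
  }
  out %||% data.frame(group = character(0), descriptor = character(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0),
                      single_n = logical(0))
}
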