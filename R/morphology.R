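#' Morphological opening configuration
#'
#' The protrusion detector isolates thin appendages as the residue of an
#' iterated binary opening of the cell mask: `passes` erosions followed by the
#' same number of dilations with one structuring element (SE).  Structures
#' whose half-width (in pixels) is at most roughly `passes` times the SE
#' extent are removed by the erosions and not restored by the dilations, so
#' they end up in the residue.
#'
#' Two SEs are offered.  `square3x3` (the default) is the centred 3x3 square.
#' `square2x2` is the even-sized 2x2 square with a fixed anchor rule: the SE
#' offset set is \{(0,0), (0,1), (1,0), (1,1)\} for erosion and its reflection
#' for dilation, which makes the composite a true opening (anti-extensive)
#' despite the SE having no central pixel.
#'
#' `captured_width_um(cfg, pixel_size)` reports the approximate maximum
#' structure width captured in the residue, `2 * passes * pixel_size` for the
#' 3x3 SE and `passes * pixel_size` for the 2x2 SE, so the pixel-space
#' `passes` parameter can be rescaled to other calibrations.
#'
#' @param se structuring element, `"square3x3"` or `"square2x2"`.
#' @param passes number of erosion passes (>= 1); default 7.
#' @param dilation_passes number of dilation passes; defaults to `passes`
#'   (a true opening).
#' @return Object of class `morphology_config`.
#' @export
morphology_config <- function(se = c("square3x3", "square2x2"), passes = 7L,
                              dilation_passes = passes) {
  se <- match.arg(se)
  passes <- as.integer(passes)
  dilation_passes <- as.integer(dilation_passes)
  if (passes < 1L || dilation_passes < 1L) stop("passes must be >= 1")
  offs <- if (se == "square3x3") {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  } else {
    cbind(dr = c(0L, 0L, 1L, 1L), dc = c(0L, 1L, 0L, 1L))
  }
  structure(list(se = se, passes = passes, dilation_passes = dilation_passes,
                 offsets = offs),
            class = "morphology_config")
}

#' @rdname morphology_config
#' @param cfg a `morphology_config`.
#' @param pixel_size micrometres per pixel.
#' @export
captured_width_um <- function(cfg, pixel_size) {
  check_pixel_size(pixel_size)
  extent <- if (cfg$se == "square3x3") 2L else 1L
  extent * cfg$passes * pixel_size
}

# Translate a logical matrix by (dr, dc): out[r, c] = m[r - dr, c - dc],
# FALSE outside.
shift_mask <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# One erosion with offset set B: E[p] = all(m[p + b]), i.e. AND over
# shift(m, -b).  Pixels beyond the image border count as background.
erode_once <- function(m, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_mask(m, -offsets[i, 1], -offsets[i, 2])
    out <- if (is.null(out)) s else out & s
  }
  out
}

# One dilation with the same offset set: D = union of translates of m by b.
dilate_once <- function(m, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift_mask(m, offsets[i, 1], offsets[i, 2])
    out <- if (is.null(out)) s else out | s
  }
  out
}

#' Binary erosion / dilation
#'
#' Iterated binary erosion or dilation with the configured structuring
#' element.  Pixels beyond the raster border are background, so erosion eats
#' inward from the image edge.
#'
#' @param mask logical matrix or [binary_mask()].
#' @param cfg a [morphology_config()].
#' @param passes number of passes (defaults to the config's).
#' @return Same type as `mask`.
#' @export
erode_mask <- function(mask, cfg = morphology_config(), passes = cfg$passes) {
  apply_morph(mask, cfg, passes, erode_once)
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, cfg = morphology_config(),
                        passes = cfg$dilation_passes) {
  apply_morph(mask, cfg, passes, dilate_once)
}

apply_morph <- function(mask, cfg, passes, fun) {
  is_bm <- inherits(mask, "binary_mask")
  m <- if (is_bm) mask$pixels else mask
  if (!is.logical(m)) storage.mode(m) <- "logical"
  for (i in seq_len(passes)) m <- fun(m, cfg$offsets)
  if (is_bm) binary_mask(m, mask$pixel_size) else m
}

#' Morphological opening of a cell mask
#'
#' `passes` erosions followed by `dilation_passes` dilations, finally
#' intersected with the input mask so the result is contained in the input
#' even when dilation passes exceed erosion passes.  The opened mask is the
#' retained "central cell body"; everything the opening removed is the
#' protrusion residue.
#'
#' @inheritParams erode_mask
#' @return Opened mask, same type as `mask`; empty input yields empty output.
#' @export
open_mask <- function(mask, cfg = morphology_config()) {
  is_bm <- inherits(mask, "binary_mask")
  m <- if (is_bm) mask$pixels else mask
  if (!is.logical(m)) storage.mode(m) <- "logical"
  e <- m
  for (i in seq_len(cfg$passes)) e <- erode_once(e, cfg$offsets)
  d <- e
  for (i in seq_len(cfg$dilation_passes)) d <- dilate_once(d, cfg$offsets)
  d <- d & m
  if (is_bm) binary_mask(d, mask$pixel_size) else d
}

#' Opening residue of a cell region
#'
#' Subtracts the opened cell body from the original cell mask; the residue is
#' the candidate protrusion set.  A cell thinner than the accumulated erosion
#' extent everywhere loses its whole body (`degenerate = TRUE`); such cells
#' are excluded from classification downstream rather than counted as "all
#' protrusion".
#'
#' @param cell a region from [segment()] (list with `pixels`), a
#'   [binary_mask()], or a logical matrix.
#' @param cfg a [morphology_config()].
#' @param shape raster dimensions, required when `cell` is a region.
#' @param pixel_size calibration, required for a region or bare matrix.
#' @return List with `opened_body` and `residue` ([binary_mask()]s, disjoint,
#'   both subsets of the cell mask) and logical `degenerate`.
#' @export
extract_residue <- function(cell, cfg = morphology_config(), shape = NULL,
                            pixel_size = NULL) {
  if (inherits(cell, "binary_mask")) {
    m <- cell$pixels
    pixel_size <- cell$pixel_size
  } else if (is.matrix(cell)) {
    m <- cell
    storage.mode(m) <- "logical"
    check_pixel_size(pixel_size)
  } else {
    if (is.null(shape)) stop("'shape' is required for a region input")
    check_pixel_size(pixel_size)
    m <- region_mask(cell, shape)
  }
  opened <- open_mask(m, cfg)
  residue <- m & !opened
  list(opened_body = binary_mask(opened, pixel_size),
       residue = binary_mask(residue, pixel_size),
       degenerate = !any(opened))
}
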