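#' Calibrated single-channel image
#'
#' A `calibrated_image` is a 2-D intensity raster (numeric matrix, arbitrary
#' detector units, finite and non-negative) together with a mandatory physical
#' calibration in micrometres per pixel edge.  Every micrometre-stated
#' threshold downstream (cell and punctum areas, protrusion lengths) is
#' converted to pixels through this calibration, so it is never inferred
#' silently from file metadata.
#'
#' Coordinate convention: matrices are row-major with the origin at the
#' top-left; row/column indices are 1-based (R convention) throughout the
#' package API.
#'
#' @param pixels numeric matrix of intensities (finite, >= 0).
#' @param pixel_size micrometres per pixel edge (scalar > 0).
#' @param channel_tag one of `"donor"`, `"recipient"`, `"cell"`,
#'   `"unassigned"`.
#' @param bits nominal bit depth (8 or 16); used when writing.
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `pixel_size`, `channel_tag`, `bits`.
#' @export
calibrated_image <- function(pixels, pixel_size,
                             channel_tag = c("unassigned", "donor",
                                             "recipient", "cell"),
                             bits = 16L) {
  channel_tag <- match.arg(channel_tag)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix")
  if (!is.numeric(pixels) || anyNA(pixels) || any(!is.finite(pixels)))
    stop("intensities must be finite numbers")
  if (any(pixels < 0))
    stop("intensities must be >= 0")
  check_pixel_size(pixel_size)
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 channel_tag = channel_tag, bits = as.integer(bits)),
            class = "calibrated_image")
}

check_pixel_size <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (µm per pixel)")
  invisible(pixel_size)
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("calibrated_image: %d x %d px, %.4g µm/px, channel '%s', %d-bit\n",
              d[1], d[2], x$pixel_size, x$channel_tag, x$bits))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask with calibration
#'
#' @param pixels logical matrix.
#' @param pixel_size micrometres per pixel edge.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop("mask must not contain NA")
  check_pixel_size(pixel_size)
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "binary_mask")
}

#' Mask area in square micrometres
#' @param mask a `binary_mask` or logical matrix.
#' @param pixel_size required when `mask` is a bare matrix.
#' @export
area_um2 <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "binary_mask")) {
    sum(mask$pixels) * mask$pixel_size^2
  } else {
    check_pixel_size(pixel_size)
    sum(mask) * pixel_size^2
  }
}

#' Convert an area in square micrometres to pixels
#'
#' @param area area in square micrometres.
#' @param pixel_size micrometres per pixel edge.
#' @return Equivalent pixel count (real-valued).
#' @seealso [px_to_um2()]
#' @export
um2_to_px <- function(area, pixel_size) {
  check_pixel_size(pixel_size)
  area / pixel_size^2
}

#' Convert a pixel count to an area in square micrometres
#' @param n_px pixel count.
#' @inheritParams um2_to_px
#' @export
px_to_um2 <- function(n_px, pixel_size) {
  check_pixel_size(pixel_size)
  n_px * pixel_size^2
}

# Read a raster file into an array in detector units (0..2^bits-1).
# Returns list(data = 2-D or 3-D array of integers, bits).
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- suppressWarnings(tiff::readTIFF(path, info = TRUE))
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  } else {
    stop("unsupported image format '", ext, "' (TIFF or PNG expected)")
  }
  maxdn <- 2^bits - 1
  dat <- round(img * maxdn)
  attributes(dat) <- list(dim = dim(img))
  list(data = dat, bits = as.integer(bits))
}

# Pull TIFF x-resolution metadata (pixels per unit) if present, as um/px.
tiff_metadata_pixel_size <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff")) return(NULL)
  img <- try(suppressWarnings(tiff::readTIFF(path, info = TRUE, payload = FALSE)),
             silent = TRUE)
  if (inherits(img, "try-error")) return(NULL)
  res <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (is.null(res) || !is.numeric(res) || res <= 0) return(NULL)
  # resolution is pixels per unit; only centimetre units are convertible
  if (!is.null(unit) && identical(unit, "cm")) return(1e4 / res)
  NULL
}

#' Load a calibrated single-channel micrograph
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG.  An RGB/multi-channel file is
#' accepted only if exactly one channel carries signal (all others identically
#' zero), in which case that channel is used.  The physical calibration is a
#' required argument; if the TIFF carries resolution metadata that disagrees
#' with `pixel_size` by more than 1%, a warning is issued and the supplied
#' value is used.
#'
#' @inheritParams calibrated_image
#' @param path path to a TIFF or PNG file.
#' @return A [calibrated_image()]; intensities are preserved bit-exactly in
#'   detector units (0..255 or 0..65535).
#' @export
load_image <- function(path, pixel_size,
                       channel_tag = c("unassigned", "donor", "recipient",
                                       "cell")) {
  channel_tag <- match.arg(channel_tag)
  check_pixel_size(pixel_size)
  r <- read_raster(path)
  dat <- r$data
  if (length(dim(dat)) == 3L) {
    nonempty <- which(apply(dat, 3, function(ch) any(ch != 0)))
    if (length(nonempty) == 0L) {
      dat <- dat[, , 1]
    } else if (length(nonempty) == 1L) {
      dat <- dat[, , nonempty]
    } else {
      stop("multi-channel file with ", length(nonempty),
           " non-empty channels; use split_channels()")
    }
  }
  meta <- tiff_metadata_pixel_size(path)
  if (!is.null(meta) && abs(meta - pixel_size) / pixel_size > 0.01)
    warning(sprintf(paste0("TIFF metadata implies %.4g µm/px but %.4g was",
                           " supplied; using the supplied calibration"),
                    meta, pixel_size))
  calibrated_image(dat, pixel_size, channel_tag, bits = r$bits)
}

#' Split a multi-channel file into a donor/recipient channel pair
#'
#' @param path multi-channel TIFF or RGB PNG.
#' @param donor_channel,recipient_channel 1-based channel indices (for RGB
#'   files 1 = red, 2 = green, 3 = blue).
#' @param pixel_size micrometres per pixel edge, shared by both channels.
#' @return A `channel_pair`: list with `donor` and `recipient`
#'   [calibrated_image()]s of identical shape and calibration.
#' @export
split_channels <- function(path, donor_channel, recipient_channel,
                           pixel_size) {
  check_pixel_size(pixel_size)
  r <- read_raster(path)
  dat <- r$data
  if (length(dim(dat)) != 3L)
    stop("file has a single channel; split_channels() needs >= 2")
  nc <- dim(dat)[3]
  idx <- c(donor_channel, recipient_channel)
  if (any(idx < 1 | idx > nc)) stop("channel index out of range (1..", nc, ")")
  if (donor_channel == recipient_channel)
    stop("donor and recipient channel indices must differ")
  pair <- list(
    donor = calibrated_image(dat[, , donor_channel], pixel_size, "donor",
                             bits = r$bits),
    recipient = calibrated_image(dat[, , recipient_channel], pixel_size,
                                 "recipient", bits = r$bits))
  structure(pair, class = "channel_pair")
}

#' Write a calibrated image to TIFF or PNG
#'
#' TIFF supports 8- and 16-bit output; PNG output is 8-bit (values above 255
#' are an error for PNG).  Written values round-trip bit-exactly through
#' [load_image()].
#'
#' @param image a [calibrated_image()] or numeric matrix in detector units.
#' @param path destination path ending in `.tif`, `.tiff` or `.png`.
#' @param bits bit depth for bare-matrix input (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  if (inherits(image, "calibrated_image")) {
    m <- image$pixels
    bits <- image$bits
  } else {
    m <- image
  }
  maxdn <- 2^bits - 1
  if (any(m < 0) || any(m > maxdn))
    stop("intensities outside 0..", maxdn, " for ", bits, "-bit output")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m / maxdn, path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit rasters")
    png::writePNG(m / maxdn, path)
  } else {
    stop("unsupported output format '", ext, "'")
  }
  invisible(path)
}
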