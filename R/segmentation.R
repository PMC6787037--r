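#' Estimate a background intensity model
#'
#' Turns one or more calibration images (for donor channels: donor-free
#' control fields) into a single intensity threshold.  Four methods are
#' offered; the default for donor channels is `percentile` 99.9 on donor-free
#' controls, and for cell/recipient channels Otsu's method on the image
#' itself.
#'
#' * `percentile`: inverse-ECDF (type-1) quantile of the pooled control
#'   pixels; `param` is the percentile, in (50, 100).  Guarantees that the
#'   fraction of strictly supra-threshold pixels on the controls is at most
#'   `(100 - param)/100` (up to ties).
#' * `mean_plus_k_sd`: pooled mean plus `param` standard deviations.
#' * `otsu`: Otsu's between-class-variance threshold (256 levels).
#' * `manual`: `param` is the threshold itself.
#'
#' @param controls a [calibrated_image()] or list of them, sharing
#'   calibration.
#' @param method one of `"percentile"`, `"mean_plus_k_sd"`, `"otsu"`,
#'   `"manual"`.
#' @param param method parameter (see above).
#' @return Object of class `background_model` with fields
#'   `threshold_intensity`, `method`, `parameters`.
#' @export
estimate_background <- function(controls,
                                method = c("percentile", "mean_plus_k_sd",
                                           "otsu", "manual"),
                                param = 99.9) {
  method <- match.arg(method)
  if (inherits(controls, "calibrated_image")) controls <- list(controls)
  if (method != "manual") {
    if (!is.list(controls) || length(controls) == 0L)
      stop("at least one control image is required")
    if (!all(vapply(controls, inherits, logical(1), "calibrated_image")))
      stop("controls must be calibrated_image objects")
    ps <- vapply(controls, function(x) x$pixel_size, numeric(1))
    if (diff(range(ps)) > 0) stop("controls must share calibration")
    v <- unlist(lapply(controls, function(x) as.numeric(x$pixels)))
  }
  thr <- switch(method,
    percentile = {
      if (!is.numeric(param) || param <= 50 || param >= 100)
        stop("percentile must lie in (50, 100)")
      unname(stats::quantile(v, param / 100, type = 1))
    },
    mean_plus_k_sd = {
      if (!is.numeric(param) || param <= 0) stop("k must be > 0")
      mean(v) + param * stats::sd(v)
    },
    otsu = {
      if (diff(range(v)) == 0) v[1]
      else {
        maxdn <- max(2^16 - 1, max(v))
        EBImage::otsu(matrix(v, ncol = 1) / maxdn, range = c(0, 1)) * maxdn
      }
    },
    manual = {
      if (!is.numeric(param) || length(param) != 1L || !is.finite(param))
        stop("manual threshold must be a finite scalar")
      param
    })
  structure(list(threshold_intensity = as.numeric(thr), method = method,
                 parameters = param),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: threshold %.4g (%s, param %s)\n",
              x$threshold_intensity, x$method,
              paste(format(x$parameters), collapse = ", ")))
  invisible(x)
}

#' Segment an intensity channel into labeled regions
#'
#' Thresholds the image at the background model (pixels strictly above the
#' threshold are foreground), optionally fills internal holes, labels
#' connected components and retains those within the area bounds (both bounds
#' inclusive, in square micrometres).
#'
#' Hole filling is on by default for cell segmentation: the protrusion stage
#' subtracts an opened body from the cell mask, and unfilled internal holes
#' would surface as spurious residue.
#'
#' @param image a [calibrated_image()].
#' @param background a `background_model` from [estimate_background()], or a
#'   numeric threshold.
#' @param min_area minimum region area in square micrometres (inclusive).
#' @param max_area optional maximum area in square micrometres (inclusive).
#' @param connectivity pixel connectivity, 4 or 8 (default 8 so 1-px diagonal
#'   protrusion necks stay attached to the cell body).
#' @param fill_holes fill internal holes before labeling (default TRUE).
#' @return A `region_set`; empty (zero regions) when nothing is
#'   supra-threshold.
#' @export
segment <- function(image, background, min_area = 0, max_area = NULL,
                    connectivity = 8L, fill_holes = TRUE) {
  stopifnot(inherits(image, "calibrated_image"))
  thr <- if (inherits(background, "background_model"))
    background$threshold_intensity else as.numeric(background)
  if (min_area < 0) stop("min_area must be >= 0")
  mask <- image$pixels > thr
  if (fill_holes && any(mask)) {
    m <- matrix(0L, nrow(mask), ncol(mask))
    m[mask] <- 1L
    mask <- EBImage::fillHull(m) > 0
  }
  labels <- label_components(mask, connectivity)
  region_set_from_labels(labels, image$pixel_size, connectivity,
                         min_area_um2 = min_area, max_area_um2 = max_area)
}
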