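#' Transfer-quantification configuration
#'
#' Parameters for counting donor-tagged organelle puncta inside
#' recipient-cell regions of interest (ROIs).  Defaults follow the wide-field
#' co-culture workflow: recipient cells of at least 100 µm², puncta of at
#' most 25 µm², and exclusion of any donor component touching a 1-px inner
#' margin of the ROI (signal at the recipient boundary typically reflects an
#' overlapping donor cell, not transfer).  `punctum_min_area` (default
#' 1 µm²) suppresses single-pixel noise exceedances of the background
#' threshold; genuine organelle puncta at this magnification are well above
#' it.
#'
#' @param background a `background_model` for the donor channel (required;
#'   estimate it from donor-free control images).
#' @param recipient_min_area µm², minimum recipient-cell area (default 100).
#' @param punctum_max_area µm², maximum accepted punctum area (default 25).
#' @param punctum_min_area µm², minimum accepted punctum area (default 1).
#' @param boundary_width width in pixels of the excluded inner margin of
#'   each ROI (default 1).
#' @param recipient_background optional background model for the recipient
#'   channel; default Otsu on the channel itself.
#' @param connectivity labeling connectivity (default 8).
#' @return Object of class `transfer_config`.
#' @export
transfer_config <- function(background, recipient_min_area = 100,
                            punctum_max_area = 25, punctum_min_area = 1,
                            boundary_width = 1L,
                            recipient_background = NULL,
                            connectivity = 8L) {
  if (missing(background))
    stop("a donor-channel background model is required; build one with ",
         "estimate_background() on donor-free controls")
  if (recipient_min_area <= 0 || punctum_max_area <= 0 ||
      punctum_min_area < 0 || boundary_width < 0)
    stop("all sizes must be positive")
  if (punctum_max_area >= recipient_min_area)
    stop("punctum_max_area must be smaller than recipient_min_area")
  structure(list(background = background,
                 recipient_min_area = recipient_min_area,
                 punctum_max_area = punctum_max_area,
                 punctum_min_area = punctum_min_area,
                 boundary_width = as.integer(boundary_width),
                 recipient_background = recipient_background,
                 connectivity = as.integer(connectivity)),
            class = "transfer_config")
}

#' Segment recipient-cell regions of interest
#'
#' Recipient (e.g. DsRed fibroblast) cell outlines at the configured minimum
#' area; each becomes an ROI applied to the donor channel.
#'
#' @param recipient_channel a [calibrated_image()].
#' @param cfg a [transfer_config()].
#' @return A `region_set` of recipient ROIs (possibly empty).
#' @export
recipient_rois <- function(recipient_channel, cfg) {
  stopifnot(inherits(recipient_channel, "calibrated_image"),
            inherits(cfg, "transfer_config"))
  bg <- cfg$recipient_background %||%
    estimate_background(recipient_channel, "otsu")
  segment(recipient_channel, bg, min_area = cfg$recipient_min_area,
          connectivity = cfg$connectivity, fill_holes = TRUE)
}

# Label supra-background donor components on the full channel (components
# are defined before ROI clipping, so one physical punctum spanning two
# touching ROIs is boundary-excluded from both).
donor_component_labels <- function(donor_channel, cfg) {
  mask <- donor_channel$pixels > cfg$background$threshold_intensity
  label_components(mask, cfg$connectivity)
}

#' Detect donor puncta within one recipient ROI
#'
#' Donor components are taken on the full channel, then assessed against the
#' ROI.  Exclusion precedence is fixed and auditable: components below
#' `punctum_min_area` are suppressed first as noise (`excluded_small`) —
#' they are detector-noise specks, not objects, so they must not consume a
#' boundary or size verdict; then a component touching the ROI's inner
#' boundary band (or extending beyond the ROI) is excluded and counted in
#' `excluded_boundary`; of the remaining fully-interior components, those
#' larger than `punctum_max_area` are counted in `excluded_oversize`; the
#' rest are accepted.
#'
#' @param donor_channel donor [calibrated_image()] (same shape and
#'   calibration as the recipient channel).
#' @param roi one recipient region from [recipient_rois()].
#' @param cfg a [transfer_config()].
#' @param donor_labels optional precomputed label matrix from the donor
#'   channel (internal reuse across ROIs).
#' @param shape raster dimensions (defaults to the donor channel's).
#' @return List: `accepted` (`region_set` of puncta), `excluded_boundary`,
#'   `excluded_oversize`, `excluded_small` counts.
#' @export
detect_puncta <- function(donor_channel, roi, cfg, donor_labels = NULL,
                          shape = NULL) {
  stopifnot(inherits(cfg, "transfer_config"))
  if (is.null(donor_labels))
    donor_labels <- donor_component_labels(donor_channel, cfg)
  shape <- shape %||% dim(donor_channel$pixels)
  ps <- donor_channel$pixel_size
  roimask <- region_mask(roi, shape)
  interior <- roimask
  if (cfg$boundary_width > 0L)
    interior <- erode_mask(roimask, morphology_config("square3x3", 1L),
                           passes = cfg$boundary_width)
  band <- roimask & !interior
  in_roi <- unique(donor_labels[roimask])
  in_roi <- in_roi[in_roi > 0L]
  accepted <- list(); k <- 0L
  n_boundary <- 0L; n_oversize <- 0L; n_small <- 0L
  for (lab in sort(in_roi)) {
    px <- which(donor_labels == lab)
    a <- length(px) * ps^2
    if (a < cfg$punctum_min_area) {
      n_small <- n_small + 1L
      next
    }
    inside <- roimask[px]
    if (any(band[px]) || !all(inside)) {
      n_boundary <- n_boundary + 1L
      next
    }
    if (a > cfg$punctum_max_area) {
      n_oversize <- n_oversize + 1L
    } else {
      k <- k + 1L
      nr <- shape[1]
      r <- ((px - 1L) %% nr) + 1L
      c <- ((px - 1L) %/% nr) + 1L
      accepted[[k]] <- list(label = k, pixels = px, area_um2 = a,
                            centroid = c(row = mean(r), col = mean(c)),
                            bbox = c(min_row = min(r), min_col = min(c),
                                     max_row = max(r), max_col = max(c)))
    }
  }
  acc <- structure(list(regions = accepted, source_shape = shape,
                        pixel_size = ps, connectivity = cfg$connectivity),
                   class = "region_set")
  list(accepted = acc, excluded_boundary = n_boundary,
       excluded_oversize = n_oversize, excluded_small = n_small)
}

#' Classify recipients as donor-positive and summarize a field
#'
#' Runs [detect_puncta()] over every ROI (donor components computed once).
#' A recipient is donor-positive iff it holds at least one accepted punctum.
#' The summary unit is the field: one percent-positive value per image.
#'
#' @param rois `region_set` from [recipient_rois()].
#' @param donor_channel donor [calibrated_image()].
#' @param cfg a [transfer_config()].
#' @return Object of class `transfer_analysis`: list with `recipients`
#'   (data.frame: label, area_um2, n_puncta, excluded_boundary,
#'   excluded_oversize, excluded_small, positive), `results` (per-ROI
#'   [detect_puncta()] output), and `summary` (n, n_positive, percent;
#'   `percent = NA` when there is no ROI).
#' @export
classify_recipients <- function(rois, donor_channel, cfg) {
  stopifnot(inherits(rois, "region_set"),
            inherits(donor_channel, "calibrated_image"),
            inherits(cfg, "transfer_config"))
  if (!all(rois$source_shape == dim(donor_channel$pixels)))
    stop("donor channel and ROI field shapes differ")
  labels <- donor_component_labels(donor_channel, cfg)
  results <- vector("list", length(rois$regions))
  rows <- vector("list", length(rois$regions))
  for (i in seq_along(rois$regions)) {
    roi <- rois$regions[[i]]
    det <- detect_puncta(donor_channel, roi, cfg, donor_labels = labels,
                         shape = rois$source_shape)
    results[[i]] <- det
    rows[[i]] <- data.frame(
      label = roi$label, area_um2 = roi$area_um2,
      n_puncta = length(det$accepted$regions),
      excluded_boundary = det$excluded_boundary,
      excluded_oversize = det$excluded_oversize,
      excluded_small = det$excluded_small,
      positive = length(det$accepted$regions) > 0L)
  }
  recipients <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), area_um2 = numeric(0),
               n_puncta = integer(0), excluded_boundary = integer(0),
               excluded_oversize = integer(0), excluded_small = integer(0),
               positive = logical(0))
  n <- nrow(recipients)
  np <- sum(recipients$positive)
  structure(list(recipients = recipients, results = results,
                 summary = list(n = n, n_positive = np,
                                percent = if (n > 0) 100 * np / n
                                          else NA_real_)),
            class = "transfer_analysis")
}

#' @export
print.transfer_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("transfer_analysis: %d recipient(s), %d donor-positive (%s%%)\n",
              s$n, s$n_positive,
              if (is.na(s$percent)) "NA" else sprintf("%.1f", s$percent)))
  invisible(x)
}
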