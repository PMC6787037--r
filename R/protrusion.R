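#' TNT shape-filter configuration
#'
#' Residue components qualify as TNT-like protrusions when they pass all four
#' filters (every comparison inclusive):
#' area >= `min_area`, maximum Feret diameter >= `min_longest_axis`,
#' circularity <= `max_circularity`, bounding-box-area / region-area >=
#' `min_box_area_ratio`.  The defaults are the TNT filter set used for
#' wide-field macrophage imaging: 20 µm² minimum area, 10 µm minimum longest
#' axis, 0.6 maximum circularity, 1.9 minimum box-area ratio.  Filters
#' compare the uncapped circularity value.
#'
#' Setting `min_box_area_ratio = 0` disables the box-area criterion (its
#' exact provenance is tool-specific; the ratio reading selects elongated or
#' bent shapes).
#'
#' @param min_area µm², minimum protrusion area.
#' @param min_longest_axis µm, minimum maximum-Feret length.
#' @param max_circularity maximum circularity, in (0, 1].
#' @param min_box_area_ratio minimum bounding-box-area to region-area ratio.
#' @return Object of class `protrusion_filter_config`.
#' @export
protrusion_filter_config <- function(min_area = 20, min_longest_axis = 10,
                                     max_circularity = 0.6,
                                     min_box_area_ratio = 1.9) {
  if (min_area <= 0 || min_longest_axis <= 0 || min_box_area_ratio < 0)
    stop("filter thresholds must be positive")
  if (max_circularity <= 0 || max_circularity > 1)
    stop("max_circularity must lie in (0, 1]")
  structure(list(min_area = min_area, min_longest_axis = min_longest_axis,
                 max_circularity = max_circularity,
                 min_box_area_ratio = min_box_area_ratio),
            class = "protrusion_filter_config")
}

#' Filter residue components into qualifying protrusions
#'
#' Labels the connected components of the opening residue and retains those
#' passing every shape filter in `filters`.  Components of a single pixel
#' cannot satisfy the length filter and are dropped.
#'
#' @param residue a [binary_mask()] (or logical matrix) of residue pixels.
#' @param filters a [protrusion_filter_config()].
#' @param pixel_size calibration, required for a bare matrix.
#' @param connectivity labeling connectivity (default 8).
#' @return A `region_set` of accepted protrusions; each region carries its
#'   `descriptors` row.
#' @export
filter_protrusions <- function(residue, filters = protrusion_filter_config(),
                               pixel_size = NULL, connectivity = 8L) {
  if (inherits(residue, "binary_mask")) {
    m <- residue$pixels; pixel_size <- residue$pixel_size
  } else {
    m <- residue; storage.mode(m) <- "logical"
    check_pixel_size(pixel_size)
  }
  labels <- label_components(m, connectivity)
  rs <- region_set_from_labels(labels, pixel_size, connectivity)
  if (length(rs$regions) == 0L) return(rs)
  nr <- nrow(m)
  keep <- list(); k <- 0L
  for (r in rs$regions) {
    rows <- ((r$pixels - 1L) %% nr) + 1L
    cols <- ((r$pixels - 1L) %/% nr) + 1L
    d <- measure_pixels(rows, cols, pixel_size)
    if (d$degenerate) next
    if (d$area_um2 >= filters$min_area &&
        d$length_um >= filters$min_longest_axis &&
        d$circularity <= filters$max_circularity &&
        d$box_area_ratio >= filters$min_box_area_ratio) {
      k <- k + 1L
      r$label <- k
      r$descriptors <- d
      keep[[k]] <- r
    }
  }
  rs$regions <- keep
  rs
}

#' Classify a cell as protrusion-positive or -negative
#'
#' A cell is positive when at least one filtered protrusion overlaps or is
#' 8-adjacent to the opened cell body (the protrusion must emanate from the
#' retained central body, not float free).  Degenerate cells (body vanished
#' under erosion) are never positive.
#'
#' @param protrusions `region_set` from [filter_protrusions()].
#' @param opened_body [binary_mask()] (or logical matrix) of the opened body.
#' @return TRUE/FALSE.
#' @export
classify_cell <- function(protrusions, opened_body) {
  m <- if (inherits(opened_body, "binary_mask")) opened_body$pixels
       else opened_body
  if (!any(m)) return(FALSE)
  if (length(protrusions$regions) == 0L) return(FALSE)
  grown <- dilate_once(m, morphology_config("square3x3", 1L)$offsets)
  for (r in protrusions$regions)
    if (any(grown[r$pixels])) return(TRUE)
  FALSE
}

#' Per-image protrusion analysis
#'
#' Full protrusion workflow on one cell channel: segment cells (>=
#' `min_cell_area`, holes filled), then per cell take the opening residue,
#' filter its components with the TNT shape filters, and classify the cell.
#' Each cell is processed in a padded crop of its bounding box so image-border
#' effects cannot leak between cells.
#'
#' @param cell_channel a [calibrated_image()] of the labeled cell population.
#' @param background background model or threshold for the cell channel;
#'   default Otsu on the image itself.
#' @param min_cell_area µm², minimum cell area (default 100).
#' @param morph a [morphology_config()].
#' @param filters a [protrusion_filter_config()].
#' @param connectivity segmentation connectivity (default 8).
#' @return Object of class `protrusion_analysis`: list with `cells`
#'   (data.frame: label, area_um2, centroid, n_protrusions, positive,
#'   degenerate), `results` (per-cell list with `opened_body`, `residue`,
#'   `protrusions`, `positive`, `degenerate`, crop `offset`), and the
#'   segmentation `regions`.
#' @export
analyze_protrusions <- function(cell_channel, background = NULL,
                                min_cell_area = 100,
                                morph = morphology_config(),
                                filters = protrusion_filter_config(),
                                connectivity = 8L) {
  stopifnot(inherits(cell_channel, "calibrated_image"))
  if (is.null(background))
    background <- estimate_background(cell_channel, "otsu")
  cells <- segment(cell_channel, background, min_area = min_cell_area,
                   connectivity = connectivity, fill_holes = TRUE)
  ps <- cell_channel$pixel_size
  nr <- cells$source_shape[1]; ncl <- cells$source_shape[2]
  pad <- morph$passes + 2L
  results <- vector("list", length(cells$regions))
  rows_out <- vector("list", length(cells$regions))
  for (i in seq_along(cells$regions)) {
    r <- cells$regions[[i]]
    r0 <- max(1L, r$bbox["min_row"] - pad); r1 <- min(nr, r$bbox["max_row"] + pad)
    c0 <- max(1L, r$bbox["min_col"] - pad); c1 <- min(ncl, r$bbox["max_col"] + pad)
    crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    prow <- ((r$pixels - 1L) %% nr) + 1L
    pcol <- ((r$pixels - 1L) %/% nr) + 1L
    crop[cbind(prow - r0 + 1L, pcol - c0 + 1L)] <- TRUE
    res <- extract_residue(crop, morph, pixel_size = ps)
    prot <- filter_protrusions(res$residue, filters)
    positive <- if (res$degenerate) FALSE
                else classify_cell(prot, res$opened_body)
    results[[i]] <- list(cell = r, opened_body = res$opened_body,
                         residue = res$residue, protrusions = prot,
                         positive = positive, degenerate = res$degenerate,
                         offset = c(row = r0, col = c0))
    rows_out[[i]] <- data.frame(
      label = r$label, area_um2 = r$area_um2,
      centroid_row = unname(r$centroid["row"]),
      centroid_col = unname(r$centroid["col"]),
      n_protrusions = length(prot$regions),
      positive = positive, degenerate = res$degenerate)
  }
  cells_df <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(label = integer(0), area_um2 = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               n_protrusions = integer(0), positive = logical(0),
               degenerate = logical(0))
  structure(list(cells = cells_df, results = results, regions = cells,
                 morph = morph, filters = filters),
            class = "protrusion_analysis")
}

#' @export
print.protrusion_analysis <- function(x, ...) {
  n <- nrow(x$cells); nd <- sum(x$cells$degenerate)
  np <- sum(x$cells$positive & !x$cells$degenerate)
  cat(sprintf("protrusion_analysis: %d cell(s), %d positive (%.1f%%), %d degenerate\n",
              n, np, if (n - nd > 0) 100 * np / (n - nd) else NA_real_, nd))
  invisible(x)
}

#' Percent protrusion-positive cells per group
#'
#' Summary readout per experimental field/condition: percent = 100 ×
#' positives / valid cells.  Degenerate cells are excluded from both counts
#' and reported separately; a group containing no valid cell is reported with
#' `percent = NA` (missing, not 0%).
#'
#' @param cells a `protrusion_analysis`, its `cells` data.frame, or an
#'   rbind of such data.frames from several fields.
#' @param group grouping labels recycled to rows (default one group).
#' @return data.frame: group, n_cells, n_positive, n_degenerate, percent.
#' @export
percent_positive <- function(cells, group = NULL) {
  if (inherits(cells, "protrusion_analysis")) cells <- cells$cells
  if (is.null(group)) group <- rep("all", nrow(cells))
  group <- rep_len(as.character(group), nrow(cells))
  out <- NULL
  for (g in unique(group)) {
    d <- cells[group == g, , drop = FALSE]
    valid <- !d$degenerate
    n <- sum(valid)
    np <- sum(d$positive & valid)
    out <- rbind(out, data.frame(
      group = g, n_cells = n, n_positive = np,
      n_degenerate = sum(!valid),
      percent = if (n > 0) 100 * np / n else NA_real_))
  }
  out
}
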