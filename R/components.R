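# Connected-component labeling on logical matrices.
#
# Foreground pixels become graph vertices joined to their right/down (and, for
# 8-connectivity, both diagonal) neighbours; igraph::components() gives the
# partition.  Labels are renumbered in row-major scan order of each
# component's first pixel so output is deterministic.

label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(labels)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  efrom <- integer(0); eto <- integer(0)
  for (o in offs) {
    r2 <- rr + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      efrom <- c(efrom, pos[idx[ok][hit]])
      eto <- c(eto, pos[nb[hit]])
    }
  }
  if (length(efrom)) {
    g <- igraph::make_graph(rbind(efrom, eto), n = length(idx),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  # renumber by first occurrence in scan order (column-major over the matrix
  # equals top-left-first within columns; stable and deterministic)
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  labels[idx] <- relab[memb]
  labels
}

# Build a region_set from a label matrix.
region_set_from_labels <- function(labels, pixel_size, connectivity = 8L,
                                   min_area_um2 = 0, max_area_um2 = NULL) {
  nr <- nrow(labels)
  idx <- which(labels > 0L)
  regions <- list()
  if (length(idx)) {
    by_lab <- split(idx, labels[idx])
    by_lab <- by_lab[order(as.integer(names(by_lab)))]
    keep <- 0L
    for (px in by_lab) {
      a <- length(px) * pixel_size^2
      if (a < min_area_um2) next
      if (!is.null(max_area_um2) && a > max_area_um2) next
      keep <- keep + 1L
      r <- ((px - 1L) %% nr) + 1L
      c <- ((px - 1L) %/% nr) + 1L
      regions[[keep]] <- list(
        label = keep,
        pixels = px,
        area_um2 = a,
        centroid = c(row = mean(r), col = mean(c)),
        bbox = c(min_row = min(r), min_col = min(c),
                 max_row = max(r), max_col = max(c)))
    }
  }
  structure(list(regions = regions, source_shape = dim(labels),
                 pixel_size = pixel_size,
                 connectivity = as.integer(connectivity)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d region(s) in a %d x %d field, %.4g µm/px, %d-connectivity\n",
              length(x$regions), x$source_shape[1], x$source_shape[2],
              x$pixel_size, x$connectivity))
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$regions)

#' Tabulate a region set
#'
#' @param x a `region_set` as returned by [segment()].
#' @param ... unused.
#' @return data.frame with label, area_um2, centroid and bounding box
#'   (1-based, inclusive) per region.
#' @export
as.data.frame.region_set <- function(x, ...) {
  if (length(x$regions) == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      min_row = integer(0), min_col = integer(0),
                      max_row = integer(0), max_col = integer(0)))
  do.call(rbind, lapply(x$regions, function(r)
    data.frame(label = r$label, area_um2 = r$area_um2,
               centroid_row = r$centroid["row"], centroid_col = r$centroid["col"],
               min_row = r$bbox["min_row"], min_col = r$bbox["min_col"],
               max_row = r$bbox["max_row"], max_col = r$bbox["max_col"],
               row.names = NULL)))
}

# Materialize one region as a logical matrix over the full field.
region_mask <- function(region, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[region$pixels] <- TRUE
  m
}

#' Export a region set as a 16-bit label image
#'
#' @param x a `region_set`.
#' @param path destination TIFF path.
#' @export
write_label_image <- function(x, path) {
  m <- matrix(0, x$source_shape[1], x$source_shape[2])
  for (r in x$regions) m[r$pixels] <- r$label
  if (max(m) > 65535) stop("more than 65535 regions")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
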