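# Deterministic geometric fixtures built in code (no noise unless asked).

disk_mask <- function(radius, pad = 3L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  row <- matrix(seq_len(n), n, n)
  col <- t(row)
  (row - ctr)^2 + (col - ctr)^2 <= radius^2
}

rect_mask <- function(w, h, pad = 3L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# Rotated solid ellipse mask (axes in px).
ellipse_mask <- function(a, b, theta = 0, pad = 3L) {
  n <- 2L * ceiling(a + pad) + 1L
  ctr <- ceiling(a + pad) + 1L
  shape <- c(n, n)
  m <- matrix(FALSE, n, n)
  m[tntquant:::rasterize_ellipse(c(ctr, ctr), a, b, theta, shape)] <- TRUE
  m
}

# Flat-intensity calibrated image from a mask: background 0, foreground fg.
flat_image <- function(mask, pixel_size = 0.5, fg = 1000,
                       channel = "unassigned") {
  calibrated_image(matrix(as.numeric(mask) * fg, nrow(mask), ncol(mask)),
                   pixel_size, channel)
}

# A circular cell with one straight ribbon appendage, plus ground truth.
cell_with_ribbon <- function(body_r = 20L, rib_len = 60, rib_w = 4,
                             angle = pi / 4, field = 160L) {
  ctr <- c(field / 2, field / 2)
  shape <- c(field, field)
  body <- tntquant:::rasterize_disk(ctr, body_r, shape)
  d <- c(sin(angle), cos(angle))
  p0 <- ctr + (body_r - 2) * d
  p1 <- p0 + (rib_len + 2) * d
  rib <- setdiff(rasterize_ribbon(p0, p1, width = rib_w, shape = shape), body)
  m <- matrix(FALSE, field, field)
  m[body] <- TRUE; m[rib] <- TRUE
  list(mask = m, body = body, ribbon = rib, shape = shape)
}
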