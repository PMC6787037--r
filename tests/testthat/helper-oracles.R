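# Independent brute-force oracles, written from the literal set definitions
# of the operations they check.  They share no code with the package's
# shift-based implementations.

# A ⊖ B = {p : p + b ∈ A for every b in B}, image border = background.
# Pixel sets are represented as linear-index sets; membership via %in%.
oracle_erode <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m)
  if (!length(fg)) return(m & FALSE)
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  keep <- rep(TRUE, length(fg))
  for (i in seq_len(nrow(offsets))) {
    r2 <- r + offsets[i, 1]; c2 <- c + offsets[i, 2]
    inb <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok <- inb
    ok[inb] <- ((c2[inb] - 1L) * nr + r2[inb]) %in% fg
    keep <- keep & ok
  }
  out <- matrix(FALSE, nr, nc)
  out[fg[keep]] <- TRUE
  out
}

# A ⊕ B = {p + b : p ∈ A, b ∈ B}, clipped to the raster.
oracle_dilate <- function(m, offsets) {
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m)
  out <- matrix(FALSE, nr, nc)
  if (!length(fg)) return(out)
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  for (i in seq_len(nrow(offsets))) {
    r2 <- r + offsets[i, 1]; c2 <- c + offsets[i, 2]
    inb <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out[(c2[inb] - 1L) * nr + r2[inb]] <- TRUE
  }
  out
}

# n-pass opening from the definitions above, clipped to the input mask the
# same way the package documents.
oracle_open <- function(m, offsets, passes) {
  e <- m
  for (i in seq_len(passes)) e <- oracle_erode(e, offsets)
  d <- e
  for (i in seq_len(passes)) d <- oracle_dilate(d, offsets)
  d & m
}

se_offsets <- function(se) {
  if (se == "square3x3") as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  else cbind(dr = c(0L, 0L, 1L, 1L), dc = c(0L, 1L, 0L, 1L))
}

# Connected components by explicit breadth-first flood fill.
oracle_label <- function(m, connectivity = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (start in which(m)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(offs))) {
        r2 <- pr + offs[k, 1]; c2 <- pc + offs[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (m[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Max Feret diameter as the all-pairs maximum distance over the pixel corner
# points (no convex hull involved).
oracle_feret <- function(rows, cols) {
  pr <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  pc <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  sqrt(max(outer(pr, pr, "-")^2 + outer(pc, pc, "-")^2))
}

# Equivalent-ellipse aspect ratio by direct moment sums (quadratic formula
# for the eigenvalues written out).
oracle_aspect <- function(rows, cols) {
  n <- length(rows)
  mr <- sum(rows) / n; mc <- sum(cols) / n
  srr <- sum((rows - mr)^2) / n + 1 / 12
  scc <- sum((cols - mc)^2) / n + 1 / 12
  src <- sum((rows - mr) * (cols - mc)) / n
  l1 <- (srr + scc) / 2 + sqrt(((srr - scc) / 2)^2 + src^2)
  l2 <- (srr + scc) / 2 - sqrt(((srr - scc) / 2)^2 + src^2)
  sqrt(l1 / l2)
}

# Seeded random masks: a mix of pure salt at several densities and blobby
# masks (sparse seeds dilated), which exercise both tiny and fat structures.
random_masks <- function(n, size, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kind <- i %% 3L
    if (kind < 2L) {
      p <- sample(c(0.2, 0.4, 0.6, 0.8), 1)
      matrix(runif(size * size) < p, size, size)
    } else {
      m <- matrix(runif(size * size) < 0.02, size, size)
      offs <- se_offsets("square3x3")
      for (k in 1:3) m <- oracle_dilate(m, offs)
      m
    }
  })
}
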