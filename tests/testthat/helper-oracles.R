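# Independent brute-force oracles used to check the package's fast paths.

# Even-odd point-in-polygon by ray casting to +x (counts crossings
# strictly right of the point).
oracle_pip <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    if ((yi <= py && py < yj) || (yj <= py && py < yi)) {
      xc <- poly[i, 1] + (py - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
      if (xc > px) inside <- !inside
    }
    j <- i
  }
  inside
}

# Rasterise one polygon by evaluating every pixel centre.
oracle_rasterise <- function(poly, width, height, downsample = 1L) {
  mw <- ceiling(width / downsample); mh <- ceiling(height / downsample)
  m <- matrix(FALSE, mh, mw)
  for (v in seq_len(mh)) {
    for (u in seq_len(mw)) {
      m[v, u] <- oracle_pip((u - 0.5) * downsample, (v - 0.5) * downsample, poly)
    }
  }
  m
}

# 8-connected component labelling by breadth-first search.
oracle_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) {
    for (i in seq_len(nrow(mask))) {
      if (!mask[i, j] || lab[i, j] > 0) next
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue)) {
        c0 <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- c0[1] + di; nj <- c0[2] + dj
          if (ni < 1 || nj < 1 || ni > nrow(mask) || nj > ncol(mask)) next
          if (mask[ni, nj] && lab[ni, nj] == 0) {
            lab[ni, nj] <- nxt
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# Count DAB pixels and total pixels inside a disc by scanning the whole
# image with a double loop.
oracle_disc_ratio <- function(dab, cx, cy, r) {
  pos <- 0L; tot <- 0L
  for (col in seq_len(ncol(dab))) {
    for (row in seq_len(nrow(dab))) {
      x <- col - 1L; y <- row - 1L
      if ((x - cx)^2 + (y - cy)^2 <= r^2) {
        tot <- tot + 1L
        if (dab[row, col]) pos <- pos + 1L
      }
    }
  }
  c(pos = pos, tot = tot)
}

# Axis-aligned rectangle polygon covering pixels [x0, x1) x [y0, y1).
rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Random simple (star-shaped) polygon around a centre.  Angles are
# equally spaced with bounded jitter so no angular gap exceeds pi,
# which guarantees the polygon is simple.
random_star_polygon <- function(cx, cy, rmin, rmax, nv = 8) {
  step <- 2 * pi / nv
  th <- step * (seq_len(nv) - 1) + runif(nv, 0, 0.4 * step)
  r <- runif(nv, rmin, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

metric_formulas_for_test <- function(cc) ihcseg:::metric_formulas(cc)

# Uniform random patches on the 8-bit scale, as [0,1] arrays.
random_patch <- function(h = 64, w = 64) {
  array(sample(0:255, h * w * 3, replace = TRUE) / 255, c(h, w, 3))
}
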