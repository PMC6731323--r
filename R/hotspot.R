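#' H-DAB colour deconvolution
#'
#' Separates haematoxylin and DAB staining by Ruifrok-Johnston colour
#' deconvolution: RGB intensities are converted to optical densities and
#' projected onto the H-DAB stain basis (haematoxylin
#' (0.650, 0.704, 0.286), DAB (0.268, 0.570, 0.776), third vector the
#' normalised cross product).
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @return List of H x W optical-density matrices `haematoxylin`, `dab`
#'   and `residual`.
#' @export
hdab_deconvolve <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stopf("img must be an H x W x 3 RGB array")
  h_vec <- c(0.650, 0.704, 0.286)
  d_vec <- c(0.268, 0.570, 0.776)
  r_vec <- c(h_vec[2] * d_vec[3] - h_vec[3] * d_vec[2],
             h_vec[3] * d_vec[1] - h_vec[1] * d_vec[3],
             h_vec[1] * d_vec[2] - h_vec[2] * d_vec[1])
  r_vec <- r_vec / sqrt(sum(r_vec^2))
  M <- rbind(h_vec, d_vec, r_vec)
  od <- -log10(pmax(img, 1 / 255))
  dim(od) <- c(prod(dim(img)[1:2]), 3)
  conc <- od %*% solve(M)  # rows: pixels; cols: H, DAB, residual
  out <- lapply(1:3, function(i)
    matrix(conc[, i], dim(img)[1], dim(img)[2]))
  names(out) <- c("haematoxylin", "dab", "residual")
  out
}

#' Extract DAB-positive (Ki67-positive) pixels within the tumour mask
#'
#' The DAB optical-density channel from [hdab_deconvolve()] is
#' thresholded, cleaned by a morphological opening, small components are
#' removed, and the result is intersected with the tumour mask; pixels
#' outside the tumour mask are never DAB-positive by construction.
#'
#' @param img H x W x 3 RGB slide (or region) in `[0, 1]`.
#' @param tumour_mask logical H x W matrix of predicted (or known)
#'   tumour pixels at the same resolution.
#' @param od_threshold DAB optical density above which a pixel is
#'   candidate-positive (default 0.15).
#' @param min_area_px connected components smaller than this are
#'   dropped (default 20).
#' @param morph_radius radius of the opening disc (default 1; 0 skips
#'   the opening).
#' @return Logical H x W `dab_mask` matrix.
#' @export
extract_dab <- function(img, tumour_mask, od_threshold = 0.15,
                        min_area_px = 20L, morph_radius = 1L) {
  if (!identical(dim(img)[1:2], dim(tumour_mask)))
    stopf("image and tumour mask are not aligned")
  if (!any(tumour_mask)) {
    warning("tumour mask is empty; returning an empty DAB mask")
    return(matrix(FALSE, nrow(tumour_mask), ncol(tumour_mask)))
  }
  dabod <- hdab_deconvolve(img)$dab
  mask <- dabod > od_threshold
  if (morph_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(morph_radius) + 1L, "disc")
    mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), nrow(tumour_mask), ncol(tumour_mask))
  }
  mask <- mask & tumour_mask
  if (min_area_px > 1 && any(mask)) {
    lab <- label_components_cpp(mask)
    sizes <- tabulate(lab[lab > 0])
    mask[lab > 0 & sizes[pmax(lab, 1L)] < min_area_px] <- FALSE
  }
  mask
}

#' Centroids of DAB-positive components
#'
#' One centroid per 8-connected component of the binary mask, at the
#' component's pixel-mean position in 0-based (x, y) coordinates.
#'
#' @param mask logical matrix (a DAB mask).
#' @return n x 2 matrix of centroid (x, y) positions; zero rows when
#'   the mask is empty.
#' @export
dab_centroids <- function(mask) {
  if (!any(mask)) return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("x", "y"))))
  lab <- label_components_cpp(mask)
  idx <- which(lab > 0)
  comp <- lab[idx]
  ys <- (idx - 1L) %% nrow(mask)
  xs <- (idx - 1L) %/% nrow(mask)
  cbind(x = as.numeric(tapply(xs, comp, mean)),
        y = as.numeric(tapply(ys, comp, mean)))
}

#' Subtractive clustering of point patterns
#'
#' Chiu's subtractive clustering: every point receives a potential
#' `P_i = sum_j exp(-4 ||x_i - x_j||^2 / ra^2)`; the highest-potential
#' point becomes a cluster centre, its influence
#' `P_c exp(-4 ||x_i - x_c||^2 / rb^2)` is subtracted from all
#' potentials, and the process repeats.  A candidate with potential
#' above `accept_ratio` times the first potential is accepted; below
#' `reject_ratio` the procedure stops; in between, the candidate is
#' accepted when `d_min / ra + P / P1 >= 1` (with `d_min` its distance
#' to the nearest existing centre) and otherwise its potential is
#' zeroed and the search continues.
#'
#' @param points n x 2 matrix of (x, y) positions.
#' @param ra cluster radius (default 200 px at level-0 resolution).
#' @param rb squash radius, `rb > ra` (default `1.5 * ra`).
#' @param accept_ratio,reject_ratio acceptance thresholds with
#'   `0 < reject_ratio < accept_ratio < 1` (defaults 0.5 / 0.15).
#' @return m x 2 matrix of cluster centres (a subset of the input
#'   points); empty input gives an empty result, a single point is its
#'   own centre.
#' @export
subtractive_cluster <- function(points, ra = 200, rb = 1.5 * ra,
                                accept_ratio = 0.5, reject_ratio = 0.15) {
  if (ra <= 0 || rb <= ra) stopf("need 0 < ra < rb")
  if (reject_ratio <= 0 || accept_ratio <= reject_ratio || accept_ratio >= 1)
    stopf("need 0 < reject_ratio < accept_ratio < 1")
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  n <- nrow(points)
  if (n == 0) return(points[0, , drop = FALSE])
  if (n == 1) return(points)
  alpha <- 4 / ra^2
  beta <- 4 / rb^2
  # pairwise squared distances, chunked to bound memory
  pot <- numeric(n)
  for (at in seq(1, n, by = 1024)) {
    idx <- at:min(at + 1023, n)
    d2 <- outer(points[idx, 1], points[, 1], "-")^2 +
          outer(points[idx, 2], points[, 2], "-")^2
    pot[idx] <- rowSums(exp(-alpha * d2))
  }
  centres <- integer()
  p1 <- NULL
  repeat {
    cand <- which.max(pot)
    pc <- pot[cand]
    if (is.null(p1)) p1 <- pc
    accept <- if (pc > accept_ratio * p1) TRUE
    else if (pc < reject_ratio * p1) NA     # stop
    else {
      dmin <- sqrt(min((points[centres, 1] - points[cand, 1])^2 +
                       (points[centres, 2] - points[cand, 2])^2))
      dmin / ra + pc / p1 >= 1
    }
    if (is.na(accept)) break
    if (accept) {
      centres <- c(centres, cand)
      d2 <- (points[, 1] - points[cand, 1])^2 +
            (points[, 2] - points[cand, 2])^2
      pot <- pot - pc * exp(-beta * d2)
      pot[cand] <- -Inf
    } else {
      pot[cand] <- -Inf
    }
    if (all(!is.finite(pot)) || length(centres) >= n) break
  }
  points[centres, , drop = FALSE]
}

#' Score fixed-diameter circles at cluster centres
#'
#' For every centre a circle of the given diameter is laid on the DAB
#' mask and the Ki67 ratio is computed as DAB-positive pixels over total
#' circle pixels; circles clipped by the image border use the clipped
#' area as denominator.  A circle whose ratio exceeds the threshold is
#' a proliferation hotspot.
#'
#' @param dab logical DAB mask (level-0 resolution).
#' @param centres m x 2 matrix of circle centres (x, y), e.g. from
#'   [subtractive_cluster()]; all centres must lie inside the image.
#' @param diameter_px circle diameter (default 100 px, ~50 um at
#'   0.5 um/px).
#' @param threshold Ki67 ratio above which a circle is called a hotspot
#'   (default 0.20).
#' @return A `hotspot_report`: data frame `circles` (centre, ratio,
#'   hotspot call) plus the parameters.
#' @export
score_circles <- function(dab, centres, diameter_px = 100, threshold = 0.20) {
  if (diameter_px <= 0) stopf("diameter_px must be positive")
  centres <- matrix(as.numeric(centres), ncol = 2)
  h <- nrow(dab); w <- ncol(dab)
  if (nrow(centres) > 0 &&
      (any(centres[, 1] < 0) || any(centres[, 1] > w - 1) ||
       any(centres[, 2] < 0) || any(centres[, 2] > h - 1)))
    stopf("circle centre outside the image")
  r <- diameter_px / 2
  ratio <- numeric(nrow(centres))
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    xs <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
    ys <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
    inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    ratio[i] <- sum(dab[ys + 1, xs + 1][inside]) / sum(inside)
  }
  circles <- data.frame(x = centres[, 1], y = centres[, 2],
                        diameter_px = rep(diameter_px, nrow(centres)),
                        ki67_ratio = ratio,
                        is_hotspot = ratio > threshold)
  structure(list(circles = circles, diameter_px = diameter_px,
                 hotspot_threshold = threshold),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("<hotspot_report> %d circle(s), %d hotspot(s) at ratio > %.2f\n",
              nrow(x$circles), sum(x$circles$is_hotspot), x$hotspot_threshold))
  invisible(x)
}

#' Assign proliferation bands to scored circles
#'
#' Splits circles into `length(cut_offs) + 1` ordered bands by their
#' Ki67 ratio; a ratio exactly at a cut-off falls in the upper band.
#' Band boundaries are configuration: no canonical low/medium/high
#' values are fixed by the method.
#'
#' @param report a `hotspot_report`.
#' @param cut_offs strictly increasing ratio cut-offs, all <= 1.
#' @param band_names optional names, `length(cut_offs) + 1` from lowest
#'   to highest.
#' @return The report with a `band` column added to `circles`.
#' @export
band_proliferation <- function(report, cut_offs = c(0.1, 0.2),
                               band_names = NULL) {
  stopifnot(inherits(report, "hotspot_report"))
  if (is.unsorted(cut_offs, strictly = TRUE) || any(cut_offs > 1))
    stopf("cut_offs must be strictly increasing and <= 1")
  nb <- length(cut_offs) + 1
  if (is.null(band_names))
    band_names <- if (nb == 3) c("low", "medium", "high")
                  else paste0("band", seq_len(nb))
  if (length(band_names) != nb)
    stopf("need %d band names", nb)
  idx <- findInterval(report$circles$ki67_ratio, cut_offs) + 1L
  report$circles$band <- factor(band_names[idx], levels = band_names)
  report$cut_offs <- cut_offs
  report
}

#' Write a hotspot report as JSON
#'
#' @param report a `hotspot_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_hotspot_report <- function(report, path) {
  jsonlite::write_json(list(diameter_px = report$diameter_px,
                            hotspot_threshold = report$hotspot_threshold,
                            circles = report$circles),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
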