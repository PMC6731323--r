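#' Assemble a probability map from per-tile scores
#'
#' Tiles live on a stride lattice; the map has one cell per lattice
#' position (`ceiling(dim / stride)` cells per axis), and every tile
#' contributes its score to each of the `(patch / stride)^2` cells it
#' covers.  Overlapping contributions are averaged per cell.  Cells no
#' tile covers are background: their probability is `NA`, not 0.
#'
#' @param x,y integer tile origins (0-based level-0 pixels, multiples of
#'   the stride).
#' @param scores numeric tumour probabilities, one per tile.
#' @param slide_dims `c(width, height)` in level-0 pixels.
#' @param stride_px lattice stride.
#' @param patch_w,patch_h tile dimensions.
#' @param slide_id identifier carried in the map.
#' @return A `probability_map`: probability matrix `p` (rows = lattice
#'   y), `coverage` counts, and the tile geometry.
#' @export
assemble_probability_map <- function(x, y, scores, slide_dims,
                                     stride_px = 32L, patch_w = 64L,
                                     patch_h = 64L, slide_id = NA_character_) {
  gw <- ceiling(slide_dims[1] / stride_px)
  gh <- ceiling(slide_dims[2] / stride_px)
  acc <- matrix(0, gh, gw)
  cov <- matrix(0L, gh, gw)
  cx <- patch_w %/% stride_px
  cy <- patch_h %/% stride_px
  for (i in seq_along(scores)) {
    u <- x[i] %/% stride_px; v <- y[i] %/% stride_px
    rows <- (v + 1):min(v + cy, gh)
    cols <- (u + 1):min(u + cx, gw)
    acc[rows, cols] <- acc[rows, cols] + scores[i]
    cov[rows, cols] <- cov[rows, cols] + 1L
  }
  p <- ifelse(cov > 0, acc / pmax(cov, 1L), NA_real_)
  structure(list(p = p, coverage = cov, stride_px = as.integer(stride_px),
                 patch_w = as.integer(patch_w), patch_h = as.integer(patch_h),
                 slide_dims = as.integer(slide_dims),
                 slide_id = slide_id, excluded = matrix(FALSE, gh, gw)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d cells (stride %d px), %d covered\n",
              ncol(x$p), nrow(x$p), x$stride_px, sum(x$coverage > 0)))
  invisible(x)
}

#' Score a whole pseudo-slide with a trained classifier
#'
#' Slides overlapping `patch_w` x `patch_h` tiles over the stride
#' lattice, skips glass tiles by the mean-intensity tissue rule, scores
#' every tissue tile with the classifier, and averages overlapping
#' contributions per map cell.  The probability reported per tile is
#' that of the model's positive (last) class.
#'
#' @param slide a `pseudo_slide`.
#' @param model a trained `ihc_cnn`.
#' @param stride_px inference stride; must divide the patch size
#'   (default 32, i.e. 50% overlap).
#' @param rule a [tissue_rule()].
#' @return A `probability_map`.
#' @export
infer_slide <- function(slide, model, stride_px = 32L, rule = tissue_rule()) {
  stopifnot(inherits(model, "ihc_cnn"))
  din <- model$spec$input_dim
  ph <- din[1]; pw <- din[2]
  h <- dim(slide$img)[1]; w <- dim(slide$img)[2]
  if (h < ph || w < pw)
    stopf("slide (%d x %d) is smaller than one %d x %d patch", w, h, pw, ph)
  if (pw %% stride_px != 0)
    stopf("stride (%d) must divide the patch size (%d)", stride_px, pw)
  xs <- seq(0L, w - pw, by = stride_px)
  ys <- seq(0L, h - ph, by = stride_px)
  origins <- expand.grid(x = xs, y = ys)
  # tissue tiles only: mean intensity per tile
  mi <- vapply(seq_len(nrow(origins)), function(i) {
    mean(slide$img[(origins$y[i] + 1):(origins$y[i] + ph),
                   (origins$x[i] + 1):(origins$x[i] + pw), ])
  }, 0)
  keep <- which(mi * 255 < rule$mi_threshold)
  scores <- numeric(length(keep))
  chunk <- 250L
  for (at in if (length(keep)) seq(1L, length(keep), by = chunk) else integer()) {
    idx <- keep[at:min(at + chunk - 1L, length(keep))]
    batch <- array(0, c(ph, pw, 3, length(idx)))
    for (j in seq_along(idx)) {
      i <- idx[j]
      batch[, , , j] <- slide$img[(origins$y[i] + 1):(origins$y[i] + ph),
                                  (origins$x[i] + 1):(origins$x[i] + pw), ]
    }
    pr <- predict_patches(model, batch)$probabilities
    scores[at:(at + length(idx) - 1L)] <- pr[, ncol(pr)]
  }
  assemble_probability_map(origins$x[keep], origins$y[keep], scores,
                           c(w, h), stride_px, pw, ph, slide$slide_id)
}

#' Exclude lymphocytic infiltrate from a tumour probability map
#'
#' Cells whose infiltrate probability meets the threshold are forced to
#' non-tumour (probability 0) and flagged in the map's `excluded`
#' matrix.  The operation is idempotent.
#'
#' @param tumour_map,infiltrate_map `probability_map`s sharing geometry.
#' @param threshold infiltrate probability at or above which a cell is
#'   excluded (default 0.5).
#' @return The adjusted tumour `probability_map`.
#' @export
exclude_infiltrate <- function(tumour_map, infiltrate_map, threshold = 0.5) {
  stopifnot(inherits(tumour_map, "probability_map"),
            inherits(infiltrate_map, "probability_map"))
  if (!identical(dim(tumour_map$p), dim(infiltrate_map$p)) ||
      tumour_map$stride_px != infiltrate_map$stride_px)
    stopf("tumour and infiltrate maps do not share geometry")
  drop <- !is.na(infiltrate_map$p) & infiltrate_map$p >= threshold
  tumour_map$p[drop & !is.na(tumour_map$p)] <- 0
  tumour_map$excluded <- tumour_map$excluded | drop
  tumour_map
}

#' Binarise a probability map
#'
#' @param map a `probability_map`.
#' @param threshold cells with `p > threshold` become tumour (default
#'   0.55, the lower edge of the lowest tumour colour bin).
#' @return Logical matrix; uncovered cells are `FALSE`.
#' @export
binarise_map <- function(map, threshold = 0.55) {
  stopifnot(inherits(map, "probability_map"))
  if (threshold <= 0 || threshold > 1) stopf("threshold must lie in (0, 1]")
  !is.na(map$p) & map$p > threshold
}

#' Probability colour binning
#'
#' The default bins follow the probability-map colour key: red for
#' p > 0.75, orange for 0.65 < p <= 0.75, yellow for 0.55 < p <= 0.65
#' and blue (non-tumour) for p <= 0.55.  Bins are half-open with the
#' upper edge belonging to the lower-colour bin, matching the strict
#' inequality p > 0.75 for red.
#'
#' @param breaks increasing cut points within (0, 1).
#' @param colours `length(breaks) + 1` colour names or hex values, from
#'   the lowest bin upwards.
#' @return A `colour_binning` object.
#' @export
colour_binning <- function(breaks = c(0.55, 0.65, 0.75),
                           colours = c("blue", "yellow", "orange", "red")) {
  if (is.unsorted(breaks, strictly = TRUE))
    stopf("breaks must be strictly increasing")
  if (length(colours) != length(breaks) + 1)
    stopf("need %d colours for %d breaks", length(breaks) + 1, length(breaks))
  structure(list(breaks = breaks, colours = colours), class = "colour_binning")
}

#' Bin index of probabilities
#'
#' @param p numeric vector of probabilities.
#' @param bins a [colour_binning()].
#' @return Integer bin index (1 = lowest bin); boundary values fall in
#'   the lower bin.
#' @export
probability_bin <- function(p, bins = colour_binning()) {
  findInterval(p, bins$breaks, left.open = TRUE) + 1L
}

#' Render a pseudo-colour probability overlay
#'
#' Paints every covered map cell with its bin colour over a thumbnail of
#' the slide (block-mean downsampled to the cell lattice); uncovered
#' cells keep the plain thumbnail.
#'
#' @param map a `probability_map`.
#' @param bins a [colour_binning()].
#' @param slide the `pseudo_slide` the map was computed from (optional;
#'   when `NULL` the overlay is painted on white).
#' @param opacity overlay opacity in `[0, 1]`.
#' @return RGB array (cells x cells x 3).
#' @export
render_pseudocolour <- function(map, bins = colour_binning(), slide = NULL,
                                opacity = 0.6) {
  stopifnot(inherits(map, "probability_map"))
  gh <- nrow(map$p); gw <- ncol(map$p)
  thumb <- if (is.null(slide)) array(1, c(gh, gw, 3))
           else block_mean_thumbnail(slide$img, map$stride_px, gh, gw)
  rgbcols <- grDevices::col2rgb(bins$colours) / 255
  covered <- which(!is.na(map$p))
  binidx <- probability_bin(map$p[covered], bins)
  for (ch in 1:3) {
    plane <- thumb[, , ch]
    plane[covered] <- plane[covered] * (1 - opacity) +
      rgbcols[ch, binidx] * opacity
    thumb[, , ch] <- plane
  }
  thumb
}

# Block-mean downsample of an RGB array onto a gh x gw cell lattice.
block_mean_thumbnail <- function(img, stride, gh, gw) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ry <- pmin((seq_len(h) - 1L) %/% stride + 1L, gh)
  rx <- pmin((seq_len(w) - 1L) %/% stride + 1L, gw)
  out <- array(0, c(gh, gw, 3))
  cnt <- table(factor(rep(ry, times = w), levels = 1:gh),
               factor(rep(rx, each = h), levels = 1:gw))
  for (ch in 1:3) {
    s <- rowsum(img[, , ch], ry)          # sum over row blocks
    s <- t(rowsum(t(s), rx))              # then over column blocks
    out[, , ch] <- s / as.numeric(cnt)
  }
  out
}

#' Expand a binary cell mask to a pixel mask at a given downsample
#'
#' Each mask pixel at downsample `d` takes the value of the map cell
#' containing its centre, aligning cell-lattice predictions with
#' ground-truth masks rasterised at `d`.
#'
#' @param map a `probability_map`.
#' @param binary logical cell matrix, e.g. from [binarise_map()].
#' @param downsample target mask downsample (level-0 px per mask px).
#' @return Logical matrix of dimension `ceiling(slide_dims / downsample)`.
#' @export
map_to_mask <- function(map, binary = binarise_map(map), downsample = 8L) {
  stopifnot(inherits(map, "probability_map"))
  mw <- ceiling(map$slide_dims[1] / downsample)
  mh <- ceiling(map$slide_dims[2] / downsample)
  cy <- pmin(floor(((seq_len(mh) - 0.5) * downsample) / map$stride_px) + 1L,
             nrow(binary))
  cx <- pmin(floor(((seq_len(mw) - 0.5) * downsample) / map$stride_px) + 1L,
             ncol(binary))
  binary[cy, cx, drop = FALSE]
}

#' Persist a probability map as floating-point TIFF plus JSON geometry
#'
#' @param map a `probability_map`.
#' @param tiff_path output TIFF (32-bit float; `NA` cells stored as -1).
#' @param json_path sidecar JSON with the lattice geometry.
#' @return `tiff_path`, invisibly.
#' @export
write_probability_map <- function(map, tiff_path,
                                  json_path = sub("\\.tiff?$", ".json",
                                                  tiff_path)) {
  p <- map$p
  p[is.na(p)] <- -1
  tiff::writeTIFF((p + 1) / 2, tiff_path, bits.per.sample = 32L)
  jsonlite::write_json(list(stride_px = map$stride_px,
                            patch_w = map$patch_w, patch_h = map$patch_h,
                            slide_dims = map$slide_dims,
                            slide_id = map$slide_id,
                            encoding = "p = 2 * stored - 1; p < 0 is background"),
                       json_path, auto_unbox = TRUE)
  invisible(tiff_path)
}
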