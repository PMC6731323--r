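#' Specify a tissue region for a synthetic pseudo-slide
#'
#' @param polygon n x 2 numeric matrix of (x, y) vertices in level-0
#'   pixel coordinates (0-based, x rightwards, y downwards).
#' @param class one of `"tumour"`, `"benign"`, `"stroma"`,
#'   `"infiltrate"`.  `benign` emulates non-tumour epithelium, `stroma`
#'   sparse fibroblast-like tissue and `infiltrate` dense fields of
#'   small lymphocyte nuclei.
#' @param ki67_fraction for tumour regions, the fraction of nuclei
#'   rendered DAB-brown (Ki67-positive); required for tumour regions.
#' @return A `slide_region` list.
#' @export
slide_region <- function(polygon, class = c("tumour", "benign", "stroma",
                                            "infiltrate"),
                         ki67_fraction = NULL) {
  class <- match.arg(class)
  if (!is.matrix(polygon) || ncol(polygon) != 2 || nrow(polygon) < 3)
    stopf("polygon must be an n x 2 matrix with n >= 3 vertices")
  if (class == "tumour") {
    if (is.null(ki67_fraction))
      stopf("tumour regions require a ki67_fraction")
    if (ki67_fraction < 0 || ki67_fraction > 1)
      stopf("ki67_fraction must lie in [0, 1]")
  }
  structure(list(polygon = unname(polygon), class = class,
                 ki67_fraction = ki67_fraction), class = "slide_region")
}

#' Specify a synthetic IHC pseudo-slide
#'
#' Defines the geometry, tissue content and randomness of a synthetic
#' Ki67-like pseudo-slide: near-white glass background, tissue fields of
#' haematoxylin-blue nuclei on pale stroma, tumour nests with a
#' controlled fraction of DAB-brown nuclei, and optional dense
#' small-nucleus lymphocytic infiltrate.
#'
#' Defaults emulate a 20x scan at 0.5 um/pixel: nucleus radii of 4-6 px,
#' nucleus densities per 1000 px2 of 8 (tumour), 4 (benign epithelium),
#' 1.5 (stroma) and 16 (infiltrate), a small 2% Ki67-positive fraction
#' in benign epithelium, and glass at grey level ~249 with sigma = 2
#' Gaussian noise (all channels >= 240).
#'
#' @param width_px,height_px canvas size in pixels (>= 256 each).
#' @param microns_per_px physical resolution (default 0.5).
#' @param regions list of [slide_region()] objects; all polygons must
#'   lie inside the canvas.
#' @param nucleus_radius_px length-2 integer range of nucleus radii.
#' @param nucleus_density named vector, nuclei per 1000 px2 for classes
#'   tumour, benign, stroma, infiltrate.
#' @param benign_ki67_fraction Ki67-positive fraction in benign
#'   epithelium (real tissue shows sparse positivity outside tumour).
#' @param downsample downsample factor of the ground-truth label mask
#'   (default 8, approximating annotation at an apparent 10x scale).
#' @param rng_seed integer seed; generation is fully deterministic.
#' @return A `slide_spec` object.
#' @export
slide_spec <- function(width_px, height_px, microns_per_px = 0.5,
                       regions = list(),
                       nucleus_radius_px = c(4L, 6L),
                       nucleus_density = c(tumour = 8, benign = 4,
                                           stroma = 1.5, infiltrate = 16),
                       benign_ki67_fraction = 0.02,
                       downsample = 8L, rng_seed = 1L) {
  if (!is_count(width_px) || !is_count(height_px) ||
      width_px < 256 || height_px < 256)
    stopf("canvas must be at least 256 x 256 pixels")
  if (microns_per_px <= 0) stopf("microns_per_px must be positive")
  if (length(nucleus_radius_px) != 2 || any(nucleus_radius_px <= 0) ||
      nucleus_radius_px[1] > nucleus_radius_px[2])
    stopf("nucleus_radius_px must be an increasing positive range")
  need <- c("tumour", "benign", "stroma", "infiltrate")
  if (!all(need %in% names(nucleus_density)))
    stopf("nucleus_density must name all of: %s", paste(need, collapse = ", "))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (!inherits(r, "slide_region"))
      stopf("regions[[%d]] is not a slide_region", i)
    p <- r$polygon
    if (any(p[, 1] < 0) || any(p[, 1] > width_px) ||
        any(p[, 2] < 0) || any(p[, 2] > height_px))
      stopf("regions[[%d]]: polygon extends outside the canvas", i)
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_px = microns_per_px,
                 regions = regions,
                 nucleus_radius_px = as.numeric(nucleus_radius_px),
                 nucleus_density = nucleus_density,
                 benign_ki67_fraction = benign_ki67_fraction,
                 downsample = as.integer(downsample),
                 rng_seed = as.integer(rng_seed)),
            class = "slide_spec")
}

# region class -> annotation label
region_class_label <- function(class) {
  switch(class, tumour = "tumour", infiltrate = "infiltrate", "non-tumour")
}

# Per-class appearance: base tissue colour and nucleus colour/geometry.
slide_palette <- function() {
  list(
    glass = 249 / 255, glass_sd = 2 / 255, glass_floor = 242 / 255,
    base = list(tumour = c(0.90, 0.87, 0.90),
                benign = c(0.91, 0.88, 0.91),
                stroma = c(0.93, 0.90, 0.92),
                infiltrate = c(0.91, 0.90, 0.93)),
    base_sd = 0.015,
    haematoxylin = c(0.26, 0.28, 0.58),
    lymphocyte = c(0.18, 0.20, 0.50),
    dab = c(0.55, 0.33, 0.14),
    colour_jitter = 0.04)
}

#' Generate a synthetic pseudo-slide with exact ground truth
#'
#' Renders the slide described by a [slide_spec()]: glass background,
#' per-region tissue base colour with texture noise, and nuclei drawn as
#' anti-aliased filled ellipses with jittered radius, orientation and
#' hue.  Ki67-positive nuclei are DAB-brown, all others haematoxylin
#' blue.  Within each tumour region, exactly `round(n * ki67_fraction)`
#' of the n nuclei are positive, so the realised fraction matches the
#' requested one to within 1/n.
#'
#' @param spec a [slide_spec()].
#' @return A list with elements `slide` (a `pseudo_slide`: RGB array in
#'   `[0, 1]` plus resolution metadata) and `ground_truth` (label mask at
#'   `spec$downsample`, the matching [annotation_set()], full-resolution
#'   DAB-positive nucleus mask, and the nucleus table).
#' @export
generate_pseudo_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  w <- spec$width_px; h <- spec$height_px
  pal <- slide_palette()

  # annotation set mirroring the regions (benign/stroma -> non-tumour)
  ann <- annotation_set(lapply(spec$regions, function(r)
    list(polygon = r$polygon, label = region_class_label(r$class))),
    slide_dims = c(w, h))
  label_mask <- rasterise_annotations(ann, spec$downsample)

  # full-resolution region-identity raster (paint priority: infiltrate >
  # tumour > non-tumour, matching the annotation label priority)
  nreg <- length(spec$regions)
  classes <- vapply(spec$regions, `[[`, "", "class")
  codes <- annotation_label_codes()
  prio <- codes[vapply(classes, region_class_label, "")]
  ord <- order(prio)
  region_raster <- if (nreg)
    rasterise_polygons_cpp(lapply(spec$regions[ord], `[[`, "polygon"),
                           as.integer(seq_len(nreg)[ord]), w, h, 1L)
  else matrix(0L, h, w)

  # full-res tissue support = nearest-neighbour upsample of label_mask,
  # so DAB ground truth can never fall on a pixel the downsampled mask
  # calls background
  d <- spec$downsample
  tissue_full <- label_mask[pmin(nrow(label_mask), (seq_len(h) - 1L) %/% d + 1L),
                            pmin(ncol(label_mask), (seq_len(w) - 1L) %/% d + 1L),
                            drop = FALSE] > 0L

  out <- with_seed(spec$rng_seed, {
    img <- array(clamp(pal$glass + rnorm(h * w * 3, 0, pal$glass_sd),
                       pal$glass_floor, 1), dim = c(h, w, 3))
    dab <- matrix(FALSE, h, w)
    nuclei <- list()

    for (ri in seq_len(nreg)) {
      r <- spec$regions[[ri]]
      sel <- which(region_raster == ri)
      if (length(sel) == 0)
        stopf("region %d rasterises to zero pixels", ri)
      # tissue base colour with texture noise
      base <- pal$base[[r$class]]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- clamp(base[ch] + rnorm(length(sel), 0, pal$base_sd))
        img[, , ch] <- plane
      }
      # nucleus count from density (per 1000 px2 of realised region area)
      n <- round(spec$nucleus_density[[r$class]] / 1000 * length(sel))
      if (n < 1)
        stopf("region %d (%s): nucleus density yields zero nuclei", ri, r$class)
      placeable <- sel[tissue_full[sel]]
      if (length(placeable) == 0) placeable <- sel
      at <- sample(placeable, n, replace = n > length(placeable))
      # 0-based pixel coords with sub-pixel jitter
      cy <- (at - 1L) %% h + runif(n)
      cx <- (at - 1L) %/% h + runif(n)
      if (r$class == "infiltrate") {
        a <- runif(n, 1.8, 2.8); b <- a * runif(n, 0.85, 1)
      } else {
        a <- runif(n, spec$nucleus_radius_px[1], spec$nucleus_radius_px[2])
        b <- a * if (r$class == "stroma") runif(n, 0.35, 0.55)
                 else runif(n, 0.75, 1)
      }
      theta <- runif(n, 0, pi)
      frac <- switch(r$class, tumour = r$ki67_fraction,
                     benign = spec$benign_ki67_fraction, 0)
      npos <- round(frac * n)
      positive <- rep(FALSE, n)
      if (npos > 0) positive[sample.int(n, npos)] <- TRUE
      basecol <- switch(r$class, infiltrate = pal$lymphocyte,
                        pal$haematoxylin)
      cols <- matrix(rep(basecol, each = n), n, 3)
      cols[positive, ] <- matrix(rep(pal$dab, each = sum(positive)),
                                 sum(positive), 3)
      cols <- clamp(cols + matrix(rnorm(3 * n, 0, pal$colour_jitter), n, 3))
      nuclei[[ri]] <- data.frame(region_id = ri, class = r$class,
                                 x = cx, y = cy, a = a, b = b, theta = theta,
                                 positive = positive,
                                 col_r = cols[, 1], col_g = cols[, 2],
                                 col_b = cols[, 3])
      # render (later nuclei paint over earlier ones)
      support <- region_raster == ri & tissue_full
      drawn <- render_nuclei(img, dab, support, cx, cy, a, b, theta,
                             cols, positive)
      img <- drawn$img; dab <- drawn$dab
    }
    list(img = img, dab = dab,
         nuclei = if (length(nuclei)) do.call(rbind, nuclei)
                  else empty_nucleus_table())
  })

  slide <- structure(list(img = out$img, microns_per_px = spec$microns_per_px,
                          slide_id = sprintf("synthetic-%d", spec$rng_seed)),
                     class = "pseudo_slide")
  gt <- structure(list(label_mask = label_mask, downsample = d,
                       annotation_set = ann, ki67_positive_mask = out$dab,
                       nuclei = out$nuclei, region_raster = region_raster,
                       spec = spec),
                  class = "ground_truth")
  list(slide = slide, ground_truth = gt)
}

empty_nucleus_table <- function() {
  data.frame(region_id = integer(), class = character(), x = numeric(),
             y = numeric(), a = numeric(), b = numeric(), theta = numeric(),
             positive = logical(), col_r = numeric(), col_g = numeric(),
             col_b = numeric())
}

# Draw a batch of anti-aliased filled ellipses (nuclei), restricted to
# `support` pixels.  Later nuclei paint over earlier ones; the DAB mask
# records pixels whose top-most opaque (> 0.5 alpha) nucleus is
# Ki67-positive.  Batched so the large image array is copied once per
# call rather than once per nucleus.
render_nuclei <- function(img, dab, support, cx, cy, a, b, theta, cols,
                          positive) {
  h <- nrow(support); w <- ncol(support)
  for (k in seq_along(cx)) {
    rmax <- max(a[k], b[k]) + 1
    x0 <- max(0, floor(cx[k] - rmax)); x1 <- min(w - 1, ceiling(cx[k] + rmax))
    y0 <- max(0, floor(cy[k] - rmax)); y1 <- min(h - 1, ceiling(cy[k] + rmax))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs + 0.5 - cx[k])
    dy <- outer(ys + 0.5 - cy[k], rep(1, length(xs)))
    u <- (cos(theta[k]) * dx + sin(theta[k]) * dy) / a[k]
    v <- (-sin(theta[k]) * dx + cos(theta[k]) * dy) / b[k]
    # ~1 px anti-aliased edge
    alpha <- clamp((1 - sqrt(u * u + v * v)) * max(a[k], b[k]) + 0.5)
    alpha[!support[ys + 1, xs + 1, drop = FALSE]] <- 0
    if (all(alpha == 0)) next
    rows <- ys + 1; colsx <- xs + 1
    for (ch in 1:3) {
      blk <- img[rows, colsx, ch, drop = FALSE][, , 1]
      img[rows, colsx, ch] <- blk * (1 - alpha) + cols[k, ch] * alpha
    }
    blk <- dab[rows, colsx, drop = FALSE]
    dab[rows, colsx] <- if (positive[k]) blk | (alpha > 0.5)
                        else blk & !(alpha > 0.5)
  }
  list(img = img, dab = dab)
}

#' Plant a proliferation hotspot in a synthetic tumour region
#'
#' Raises (or lowers) the Ki67-positive nucleus fraction inside a disc
#' centred on `centre` to `ki67_fraction` by recolouring the minimum
#' number of existing tumour nuclei, redrawing them and updating the
#' DAB ground-truth mask consistently.
#'
#' @param slide a `pseudo_slide` from [generate_pseudo_slide()].
#' @param gt the matching `ground_truth`.
#' @param centre length-2 numeric (x, y); must lie inside a tumour
#'   region polygon.
#' @param radius_px disc radius in pixels; must be positive (a zero
#'   radius is rejected as degenerate geometry).
#' @param ki67_fraction target positive fraction among tumour nuclei
#'   whose centres fall inside the disc.
#' @param seed seed for choosing which nuclei flip.
#' @return A list with updated `slide` and `ground_truth`.
#' @export
plant_hotspot <- function(slide, gt, centre, radius_px, ki67_fraction,
                          seed = 1L) {
  stopifnot(inherits(slide, "pseudo_slide"), inherits(gt, "ground_truth"))
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px <= 0)
    stopf("radius_px must be a positive number")
  if (ki67_fraction < 0 || ki67_fraction > 1)
    stopf("ki67_fraction must lie in [0, 1]")
  tum <- which(vapply(gt$annotation_set$regions, `[[`, "", "label") == "tumour")
  inside <- any(vapply(tum, function(i)
    point_in_polygon(centre[1], centre[2],
                     gt$annotation_set$regions[[i]]$polygon), TRUE))
  if (!inside)
    stopf("hotspot centre (%g, %g) is not inside a tumour region",
          centre[1], centre[2])

  nuc <- gt$nuclei
  in_disc <- nuc$class == "tumour" &
    (nuc$x - centre[1])^2 + (nuc$y - centre[2])^2 <= radius_px^2
  n_disc <- sum(in_disc)
  if (n_disc == 0) return(list(slide = slide, ground_truth = gt))
  target <- round(ki67_fraction * n_disc)
  cur <- sum(nuc$positive[in_disc])
  if (target == cur) return(list(slide = slide, ground_truth = gt))

  pal <- slide_palette()
  flips <- with_seed(seed, {
    if (target > cur) {
      cand <- which(in_disc & !nuc$positive)
      sample(cand, target - cur)
    } else {
      cand <- which(in_disc & nuc$positive)
      sample(cand, cur - target)
    }
  })
  to_positive <- target > cur
  img <- slide$img
  dab <- gt$ki67_positive_mask
  d <- gt$downsample
  h <- nrow(dab); w <- ncol(dab)
  tissue_full <- gt$label_mask[
    pmin(nrow(gt$label_mask), (seq_len(h) - 1L) %/% d + 1L),
    pmin(ncol(gt$label_mask), (seq_len(w) - 1L) %/% d + 1L),
    drop = FALSE] > 0L
  newcols <- with_seed(seed + 1L, {
    base <- if (to_positive) pal$dab else pal$haematoxylin
    clamp(matrix(rep(base, each = length(flips)), length(flips), 3) +
          matrix(rnorm(3 * length(flips), 0, pal$colour_jitter),
                 length(flips), 3))
  })
  for (rid in unique(nuc$region_id[flips])) {
    sel <- flips[nuc$region_id[flips] == rid]
    support <- gt$region_raster == rid & tissue_full
    drawn <- render_nuclei(img, dab, support, nuc$x[sel], nuc$y[sel],
                           nuc$a[sel], nuc$b[sel], nuc$theta[sel],
                           newcols[match(sel, flips), , drop = FALSE],
                           rep(to_positive, length(sel)))
    img <- drawn$img; dab <- drawn$dab
  }
  nuc$positive[flips] <- to_positive
  nuc$col_r[flips] <- newcols[, 1]
  nuc$col_g[flips] <- newcols[, 2]
  nuc$col_b[flips] <- newcols[, 3]
  slide$img <- img
  gt$ki67_positive_mask <- dab
  gt$nuclei <- nuc
  list(slide = slide, ground_truth = gt)
}

#' @export
print.pseudo_slide <- function(x, ...) {
  cat(sprintf("<pseudo_slide> %d x %d px, %.2f um/px, id '%s'\n",
              ncol(x$img), nrow(x$img), x$microns_per_px, x$slide_id))
  invisible(x)
}

#' Write a pseudo-slide image to PNG or TIFF
#'
#' @param slide a `pseudo_slide`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(slide$img, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(slide$img, path)
  else stopf("unsupported slide format '.%s' (use png or tiff)", ext)
  invisible(path)
}

#' Read a slide image written by [write_slide()]
#'
#' @param path PNG or TIFF path.
#' @param microns_per_px resolution metadata to attach.
#' @param slide_id identifier to attach (defaults to the file name).
#' @return A `pseudo_slide`.
#' @export
read_slide <- function(path, microns_per_px = 0.5, slide_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stopf("unsupported slide format '.%s' (use png or tiff)", ext)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  structure(list(img = img, microns_per_px = microns_per_px,
                 slide_id = slide_id), class = "pseudo_slide")
}
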