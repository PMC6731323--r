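#' Polygon annotation sets
#'
#' An `annotation_set` holds labelled polygon regions in level-0 pixel
#' coordinates (0-based, x rightwards, y downwards), mirroring the
#' structure of pathologist annotations drawn in Aperio ImageScope.
#' Labels come from the closed vocabulary `tumour`, `non-tumour`,
#' `infiltrate`.
#'
#' @param regions list of regions, each a list with elements `polygon`
#'   (an n x 2 numeric matrix of x, y vertices, n >= 3), `label`
#'   (one of `"tumour"`, `"non-tumour"`, `"infiltrate"`) and optionally
#'   `region_id` (integer; assigned sequentially when missing).
#' @param slide_dims integer vector `c(width, height)` of the level-0 slide.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(regions = list(), slide_dims) {
  if (length(slide_dims) != 2 || any(slide_dims < 1))
    stopf("slide_dims must be c(width, height) with positive entries")
  regions <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    poly <- r$polygon
    if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3)
      stopf("region %d: polygon must be an n x 2 matrix with n >= 3", i)
    if (!r$label %in% annotation_labels())
      stopf("region %d: unknown label '%s'; known labels: %s", i, r$label,
            paste(annotation_labels(), collapse = ", "))
    if (polygon_self_intersects(poly))
      stopf("region %d: polygon is self-intersecting", i)
    list(polygon = unname(poly), label = r$label,
         region_id = if (is.null(r$region_id)) i else as.integer(r$region_id))
  })
  structure(list(regions = regions,
                 slide_dims = as.integer(slide_dims)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$regions, `[[`, "", "label")
  cat(sprintf("<annotation_set> %d region(s) on a %d x %d slide\n",
              length(x$regions), x$slide_dims[1], x$slide_dims[2]))
  if (length(labs)) print(table(labs))
  invisible(x)
}

annotation_labels <- function() c("tumour", "non-tumour", "infiltrate")

# label -> integer code used in rasterised masks
annotation_label_codes <- function()
  c("non-tumour" = 1L, "tumour" = 2L, "infiltrate" = 3L)

# Proper segment-intersection test over non-adjacent edge pairs.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Default mapping from ImageScope layer/region names to labels
#'
#' ImageScope layer naming is free text, so the mapping from names found
#' in an XML file to the package's label vocabulary is configuration.
#' The default accepts the vocabulary itself plus common spellings.
#'
#' @return Named character vector mapping source names to labels.
#' @export
default_label_map <- function() {
  c("tumour" = "tumour", "tumor" = "tumour", "Tumour" = "tumour",
    "Tumor" = "tumour",
    "non-tumour" = "non-tumour", "non-tumor" = "non-tumour",
    "Non-tumour" = "non-tumour", "Non-tumor" = "non-tumour",
    "normal" = "non-tumour", "Normal" = "non-tumour",
    "infiltrate" = "infiltrate", "Infiltrate" = "infiltrate",
    "lymphocytic infiltrate" = "infiltrate")
}

#' Read an ImageScope-style annotation XML file
#'
#' Parses `Annotations/Annotation/Regions/Region/Vertices/Vertex`
#' documents as written by Aperio ImageScope.  The label of each region
#' is taken from the `Text` attribute of the `Region` when present,
#' falling back to the `Name` attribute of the enclosing `Annotation`
#' layer, and translated through `label_map`.
#'
#' @param path path to the XML file.
#' @param slide_dims `c(width, height)` of the slide in level-0 pixels.
#' @param label_map named character vector mapping layer/region names to
#'   labels; see [default_label_map()].
#' @return An [annotation_set()].
#' @export
read_imagescope_xml <- function(path, slide_dims,
                                label_map = default_label_map()) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf(
                    "failed to parse annotation XML '%s': %s", path,
                    conditionMessage(e)))
  if (xml2::xml_name(doc) != "Annotations")
    stopf("annotation XML root element is <%s>, expected <Annotations>",
          xml2::xml_name(doc))
  regions <- list()
  for (ann in xml2::xml_find_all(doc, "./Annotation")) {
    layer_name <- xml2::xml_attr(ann, "Name")
    for (reg in xml2::xml_find_all(ann, "./Regions/Region")) {
      nm <- xml2::xml_attr(reg, "Text")
      if (is.na(nm) || !nzchar(nm)) nm <- layer_name
      if (is.na(nm) || !nm %in% names(label_map))
        stopf("unknown region label '%s' in '%s'; known labels: %s",
              if (is.na(nm)) "<missing>" else nm, path,
              paste(unique(names(label_map)), collapse = ", "))
      vx <- xml2::xml_find_all(reg, "./Vertices/Vertex")
      if (length(vx) == 0)
        stopf("Region element without Vertices/Vertex in '%s'", path)
      poly <- cbind(as.numeric(xml2::xml_attr(vx, "X")),
                    as.numeric(xml2::xml_attr(vx, "Y")))
      if (anyNA(poly))
        stopf("Vertex element with missing or non-numeric X/Y in '%s'", path)
      id <- suppressWarnings(as.integer(xml2::xml_attr(reg, "Id")))
      regions[[length(regions) + 1L]] <-
        list(polygon = poly, label = unname(label_map[[nm]]),
             region_id = if (is.na(id)) length(regions) + 1L else id)
    }
  }
  annotation_set(regions, slide_dims)
}

#' Write an annotation set as ImageScope-style XML
#'
#' Regions are grouped into one `Annotation` layer per label; vertices
#' are written with full precision so that a read/write round trip is
#' vertex-identical.
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imagescope_xml <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  doc <- xml2::xml_new_root("Annotations")
  labs <- unique(vapply(ann$regions, `[[`, "", "label"))
  lid <- 0L
  for (lab in labs) {
    lid <- lid + 1L
    layer <- xml2::xml_add_child(doc, "Annotation", Id = as.character(lid),
                                 Name = lab)
    regs <- xml2::xml_add_child(layer, "Regions")
    for (r in ann$regions) {
      if (r$label != lab) next
      reg <- xml2::xml_add_child(regs, "Region",
                                 Id = as.character(r$region_id), Text = lab)
      vts <- xml2::xml_add_child(reg, "Vertices")
      for (i in seq_len(nrow(r$polygon)))
        xml2::xml_add_child(vts, "Vertex",
                            X = format(r$polygon[i, 1], digits = 17),
                            Y = format(r$polygon[i, 2], digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Rasterise an annotation set to a label mask
#'
#' Converts polygons to an integer label mask at the given downsample
#' using the pixel-centre coverage rule: mask pixel (u, v) is labelled
#' by the polygon containing the point ((u + 0.5) d, (v + 0.5) d).
#' Overlaps resolve by label priority `infiltrate > tumour > non-tumour
#' > background`; regions of equal priority are painted in region order,
#' so the later region wins.
#'
#' @param ann an [annotation_set()].
#' @param downsample integer downsample factor (>= 1).
#' @return Integer matrix of dimension `ceiling(height / downsample)` x
#'   `ceiling(width / downsample)` with codes 0 background, 1
#'   non-tumour, 2 tumour, 3 infiltrate.
#' @export
rasterise_annotations <- function(ann, downsample = 1L) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!is_count(downsample) || downsample < 1)
    stopf("downsample must be a positive integer")
  codes <- annotation_label_codes()
  labs <- vapply(ann$regions, `[[`, "", "label")
  ord <- order(codes[labs])  # paint low priority first
  rasterise_polygons_cpp(
    lapply(ann$regions[ord], `[[`, "polygon"),
    as.integer(codes[labs][ord]),
    ann$slide_dims[1], ann$slide_dims[2], as.integer(downsample))
}

#' Write a label mask as a single-channel PNG
#'
#' @param mask integer matrix of small non-negative label codes.
#' @param path output path.
#' @param scale integer intensity step per label (default 1 keeps raw
#'   codes; use e.g. 80 for a viewable image).
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path, scale = 1L) {
  png::writePNG(clamp(mask * scale / 255, 0, 1), path)
  invisible(path)
}

#' Read a label mask written by [write_mask_png()]
#'
#' @param path PNG path.
#' @param scale the scale used when writing.
#' @return Integer matrix of label codes.
#' @export
read_mask_png <- function(path, scale = 1L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255 / scale)), nrow(img), ncol(img))
}
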