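#' Tissue detection rule
#'
#' Tissue is separated from glass by the mean intensity (MI) of a patch:
#' a patch is tissue when the mean over all pixels and channels, on the
#' 8-bit scale, falls below the threshold (default 235).
#'
#' @param mi_threshold mean-intensity cut-off on the 0-255 scale,
#'   strictly between 0 and 255.
#' @return A `tissue_rule` object.
#' @export
tissue_rule <- function(mi_threshold = 235) {
  if (mi_threshold <= 0 || mi_threshold >= 255)
    stopf("mi_threshold must lie strictly between 0 and 255")
  structure(list(mi_threshold = mi_threshold), class = "tissue_rule")
}

#' Sliding-window tile grid
#'
#' @param patch_w,patch_h patch dimensions in pixels (default 64 x 64).
#' @param stride_px lattice stride in pixels, `1 <= stride_px <= patch_w`.
#' @return A `tile_grid` object with origin (0, 0) in level-0 coordinates.
#' @export
tile_grid <- function(patch_w = 64L, patch_h = 64L, stride_px = 64L) {
  if (!is_count(stride_px) || stride_px < 1 || stride_px > patch_w)
    stopf("stride_px must be an integer in [1, patch_w]")
  structure(list(patch_w = as.integer(patch_w), patch_h = as.integer(patch_h),
                 stride_px = as.integer(stride_px)), class = "tile_grid")
}

#' Is a patch tissue?
#'
#' @param patch an H x W x 3 RGB array, either in `[0, 1]` or on the
#'   8-bit 0-255 scale (detected from the value range).
#' @param rule a [tissue_rule()].
#' @return `TRUE` iff the mean intensity over all pixels and channels is
#'   below the rule's threshold.
#' @export
is_tissue <- function(patch, rule = tissue_rule()) {
  if (length(dim(patch)) != 3 || dim(patch)[3] != 3)
    stopf("patch must be an H x W x 3 RGB array")
  mi <- mean(patch)
  if (max(patch) <= 1) mi <- mi * 255
  mi < rule$mi_threshold
}

#' Labelled patch sets
#'
#' Container for 64 x 64 RGB training/evaluation patches with class
#' labels and provenance (slide id and tile origin).
#'
#' @param patches H x W x 3 x n array of RGB values in `[0, 1]`.
#' @param labels character/factor vector of length n.
#' @param x,y integer tile origins (0-based level-0 coordinates).
#' @param slide_id character vector (recycled) identifying the slide.
#' @return A `patch_set` object.
#' @export
patch_set <- function(patches, labels, x = NA_integer_, y = NA_integer_,
                      slide_id = NA_character_) {
  if (length(dim(patches)) != 4)
    stopf("patches must be an H x W x C x n array")
  n <- dim(patches)[4]
  if (length(labels) != n)
    stopf("labels (%d) do not match patch count (%d)", length(labels), n)
  structure(list(patches = patches, labels = as.character(labels),
                 x = rep_len(as.integer(x), n), y = rep_len(as.integer(y), n),
                 slide_id = rep_len(as.character(slide_id), n)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf("<patch_set> %d patch(es) of %d x %d x %d\n", d[4], d[1], d[2], d[3]))
  if (d[4]) print(table(x$labels))
  invisible(x)
}

#' Number of patches in a patch set
#' @param x a `patch_set`.
#' @export
length.patch_set <- function(x) dim(x$patches)[4]

#' Per-class patch counts
#'
#' @param patchset a [patch_set()].
#' @return Named integer vector of counts per class label.
#' @export
class_balance <- function(patchset) {
  stopifnot(inherits(patchset, "patch_set"))
  table(factor(patchset$labels))
}

# Concatenate two patch sets (internal).
concat_patch_sets <- function(a, b) {
  if (length.patch_set(b) == 0) return(a)
  if (length.patch_set(a) == 0) return(b)
  da <- dim(a$patches); db <- dim(b$patches)
  if (any(da[1:3] != db[1:3]))
    stopf("patch dimensions differ: %s vs %s",
          paste(da[1:3], collapse = "x"), paste(db[1:3], collapse = "x"))
  patch_set(array(c(a$patches, b$patches), c(da[1:3], da[4] + db[4])),
            c(a$labels, b$labels), c(a$x, b$x), c(a$y, b$y),
            c(a$slide_id, b$slide_id))
}

#' Extract labelled patches from an annotated slide
#'
#' Slides a `patch_w` x `patch_h` window over the stride lattice and
#' emits a patch when (a) the tissue rule holds and (b) at least
#' `purity` of its pixels carry one class label under the rasterised
#' annotations (at downsample 1).  Patches failing either condition are
#' skipped.  With `target = "tumour"` the positive class is tumour and
#' everything else annotated (including infiltrate) is non-tumour; with
#' `target = "infiltrate"` the positive class is infiltrate and other
#' annotated tissue is non-infiltrate.
#'
#' @param slide a `pseudo_slide` (or any object with an `img` array and
#'   `slide_id`).
#' @param ann an [annotation_set()].
#' @param grid a [tile_grid()].
#' @param purity fraction in (0.5, 1] of patch pixels that must share
#'   the label (default 0.9, excluding boundary-ambiguous patches).
#' @param rule a [tissue_rule()].
#' @param target `"tumour"` or `"infiltrate"`, selecting the label
#'   vocabulary.
#' @return A [patch_set()]; empty (with a warning) when `ann` has no
#'   regions.
#' @export
extract_labelled_patches <- function(slide, ann, grid = tile_grid(),
                                     purity = 0.9, rule = tissue_rule(),
                                     target = c("tumour", "infiltrate")) {
  target <- match.arg(target)
  stopifnot(inherits(ann, "annotation_set"))
  if (purity <= 0.5 || purity > 1)
    stopf("purity must lie in (0.5, 1]")
  h <- dim(slide$img)[1]; w <- dim(slide$img)[2]
  pw <- grid$patch_w; ph <- grid$patch_h; s <- grid$stride_px
  empty <- patch_set(array(0, c(ph, pw, 3, 0)), character())
  if (length(ann$regions) == 0) {
    warning("annotation set is empty; returning an empty patch set")
    return(empty)
  }
  if (w < pw || h < ph) return(empty)
  labmask <- rasterise_annotations(ann, 1L)
  xs <- seq(0L, w - pw, by = s)
  ys <- seq(0L, h - ph, by = s)
  min_px <- purity * pw * ph
  keep_x <- integer(); keep_y <- integer(); keep_lab <- character()
  for (x0 in xs) {
    for (y0 in ys) {
      sub <- labmask[(y0 + 1):(y0 + ph), (x0 + 1):(x0 + pw)]
      counts <- tabulate(sub + 1L, nbins = 4L)  # bg, non-tumour, tumour, infiltrate
      if (target == "tumour") {
        pos <- counts[3]; neg <- counts[2] + counts[4]
        poslab <- "tumour"; neglab <- "non-tumour"
      } else {
        pos <- counts[4]; neg <- counts[2] + counts[3]
        poslab <- "infiltrate"; neglab <- "non-infiltrate"
      }
      lab <- if (pos >= min_px) poslab
             else if (neg >= min_px) neglab
             else next
      if (!is_tissue(slide$img[(y0 + 1):(y0 + ph), (x0 + 1):(x0 + pw), ,
                               drop = FALSE], rule)) next
      keep_x <- c(keep_x, x0); keep_y <- c(keep_y, y0)
      keep_lab <- c(keep_lab, lab)
    }
  }
  n <- length(keep_x)
  if (n == 0) return(empty)
  patches <- array(0, c(ph, pw, 3, n))
  for (i in seq_len(n))
    patches[, , , i] <- slide$img[(keep_y[i] + 1):(keep_y[i] + ph),
                                  (keep_x[i] + 1):(keep_x[i] + pw), ]
  patch_set(patches, keep_lab, keep_x, keep_y, slide$slide_id)
}

#' Dihedral data augmentation
#'
#' Appends transformed copies of every patch for each requested
#' operation; with `k` operations the output holds `(1 + k)` times the
#' input patches.  Labels and provenance are preserved.  Only rigid
#' dihedral transforms are offered; photometric jitter is deliberately
#' excluded so the classifier stays stain-sensitive.
#'
#' @param patchset a [patch_set()].
#' @param ops character vector drawn from `"hflip"`, `"vflip"`,
#'   `"rot90"`, `"rot180"`, `"rot270"`.
#' @param seed unused by the deterministic dihedral transforms; kept so
#'   stochastic augmentations could be added without an interface
#'   change.
#' @return The augmented [patch_set()].
#' @export
augment_patches <- function(patchset, ops = character(), seed = 1L) {
  stopifnot(inherits(patchset, "patch_set"))
  known <- c("hflip", "vflip", "rot90", "rot180", "rot270")
  bad <- setdiff(ops, known)
  if (length(bad))
    stopf("unknown augmentation op(s): %s (known: %s)",
          paste(bad, collapse = ", "), paste(known, collapse = ", "))
  out <- patchset
  for (op in ops) {
    tr <- patchset
    tr$patches <- apply_dihedral(patchset$patches, op)
    out <- concat_patch_sets(out, tr)
  }
  out
}

# Apply one dihedral op to an H x W x C x n array.  Rotations are
# counter-clockwise in image (x right, y down) coordinates.
apply_dihedral <- function(p, op) {
  d <- dim(p)
  switch(op,
    hflip = p[, d[2]:1, , , drop = FALSE],
    vflip = p[d[1]:1, , , , drop = FALSE],
    rot180 = p[d[1]:1, d[2]:1, , , drop = FALSE],
    rot90 = aperm(p, c(2, 1, 3, 4))[d[2]:1, , , , drop = FALSE],
    rot270 = aperm(p, c(2, 1, 3, 4))[, d[1]:1, , , drop = FALSE],
    stopf("unknown op '%s'", op))
}

#' Append reviewed false-positive/false-negative regions to a training set
#'
#' Mirrors the retraining loop in which a reviewer marks false regions
#' on a probability map: false-positive patches re-enter training as
#' `non-tumour`, false-negative patches as `tumour` (their stored labels
#' are overwritten).  Duplicate positions are allowed by contract; a
#' patch may legitimately re-enter training more than once.
#'
#' @param train the current training [patch_set()].
#' @param fp patch set of false-positive regions (may be `NULL`).
#' @param fn patch set of false-negative regions (may be `NULL`).
#' @param positive,negative the label pair of the classifier (defaults
#'   tumour / non-tumour).
#' @return The concatenated [patch_set()].
#' @export
append_false_regions <- function(train, fp = NULL, fn = NULL,
                                 positive = "tumour",
                                 negative = "non-tumour") {
  stopifnot(inherits(train, "patch_set"))
  if (!all(train$labels %in% c(positive, negative)))
    stopf("training labels outside the {%s, %s} vocabulary", positive, negative)
  out <- train
  if (!is.null(fp) && length.patch_set(fp) > 0) {
    fp$labels <- rep(negative, length.patch_set(fp))
    out <- concat_patch_sets(out, fp)
  }
  if (!is.null(fn) && length.patch_set(fn) > 0) {
    fn$labels <- rep(positive, length.patch_set(fn))
    out <- concat_patch_sets(out, fn)
  }
  out
}
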