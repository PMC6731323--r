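test_that("the tissue rule thresholds the mean intensity at MI < 235", {
  glass <- array(1, c(64, 64, 3))            # all-255 on the 8-bit scale
  expect_false(is_tissue(glass))
  black <- array(0, c(64, 64, 3))
  expect_true(is_tissue(black))
  # half 255, half 200 -> MI 227.5 < 235
  half <- array(255 / 255, c(64, 64, 3))
  half[1:32, , ] <- 200 / 255
  expect_equal(mean(half) * 255, 227.5)
  expect_true(is_tissue(half))
  expect_error(is_tissue(array(0, c(64, 64))), "RGB")
  expect_error(tissue_rule(0), "between")
})

test_that("is_tissue agrees with direct mean arithmetic on random patches", {
  set.seed(13)
  rule <- tissue_rule()
  for (i in 1:200) {
    p <- random_patch(8, 8)
    expect_identical(is_tissue(p, rule), mean(p * 255) < 235)
  }
})

test_that("a fully annotated slide yields the full grid of pure patches", {
  # 640 x 640 slide entirely covered by one tumour polygon, stride 64
  img <- array(0.45, c(640, 640, 3))   # dark enough to be tissue
  slide <- structure(list(img = img, microns_per_px = 0.5, slide_id = "s"),
                     class = "pseudo_slide")
  ann <- annotation_set(list(list(polygon = rect_poly(0, 0, 640, 640),
                                  label = "tumour")), c(640, 640))
  ps <- extract_labelled_patches(slide, ann, tile_grid(stride_px = 64L))
  expect_equal(dim(ps$patches)[4], 100)
  expect_true(all(ps$labels == "tumour"))
  # all positions on the stride lattice and fully inside the slide
  expect_true(all(ps$x %% 64 == 0 & ps$y %% 64 == 0))
  expect_true(all(ps$x + 64 <= 640 & ps$y + 64 <= 640))
})

test_that("patches straddling a class boundary are skipped at purity 1", {
  img <- array(0.45, c(128, 128, 3))
  slide <- structure(list(img = img, microns_per_px = 0.5, slide_id = "s"),
                     class = "pseudo_slide")
  # tumour on the left 96 columns, non-tumour right: at stride 64 the
  # (64, 0) patch is half/half
  ann <- annotation_set(list(
    list(polygon = rect_poly(0, 0, 96, 128), label = "tumour"),
    list(polygon = rect_poly(96, 0, 128, 128), label = "non-tumour")),
    c(128, 128))
  ps <- extract_labelled_patches(slide, ann, tile_grid(stride_px = 64L),
                                 purity = 1)
  expect_equal(sort(unique(ps$x[ps$labels == "tumour"])), 0)
  expect_false(any(ps$x == 64))
})

test_that("an all-glass slide yields no patches", {
  img <- array(0.985, c(256, 256, 3))
  slide <- structure(list(img = img, microns_per_px = 0.5, slide_id = "s"),
                     class = "pseudo_slide")
  ann <- annotation_set(list(list(polygon = rect_poly(0, 0, 256, 256),
                                  label = "tumour")), c(256, 256))
  ps <- extract_labelled_patches(slide, ann, tile_grid(stride_px = 64L))
  expect_equal(dim(ps$patches)[4], 0)
})

test_that("an empty annotation set warns and yields an empty patch set", {
  slide <- fx_small_gen()$slide
  ann <- annotation_set(list(), c(640, 640))
  expect_warning(ps <- extract_labelled_patches(slide, ann), "empty")
  expect_equal(dim(ps$patches)[4], 0)
})

test_that("higher purity yields a subset of the lower-purity extraction", {
  gen <- fx_small_gen()
  lo <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                 tile_grid(stride_px = 64L), purity = 0.6)
  hi <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                 tile_grid(stride_px = 64L), purity = 0.95)
  keylo <- paste(lo$x, lo$y, lo$labels)
  keyhi <- paste(hi$x, hi$y, hi$labels)
  expect_true(all(keyhi %in% keylo))
  expect_lte(length(keyhi), length(keylo))
})

test_that("augmentation multiplies the set and involutions cancel", {
  gen <- fx_small_gen()
  ps <- extract_labelled_patches(gen$slide, gen$ground_truth$annotation_set,
                                 tile_grid(stride_px = 64L))
  ps <- ihcseg:::subsample_balanced(ps, 5L, 1L)
  n <- dim(ps$patches)[4]
  expect_identical(augment_patches(ps, character())$patches, ps$patches)
  h <- augment_patches(ps, "hflip")
  expect_equal(dim(h$patches)[4], 2 * n)
  expect_identical(h$labels, c(ps$labels, ps$labels))
  # applying hflip to the flipped half returns the originals
  flipped <- h$patches[, , , (n + 1):(2 * n), drop = FALSE]
  expect_equal(ihcseg:::apply_dihedral(flipped, "hflip"), ps$patches)
  # rot90 applied four times is the identity
  r <- ps$patches
  for (i in 1:4) r <- ihcseg:::apply_dihedral(r, "rot90")
  expect_equal(r, ps$patches)
  all5 <- augment_patches(ps, c("hflip", "vflip", "rot90", "rot180", "rot270"))
  expect_equal(dim(all5$patches)[4], 6 * n)
  expect_error(augment_patches(ps, "zoom"), "unknown augmentation")
})

test_that("reviewed false regions are appended with corrected labels", {
  mk <- function(n, lab) patch_set(array(runif(64 * 64 * 3 * n),
                                         c(64, 64, 3, n)),
                                   rep(lab, n))
  train <- append_false_regions(mk(60, "tumour"), fp = NULL, fn = NULL)
  expect_equal(dim(train$patches)[4], 60)
  base <- concat <- ihcseg:::concat_patch_sets(mk(50, "tumour"),
                                               mk(50, "non-tumour"))
  out <- append_false_regions(base, fp = mk(10, "tumour"),
                              fn = mk(5, "non-tumour"))
  expect_equal(dim(out$patches)[4], 115)
  expect_equal(sum(out$labels == "tumour"), 55)       # 50 + 5 FN
  expect_equal(sum(out$labels == "non-tumour"), 60)   # 50 + 10 FP
  bad <- patch_set(array(0, c(32, 32, 3, 2)), rep("tumour", 2))
  expect_error(append_false_regions(base, fp = bad), "dimensions differ")
})
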