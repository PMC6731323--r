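test_that("tile scores assemble onto the lattice with per-cell averaging", {
  # 640 x 640, stride 64, no overlap: a 10 x 10 grid
  m <- assemble_probability_map(x = c(0, 64), y = c(0, 0),
                                scores = c(0.2, 0.9),
                                slide_dims = c(640, 640), stride_px = 64L)
  expect_equal(dim(m$p), c(10, 10))
  expect_equal(m$p[1, 1], 0.2)
  expect_equal(m$p[1, 2], 0.9)
  expect_true(is.na(m$p[5, 5]))          # uncovered cells are background
  expect_equal(sum(m$coverage > 0), 2)
  # overlapping tiles average: cells covered by scores 0.6 and 0.8 -> 0.7
  ov <- assemble_probability_map(x = c(0, 32), y = c(0, 0),
                                 scores = c(0.6, 0.8),
                                 slide_dims = c(128, 64), stride_px = 32L)
  expect_equal(ov$p[1, 2], 0.7)          # cell under both tiles
  expect_equal(ov$p[1, 1], 0.6)          # only the first tile
  expect_equal(ov$p[1, 3], 0.8)
})

test_that("inference covers tissue and skips glass", {
  model <- fx_tumour_model()
  # all-glass slide: nothing is scored
  glass <- structure(list(img = array(0.985, c(256, 256, 3)),
                          microns_per_px = 0.5, slide_id = "glass"),
                     class = "pseudo_slide")
  m <- infer_slide(glass, model, 64L)
  expect_equal(sum(m$coverage), 0)
  expect_true(all(is.na(m$p)))
  tiny <- structure(list(img = array(0.2, c(32, 32, 3)),
                         microns_per_px = 0.5, slide_id = "t"),
                    class = "pseudo_slide")
  expect_error(infer_slide(tiny, model), "smaller than")
  expect_error(infer_slide(glass, model, stride_px = 48L), "divide")
})

test_that("infiltrate exclusion forces cells to non-tumour and is idempotent", {
  mk <- function(p) {
    m <- assemble_probability_map(x = rep(c(0, 32, 64), 3),
                                  y = rep(c(0, 32, 64), each = 3),
                                  scores = p, slide_dims = c(128, 128),
                                  stride_px = 32L)
    m
  }
  tm <- mk(rep(0.9, 9))
  zero <- mk(rep(0, 9))
  ones <- mk(rep(1, 9))
  expect_equal(exclude_infiltrate(tm, zero)$p, tm$p)
  allx <- exclude_infiltrate(tm, ones)
  expect_true(all(allx$p[!is.na(allx$p)] == 0))
  half <- mk(c(rep(1, 4), rep(0, 5)))
  once <- exclude_infiltrate(tm, half)
  twice <- exclude_infiltrate(once, half)
  expect_identical(once$p, twice$p)
  expect_identical(once$excluded, twice$excluded)
  # geometry mismatch
  other <- assemble_probability_map(0, 0, 0.5, c(64, 64), 32L)
  expect_error(exclude_infiltrate(tm, other), "geometry")
})

test_that("binarisation respects the threshold and is monotone", {
  m <- assemble_probability_map(x = c(0, 64, 128, 192), y = rep(0, 4),
                                scores = c(0.5, 0.6, 0.7, 0.8),
                                slide_dims = c(256, 64), stride_px = 64L)
  expect_false(any(binarise_map(m, 1)))
  b55 <- binarise_map(m, 0.55)
  expect_false(b55[1, 1])
  # monotone non-increasing in the threshold
  prev <- sum(binarise_map(m, 0.05))
  for (thr in c(0.3, 0.55, 0.75, 0.95)) {
    cur <- sum(binarise_map(m, thr))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("pseudo-colour bins follow the colour key with half-open edges", {
  bins <- colour_binning()
  expect_equal(probability_bin(c(0.5, 0.6, 0.7, 0.8), bins), 1:4)
  # p exactly 0.75 stays orange (bin 3), matching strict p > 0.75 for red
  expect_equal(probability_bin(0.75, bins), 3L)
  expect_equal(probability_bin(0.55, bins), 1L)
  m <- assemble_probability_map(x = c(0, 64, 128, 192), y = rep(0, 4),
                                scores = c(0.5, 0.6, 0.7, 0.8),
                                slide_dims = c(256, 64), stride_px = 64L)
  img <- render_pseudocolour(m, bins, slide = NULL, opacity = 1)
  want <- grDevices::col2rgb(c("blue", "yellow", "orange", "red")) / 255
  for (i in 1:4) expect_equal(img[1, i, ], unname(want[, i]))
  # uniformly high map renders uniformly red over covered cells
  hi <- assemble_probability_map(x = c(0, 32), y = c(0, 0),
                                 scores = c(0.9, 0.9),
                                 slide_dims = c(96, 32), stride_px = 32L)
  ri <- render_pseudocolour(hi, bins, slide = NULL, opacity = 1)
  expect_equal(ri[1, 1, ], unname(want[, 4]))
  expect_equal(ri[1, 2, ], unname(want[, 4]))
})

test_that("colour binning validates its configuration", {
  expect_error(colour_binning(c(0.7, 0.6)), "increasing")
  expect_error(colour_binning(c(0.5), c("a", "b", "c")), "colours")
})

test_that("halving the stride changes cell probabilities only slightly", {
  gen <- fx_small_gen()
  model <- fx_tumour_model()
  m32 <- infer_slide(gen$slide, model, 32L)
  m16 <- infer_slide(gen$slide, model, 16L)
  # average the fine map onto the coarse lattice and compare
  agg <- matrix(NA_real_, nrow(m32$p), ncol(m32$p))
  for (v in seq_len(nrow(m32$p))) {
    for (u in seq_len(ncol(m32$p))) {
      block <- m16$p[(2 * v - 1):min(2 * v, nrow(m16$p)),
                     (2 * u - 1):min(2 * u, ncol(m16$p))]
      agg[v, u] <- mean(block, na.rm = TRUE)
    }
  }
  both <- !is.na(m32$p) & !is.na(agg)
  expect_gt(sum(both), 100)
  expect_lt(mean(abs(m32$p[both] - agg[both])), 0.05)
})

test_that("cell masks expand consistently to pixel masks", {
  m <- assemble_probability_map(x = c(0, 32), y = c(0, 0),
                                scores = c(0.9, 0.1),
                                slide_dims = c(96, 32), stride_px = 32L)
  px <- map_to_mask(m, binarise_map(m), downsample = 8L)
  expect_equal(dim(px), c(4, 12))
  expect_true(all(px[, 1:4]))
  expect_false(any(px[, 5:12]))
})
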