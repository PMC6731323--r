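test_that("colour deconvolution separates synthetic DAB from haematoxylin", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(0.55, 0.33, 0.14)   # DAB brown
  img[1, 2, ] <- c(0.26, 0.28, 0.58)   # haematoxylin blue
  img[2, 1, ] <- c(0.92, 0.89, 0.91)   # pale stroma
  img[2, 2, ] <- c(1, 1, 1)            # glass
  od <- hdab_deconvolve(img)
  expect_gt(od$dab[1, 1], 0.15)
  expect_lt(od$dab[2, 1], 0.15)
  expect_lt(od$dab[2, 2], 0.02)
  expect_gt(od$haematoxylin[1, 2], od$haematoxylin[2, 1])
})

test_that("extract_dab recovers a synthetic DAB disc and respects the mask", {
  img <- array(0.92, c(200, 200, 3))
  # a DAB disc of radius 20 at (60, 60) and one outside the tumour mask
  fill_disc <- function(img, cx, cy, r, col) {
    for (x in (cx - r):(cx + r)) for (y in (cy - r):(cy + r))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) img[y + 1, x + 1, ] <- col
    img
  }
  img <- fill_disc(img, 60, 60, 20, c(0.55, 0.33, 0.14))
  img <- fill_disc(img, 150, 150, 20, c(0.55, 0.33, 0.14))
  tmask <- matrix(FALSE, 200, 200)
  tmask[1:100, 1:100] <- TRUE
  dab <- extract_dab(img, tmask)
  expect_false(any(dab & !tmask))          # intersection rule
  got <- sum(dab)
  area <- length(which(outer((-20:20)^2, (-20:20)^2, "+") <= 400))
  expect_lt(abs(got - area) / area, 0.10)
  # no DAB at all -> empty mask
  blank <- array(0.92, c(64, 64, 3))
  expect_false(any(extract_dab(blank, matrix(TRUE, 64, 64))))
  # empty tumour mask warns
  expect_warning(out <- extract_dab(img, matrix(FALSE, 200, 200)), "empty")
  expect_false(any(out))
})

test_that("centroids sit at component pixel means under 8-connectivity", {
  m <- matrix(FALSE, 30, 30)
  m[11:13, 11:13] <- TRUE                 # 3x3 block at (10..12, 10..12)
  c1 <- dab_centroids(m)
  expect_equal(unname(c1), cbind(11, 11))
  expect_equal(nrow(dab_centroids(matrix(FALSE, 5, 5))), 0)
  # diagonal pixels join one component (8-connectivity)
  d <- matrix(FALSE, 10, 10)
  d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(nrow(dab_centroids(d)), 1)
})

test_that("component labelling matches a brute-force flood fill", {
  set.seed(55)
  for (i in 1:5) {
    m <- matrix(runif(40 * 40) < 0.25, 40, 40)
    lab <- ihcseg:::label_components_cpp(m)
    want <- oracle_label8(m)
    expect_equal(max(lab), max(want))
    # identical partition: components agree up to label permutation
    key <- paste(lab[m], want[m])
    expect_equal(length(unique(key)), max(want))
  }
})

test_that("subtractive clustering handles degenerate inputs", {
  expect_equal(nrow(subtractive_cluster(matrix(numeric(), 0, 2))), 0)
  one <- matrix(c(10, 20), 1, 2)
  expect_equal(unname(subtractive_cluster(one)), unname(one))
  same <- matrix(rep(c(5, 5), each = 20), 20, 2)
  expect_equal(nrow(subtractive_cluster(same, ra = 10)), 1)
  expect_error(subtractive_cluster(one, ra = 10, rb = 5), "ra < rb")
})

test_that("two well-separated blobs give exactly two centres, one per blob", {
  set.seed(66)
  a <- cbind(rnorm(50, 100, 8), rnorm(50, 100, 8))
  b <- cbind(rnorm(50, 700, 8), rnorm(50, 700, 8))
  centres <- subtractive_cluster(rbind(a, b), ra = 60)
  expect_equal(nrow(centres), 2)
  d_a <- sqrt((centres[, 1] - 100)^2 + (centres[, 2] - 100)^2)
  d_b <- sqrt((centres[, 1] - 700)^2 + (centres[, 2] - 700)^2)
  expect_equal(sum(d_a < 40), 1)
  expect_equal(sum(d_b < 40), 1)
})

test_that("circle scoring matches brute-force pixel counting", {
  set.seed(99)
  dab <- matrix(runif(150 * 150) < 0.3, 150, 150)
  # full and empty discs
  full <- matrix(TRUE, 120, 120)
  r_full <- score_circles(full, cbind(60, 60), 100, 0.2)
  expect_equal(r_full$circles$ki67_ratio, 1)
  expect_true(r_full$circles$is_hotspot)
  r_empty <- score_circles(!full, cbind(60, 60), 100, 0.2)
  expect_equal(r_empty$circles$ki67_ratio, 0)
  expect_false(r_empty$circles$is_hotspot)
  # half-plane fill: ratio 0.5 within one pixel row of the disc
  half <- matrix(FALSE, 120, 120)
  half[, 1:60] <- TRUE
  r_half <- score_circles(half, cbind(59.5, 60), 100, 0.2)
  expect_lt(abs(r_half$circles$ki67_ratio - 0.5), 1 / 100)
  # random discs, including border-clipped ones, vs the oracle
  for (i in 1:20) {
    cx <- runif(1, 0, 149); cy <- runif(1, 0, 149)
    ref <- oracle_disc_ratio(dab, cx, cy, 50)
    got <- score_circles(dab, cbind(cx, cy), 100, 0.2)$circles$ki67_ratio
    expect_equal(got * ref[["tot"]], ref[["pos"]], tolerance = 1e-9)
  }
  expect_error(score_circles(dab, cbind(200, 10)), "outside")
})

test_that("ki67 ratio is invariant under translation of the scene", {
  set.seed(12)
  blob <- matrix(runif(40 * 40) < 0.4, 40, 40)
  big1 <- matrix(FALSE, 400, 400); big1[51:90, 51:90] <- blob
  big2 <- matrix(FALSE, 400, 400); big2[201:240, 151:190] <- blob
  r1 <- score_circles(big1, cbind(70, 70), 100, 0.2)$circles$ki67_ratio
  r2 <- score_circles(big2, cbind(170, 220), 100, 0.2)$circles$ki67_ratio
  expect_equal(r1, r2)
})

test_that("proliferation bands assign by interval with upper-band ties", {
  rep0 <- score_circles(matrix(TRUE, 60, 60), cbind(30, 30), 20, 0.2)
  rep0$circles$ki67_ratio <- 0.18   # synthetic ratios for banding
  rep0$circles <- rep0$circles[rep(1, 5), ]
  rep0$circles$ki67_ratio <- c(0.05, 0.12, 0.18, 0.2, 0.9)
  banded <- band_proliferation(rep0, cut_offs = c(0.1, 0.15, 0.2),
                               band_names = paste0("b", 1:4))
  expect_equal(as.character(banded$circles$band),
               c("b1", "b2", "b3", "b4", "b4"))
  zero <- rep0; zero$circles$ki67_ratio <- rep(0, 5)
  z <- band_proliferation(zero, cut_offs = c(0.1, 0.15, 0.2),
                          band_names = paste0("b", 1:4))
  expect_true(all(z$circles$band == "b1"))
  expect_error(band_proliferation(rep0, c(0.2, 0.1)), "increasing")
})
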