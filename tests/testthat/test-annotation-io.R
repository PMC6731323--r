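test_that("a minimal ImageScope document with one triangular region parses", {
  xml <- '<Annotations><Annotation Id="1" Name="Tumor"><Regions>
    <Region Id="1"><Vertices>
      <Vertex X="10" Y="10"/><Vertex X="90" Y="15"/><Vertex X="50" Y="80"/>
    </Vertices></Region></Regions></Annotation></Annotations>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  ann <- read_imagescope_xml(path, slide_dims = c(100, 100))
  expect_length(ann$regions, 1)
  expect_equal(nrow(ann$regions[[1]]$polygon), 3)
  expect_equal(ann$regions[[1]]$label, "tumour")
})

test_that("a document with zero regions yields an empty set without error", {
  xml <- '<Annotations><Annotation Id="1" Name="Tumor"><Regions/></Annotation></Annotations>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, path)
  ann <- read_imagescope_xml(path, slide_dims = c(100, 100))
  expect_length(ann$regions, 0)
})

test_that("XML write/read round trip is vertex-identical on a five-region set", {
  set.seed(31)
  regions <- c(
    lapply(1:3, function(i) list(
      polygon = random_star_polygon(100 + 60 * i, 120, 20, 40),
      label = "tumour")),
    list(list(polygon = random_star_polygon(80, 300, 25, 45),
              label = "non-tumour")),
    list(list(polygon = random_star_polygon(300, 300, 25, 45),
              label = "infiltrate")))
  ann <- annotation_set(regions, slide_dims = c(400, 400))
  path <- withr::local_tempfile(fileext = ".xml")
  write_imagescope_xml(ann, path)
  back <- read_imagescope_xml(path, slide_dims = c(400, 400))
  expect_length(back$regions, 5)
  # compare by region id: layers regroup regions by label on write
  by_id <- function(a) a$regions[order(vapply(a$regions, `[[`, 0L, "region_id"))]
  a <- by_id(ann); b <- by_id(back)
  for (i in seq_along(a)) {
    expect_identical(b[[i]]$label, a[[i]]$label)
    expect_equal(b[[i]]$polygon, a[[i]]$polygon)
  }
})

test_that("malformed documents and unknown labels fail with clear errors", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<Annotations><Annotation", path)
  expect_error(read_imagescope_xml(path, c(10, 10)), "parse")
  writeLines('<Wrong/>', path)
  expect_error(read_imagescope_xml(path, c(10, 10)), "Annotations")
  writeLines('<Annotations><Annotation Id="1" Name="Mystery"><Regions>
    <Region Id="1"><Vertices><Vertex X="0" Y="0"/><Vertex X="5" Y="0"/>
    <Vertex X="3" Y="4"/></Vertices></Region></Regions></Annotation></Annotations>',
    path)
  expect_error(read_imagescope_xml(path, c(10, 10)), "known labels")
})

test_that("self-intersecting polygons are rejected at load", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(annotation_set(list(list(polygon = bowtie, label = "tumour")),
                              c(20, 20)),
               "self-intersecting")
})

test_that("an axis-aligned rectangle rasterises to exactly its pixel area", {
  ann <- annotation_set(list(list(polygon = rect_poly(0, 0, 10, 10),
                                  label = "tumour")), c(20, 20))
  m <- rasterise_annotations(ann, 1L)
  expect_equal(sum(m == 2L), 100)
  expect_true(all(m[1:10, 1:10] == 2L))
})

test_that("an empty annotation set rasterises to all background", {
  ann <- annotation_set(list(), c(32, 16))
  m <- rasterise_annotations(ann, 1L)
  expect_equal(dim(m), c(16, 32))
  expect_true(all(m == 0L))
})

test_that("overlap priority is infiltrate > tumour > non-tumour", {
  ann <- annotation_set(list(
    list(polygon = rect_poly(0, 0, 30, 30), label = "non-tumour"),
    list(polygon = rect_poly(10, 10, 40, 40), label = "tumour"),
    list(polygon = rect_poly(20, 20, 50, 50), label = "infiltrate")),
    c(64, 64))
  m <- rasterise_annotations(ann, 1L)
  expect_equal(m[5 + 1, 5 + 1], 1L)
  expect_equal(m[15 + 1, 15 + 1], 2L)   # tumour over non-tumour
  expect_equal(m[25 + 1, 25 + 1], 3L)   # infiltrate over both
})

test_that("rasterisation matches brute-force point-in-polygon on random polygons", {
  set.seed(77)
  for (i in 1:12) {
    poly <- random_star_polygon(runif(1, 15, 33), runif(1, 15, 33), 4, 13,
                                nv = sample(4:9, 1))
    ann <- annotation_set(list(list(polygon = poly, label = "tumour")),
                          c(48, 48))
    got <- rasterise_annotations(ann, 1L) == 2L
    want <- oracle_rasterise(poly, 48, 48, 1L)
    expect_identical(got, want)
  }
})

test_that("downsampled rasterisation differs from full resolution only near edges", {
  set.seed(19)
  poly <- random_star_polygon(60, 60, 25, 45, nv = 10)
  ann <- annotation_set(list(list(polygon = poly, label = "tumour")),
                        c(128, 128))
  d <- 4L
  full <- rasterise_annotations(ann, 1L)
  coarse <- rasterise_annotations(ann, d)
  up <- coarse[(seq_len(128) - 1L) %/% d + 1L, (seq_len(128) - 1L) %/% d + 1L]
  diff_idx <- which(up != full, arr.ind = TRUE)
  if (nrow(diff_idx)) {
    # every disagreeing pixel is within d px of the polygon boundary
    n <- nrow(poly)
    edge_dist <- function(px, py) {
      dmin <- Inf
      for (i in seq_len(n)) {
        j <- i %% n + 1
        ax <- poly[i, 1]; ay <- poly[i, 2]
        bx <- poly[j, 1]; by <- poly[j, 2]
        t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
          ((bx - ax)^2 + (by - ay)^2)
        t <- min(max(t, 0), 1)
        dmin <- min(dmin, sqrt((px - (ax + t * (bx - ax)))^2 +
                               (py - (ay + t * (by - ay)))^2))
      }
      dmin
    }
    dists <- apply(diff_idx, 1, function(rc)
      edge_dist(rc[2] - 0.5, rc[1] - 0.5))
    expect_lt(max(dists), d + 1e-9)
  }
  succeed()
})

test_that("rasterised area agrees with the shoelace area for large convex polygons", {
  set.seed(41)
  for (i in 1:8) {
    nv <- sample(5:9, 1)
    th <- sort(runif(nv, 0, 2 * pi))
    R <- runif(1, 22, 40)   # circumradius; area >= 1000 px^2
    poly <- cbind(100 + R * cos(th), 100 + R * sin(th))
    area <- ihcseg:::polygon_area(poly)
    if (area < 1000) next
    ann <- annotation_set(list(list(polygon = poly, label = "tumour")),
                          c(200, 200))
    count <- sum(rasterise_annotations(ann, 1L) == 2L)
    expect_lt(abs(count - area) / area, 0.02)
  }
})

test_that("label masks survive a PNG round trip", {
  gt <- fx_small_gen()$ground_truth
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(gt$label_mask, path)
  expect_identical(read_mask_png(path), unname(gt$label_mask))
})
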