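# Mask handling: component labelling, boundary tracing, rasterization,
# resizing, frame fill, LabelMe parsing.

test_that("a filled square traces to its 36 border pixels in order", {
  m <- matrix(FALSE, 20L, 20L)
  m[6:15, 4:13] <- TRUE
  ct <- extract_contour(m)
  expect_equal(nrow(ct), 36L)
  expect_equal(attr(ct, "n_pixels"), 100L)

  # brute-force border enumeration: true pixels 8-adjacent to a false one
  border <- which(m & !(
    rbind(m[-1, ], FALSE) & rbind(FALSE, m[-20, ]) &
      cbind(m[, -1], FALSE) & cbind(FALSE, m[, -20])
  ), arr.ind = TRUE)
  got <- unique(cbind(ct[, 2L] + 1, ct[, 1L] + 1))
  expect_setequal(paste(got[, 1L], got[, 2L]),
                  paste(border[, 1L], border[, 2L]))

  # traversal order: consecutive vertices are 8-adjacent and distinct
  nxt <- ct[c(2:nrow(ct), 1L), ]
  step <- pmax(abs(nxt[, 1L] - ct[, 1L]), abs(nxt[, 2L] - ct[, 2L]))
  expect_true(all(step >= 1 & step <= 1.5))
})

test_that("contour vertices all lie on the mask boundary", {
  set.seed(31)
  m <- disk_mask(64L, 0.35)
  ct <- extract_contour(m)
  for (i in seq_len(nrow(ct))) {
    r <- ct[i, 2L] + 1L; c <- ct[i, 1L] + 1L
    expect_true(m[r, c])
    nb <- m[max(1, r - 1):min(64, r + 1), max(1, c - 1):min(64, c + 1)]
    on_edge <- r %in% c(1L, 64L) || c %in% c(1L, 64L)
    expect_true(!all(nb) || on_edge)
  }
})

test_that("the largest 8-connected component wins", {
  m <- matrix(FALSE, 30L, 30L)
  m[3:12, 3:12] <- TRUE   # 100 px
  m[20:24, 25] <- TRUE    # 5 px
  ct <- extract_contour(m)
  expect_equal(attr(ct, "n_pixels"), 100L)
  expect_equal(attr(ct, "n_components"), 2L)
  # the traced contour stays inside the big component's bounding box
  expect_true(all(ct[, 1L] >= 2 & ct[, 1L] <= 11))
})

test_that("diagonal-only adjacency counts as one component", {
  m <- matrix(FALSE, 12L, 12L)
  m[2:4, 2:4] <- TRUE
  m[5:8, 5:8] <- TRUE  # touches only at the (4,4)-(5,5) diagonal
  ct <- extract_contour(m)
  expect_equal(attr(ct, "n_components"), 1L)
  expect_equal(attr(ct, "n_pixels"), 9L + 16L)
})

test_that("degenerate masks error cleanly", {
  expect_error(extract_contour(matrix(FALSE, 5L, 5L)),
               class = "wa_empty_mask")
  m <- matrix(FALSE, 5L, 5L); m[3L, 3L] <- TRUE
  expect_error(extract_contour(m), class = "wa_degenerate_polygon")
})

test_that("polygon rasterization follows the even-odd pixel-centre rule", {
  # 2x2 square covering exactly 4 pixel centres
  sq <- rbind(c(-0.5, -0.5), c(1.5, -0.5), c(1.5, 1.5), c(-0.5, 1.5))
  m <- polygon_to_mask(sq, 4L, 4L)
  expect_equal(sum(m), 4L)
  expect_true(all(m[1:2, 1:2]))

  # brute-force half-plane oracle for a convex polygon
  tri <- rbind(c(1, 1), c(20, 3), c(8, 18))
  m2 <- polygon_to_mask(tri, 24L, 24L)
  inside_convex <- function(u, v, poly) {
    n <- nrow(poly)
    s <- sapply(seq_len(n), function(i) {
      j <- i %% n + 1L
      (poly[j, 1] - poly[i, 1]) * (v - poly[i, 2]) -
        (poly[j, 2] - poly[i, 2]) * (u - poly[i, 1])
    })
    all(s > 0) || all(s < 0)
  }
  for (u in 0:23) for (v in 0:23) {
    expect_identical(m2[v + 1L, u + 1L], inside_convex(u, v, tri),
                     label = sprintf("pixel (%d,%d)", u, v))
  }

  # orientation invariance and out-of-frame polygons
  expect_identical(polygon_to_mask(tri[3:1, ], 24L, 24L), m2)
  far <- tri + 100
  expect_equal(sum(polygon_to_mask(far, 24L, 24L)), 0L)
  expect_error(polygon_to_mask(rbind(c(0, 0), c(5, 5), c(10, 10)), 16L, 16L),
               class = "wa_degenerate_polygon")
})

test_that("rasterize-then-trace approximately recovers polygon area", {
  set.seed(32)
  polys <- list(
    rbind(c(20, 30), c(95, 22), c(105, 90), c(30, 100)),       # quad
    rbind(c(60, 10), c(110, 60), c(60, 110), c(10, 60)),       # diamond
    rbind(c(15, 15), c(100, 25), c(80, 95))                    # triangle
  )
  for (poly in polys) {
    m <- polygon_to_mask(poly, 128L, 128L)
    ct <- extract_contour(m)
    # compare the traced pixel-count-corrected area with the source polygon
    a_mask <- attr(ct, "n_pixels")
    a_poly <- shoelace_area(poly)
    expect_lt(abs(a_mask - a_poly) / a_poly, 0.02)
    expect_lt(abs(shoelace_area(ct) - a_poly) / a_poly, 0.05)
  }
})

test_that("frame fill fraction counts pixels and is monotone", {
  expect_equal(frame_fill_fraction(matrix(TRUE, 8L, 8L)), 1)
  expect_equal(frame_fill_fraction(matrix(FALSE, 8L, 8L)), 0)
  m <- matrix(FALSE, 512L, 512L)
  m[1:128, 1:128] <- TRUE
  expect_equal(frame_fill_fraction(m), 0.0625)
  m2 <- m; m2[300, 300] <- TRUE
  expect_gt(frame_fill_fraction(m2), frame_fill_fraction(m))
})

test_that("resizing preserves identity, area fraction and flags aspect", {
  m <- disk_mask(512L, 0.3)
  expect_equal(unname(resize_mask(m, 512L, 512L)), unname(m),
               ignore_attr = TRUE)
  big <- disk_mask(1024L, 0.3)
  small <- resize_mask(big, 512L, 512L)
  expect_equal(dim(small), c(512L, 512L))
  expect_lt(abs(mean(small) - mean(big)) / mean(big), 0.01)
  expect_false(attr(small, "aspect_distorted"))

  wide <- matrix(runif(480 * 640), 480L, 640L)
  out <- resize_image(wide, 512L, 512L)
  expect_equal(dim(out), c(512L, 512L))
  expect_true(attr(out, "aspect_distorted"))

  d <- depth_image(matrix(seq(0.3, 0.8, length.out = 64 * 64), 64L, 64L))
  d2 <- resize_depth(d, 32L, 32L)
  expect_s3_class(d2, "depth_image")
  # nearest-neighbour: every output depth existed in the input
  expect_true(all(d2$depth %in% d$depth))
})

test_that("LabelMe files parse, filter shapes, and round-trip areas", {
  tri <- rbind(c(5, 5), c(40, 8), c(25, 35))
  f <- tempfile(fileext = ".json")
  write_labelme_fixture(f, list(labelme_shape(tri)))
  ann <- read_labelme(f)
  expect_length(ann$shapes, 1L)
  expect_equal(ann$shapes[[1L]]$points, tri, ignore_attr = TRUE)
  expect_equal(ann$width, 64L)
  expect_equal(ann$height, 48L)

  # a rectangle shape is skipped with a warning
  f2 <- tempfile(fileext = ".json")
  write_labelme_fixture(f2, list(
    labelme_shape(tri),
    labelme_shape(rbind(c(0, 0), c(10, 10)), shape_type = "rectangle")
  ))
  expect_warning(ann2 <- read_labelme(f2), "non-polygon")
  expect_length(ann2$shapes, 1L)

  # malformed input
  f3 <- tempfile(fileext = ".json")
  writeLines("{not json", f3)
  expect_error(read_labelme(f3), class = "wa_parse_error")
  f4 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(shapes = list()), f4)
  expect_error(read_labelme(f4), class = "wa_parse_error")

  # polygon -> mask -> contour round trip within rasterization tolerance
  big_tri <- rbind(c(4, 4), c(60, 6), c(34, 44)) / c(1, 1)
  m <- polygon_to_mask(big_tri, 64L, 48L)
  ct <- extract_contour(m)
  expect_lt(abs(shoelace_area(ct) - shoelace_area(big_tri)) /
              shoelace_area(big_tri), 0.08)
})
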