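# Plane fitting, projection, and the two independent polygon-area routes.

test_that("fit_plane recovers exact planes and matches lm-free oracle", {
  # horizontal plane
  set.seed(21)
  pts <- cbind(runif(20), runif(20), 2)
  expect_equal(unname(coef(fit_plane(pts))), c(0, 0, 2), tolerance = 1e-12)

  # exact interpolation of z = 1x + 2y + 3
  xy <- cbind(runif(10), runif(10))
  pts <- cbind(xy, xy[, 1L] + 2 * xy[, 2L] + 3)
  expect_lt(max(abs(coef(fit_plane(pts)) - c(1, 2, 3))), 1e-10)

  # noisy fit equals the explicit normal-equations regression
  xy <- cbind(runif(50, -1, 1), runif(50, -1, 1))
  z <- 0.2 * xy[, 1L] - 0.5 * xy[, 2L] + 1 + rnorm(50, sd = 0.01)
  pts <- cbind(xy, z)
  expect_lt(max(abs(coef(fit_plane(pts)) - normal_equations_plane(pts))),
            1e-9)
})

test_that("fit_plane rejects degenerate inputs", {
  expect_error(fit_plane(matrix(1:6, 2L, 3L)), class = "wa_degenerate_plane")
  # collinear xy footprint (a vertical plane)
  t <- seq(0, 1, length.out = 10L)
  expect_error(fit_plane(cbind(t, 2 * t, rnorm(10))),
               class = "wa_degenerate_plane")
})

test_that("wound_plane methods behave like a fitted model", {
  set.seed(22)
  xy <- cbind(x = runif(30), y = runif(30))
  pts <- cbind(xy, z = 0.3 * xy[, 1L] + 0.1 * xy[, 2L] + 0.5)
  fit <- fit_plane(pts)
  expect_equal(predict(fit, cbind(1, 1)), 0.9, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(pts[, 3L]))
  expect_output(print(summary(fit)), "RMS vertical residual")
})

test_that("plane_cos_theta follows the normal-vector geometry", {
  expect_equal(plane_cos_theta(c(0, 0, 5)), 1)
  expect_equal(plane_cos_theta(c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(plane_cos_theta(c(1, 1, -2)), 1 / sqrt(3))
})

test_that("project_onto_plane is an orthogonal projection", {
  # idempotence for a point already on the plane
  p <- matrix(c(1, 2, 1 * 1 + 2 * 2 + 3), 1L)
  expect_equal(project_onto_plane(p, c(1, 2, 3)), p, ignore_attr = TRUE)
  # horizontal plane drops z
  expect_equal(unname(project_onto_plane(c(1, 2, 5), c(0, 0, 0))),
               matrix(c(1, 2, 0), 1L))
  # hand-computed projection onto z = x
  expect_equal(unname(project_onto_plane(c(0, 0, 2), c(1, 0, 0))),
               matrix(c(1, 0, 1), 1L))

  # property: results satisfy the plane equation; displacement is parallel
  # to the normal
  set.seed(23)
  for (i in 1:10) {
    cf <- c(rnorm(2), rnorm(1))
    q <- matrix(rnorm(30), ncol = 3L)
    qp <- project_onto_plane(q, cf)
    expect_lt(max(abs(cf[1L] * qp[, 1L] + cf[2L] * qp[, 2L] + cf[3L] -
                        qp[, 3L])), 1e-9)
    disp <- q - qp
    n <- c(cf[1L], cf[2L], -1)
    crossnorm <- apply(disp, 1L, function(v) {
      sqrt(sum((c(v[2L] * n[3L] - v[3L] * n[2L],
                  v[3L] * n[1L] - v[1L] * n[3L],
                  v[1L] * n[2L] - v[2L] * n[1L]))^2))
    })
    expect_lt(max(crossnorm), 1e-9 * sqrt(sum(n^2)) * (1 + max(abs(disp))))
  }
})

test_that("tilt-corrected shoelace area matches analytic cases", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(plane_polygon_area(sq, 1), 1)
  expect_equal(plane_polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1)), 1), 0.5)

  # unit square drawn on the plane z = sqrt(3) y (tilt 60 deg): its xy
  # shadow has area 1/2 and the 1/cos rescaling restores area 1
  sq3d <- rbind(c(0, 0, 0), c(1, 0, 0),
                c(1, 0.5, sqrt(3) / 2), c(0, 0.5, sqrt(3) / 2))
  ct <- plane_cos_theta(c(0, sqrt(3), 0))
  expect_equal(ct, 0.5)
  expect_equal(shoelace_area(sq3d[, 1:2]), 0.5)
  expect_equal(plane_polygon_area(sq3d, ct), 1)
})

test_that("steep planes and degenerate polygons are refused", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(plane_polygon_area(sq, 0.05), class = "wa_steep_plane")
  expect_error(plane_polygon_area(sq[1:2, ], 1),
               class = "wa_degenerate_polygon")
})

test_that("cross-product oracle gives closed-form areas and is rigid-motion invariant", {
  set.seed(24)
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  for (i in 1:5) {
    Q <- random_rotation()
    moved <- sq %*% t(Q) + matrix(rnorm(3), 4L, 3L, byrow = TRUE)
    expect_equal(polygon_area_3d(moved), 1, tolerance = 1e-12)
  }
  hexa <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6), 0)
  expect_equal(polygon_area_3d(hexa), 3 * sqrt(3) / 2, tolerance = 1e-12)
})

test_that("the two area routes agree on random planar polygons", {
  set.seed(25)
  worst <- 0
  for (i in 1:100) {
    a <- runif(1, -1.5, 1.5); b <- runif(1, -1.5, 1.5)
    poly <- random_planar_polygon(n = sample(4:12, 1L), a = a, b = b,
                                  c = runif(1, 0.2, 2))
    ct <- plane_cos_theta(c(a, b))
    a1 <- plane_polygon_area(poly, ct)
    a2 <- polygon_area_3d(poly)
    worst <- max(worst, abs(a1 - a2) / a2)
  }
  expect_lt(worst, 1e-9)
})

test_that("polygon area is invariant to vertex order and scales quadratically", {
  set.seed(26)
  poly <- random_planar_polygon(n = 9L, a = 0.4, b = -0.7, c = 1)
  ct <- plane_cos_theta(c(0.4, -0.7))
  a0 <- plane_polygon_area(poly, ct)
  # cyclic rotation
  expect_equal(plane_polygon_area(poly[c(4:9, 1:3), ], ct), a0)
  # reversal
  expect_equal(plane_polygon_area(poly[9:1, ], ct), a0)
  # uniform scaling
  expect_equal(plane_polygon_area(poly * 2.5, ct), 2.5^2 * a0,
               tolerance = 1e-9)
  # z = const reduces to the plain 2D shoelace
  flat <- cbind(poly[, 1:2], 3)
  expect_equal(plane_polygon_area(flat, 1), shoelace_area(poly[, 1:2]))
})
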