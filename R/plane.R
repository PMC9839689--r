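# Least-squares plane fit and tilt-corrected polygon area.
#
# The wound surface is modelled as the plane z = a x + b y + c with the
# shortest average (least-squares) vertical distance to the 3D border
# points: stacking the border coordinates as design matrix A = [x y 1] and
# response B = z reduces the fit to the multiple linear regression B = A x
# for x = (a, b, c). The fit here uses the QR factorization (lm.fit); the
# explicit normal-equations solve (A'A) x = A'B is kept as an independent
# test oracle.

#' Fit a least-squares plane to 3D contour points
#'
#' Fits z = a x + b y + c to the points by least squares. The residual sum
#' of squares is minimal among all (a, b, c); with points exactly on a
#' plane the coefficients are recovered to machine precision.
#'
#' @param points An n x 3 matrix of 3D points (metres), n >= 3, whose (x, y)
#'   footprint is not collinear.
#' @return An object of class `"wound_plane"` with components
#'   `coefficients` (named a, b, c), `cos_theta` (cosine of the angle
#'   between the plane and the x-y plane), `fitted.values`, `residuals`,
#'   and `df.residual`. Supports `coef()`, `predict()`, `residuals()`,
#'   `fitted()`, `print()` and `summary()`.
#' @examples
#' pts <- cbind(x = runif(30), y = runif(30))
#' pts <- cbind(pts, z = 0.2 * pts[, 1] - 0.5 * pts[, 2] + 1)
#' coef(fit_plane(pts))
#' @export
fit_plane <- function(points) {
  points <- as_xyz_matrix(points, "points")
  if (nrow(points) < 3L) {
    stop_wa("plane fitting needs at least 3 points",
            c("wa_degenerate_plane", "wa_geometry_error"))
  }
  if (anyNA(points) || any(!is.finite(points))) {
    stop_wa("plane fitting requires finite coordinates",
            c("wa_degenerate_plane", "wa_geometry_error"))
  }
  A <- cbind(points[, 1L], points[, 2L], 1)
  fit <- lm.fit(A, points[, 3L])
  if (fit$rank < 3L) {
    stop_wa(paste("degenerate plane: the (x, y) footprint of the points is",
                  "collinear (near-vertical surface cannot be written as",
                  "z = a x + b y + c)"),
            c("wa_degenerate_plane", "wa_geometry_error"))
  }
  cf <- setNames(fit$coefficients, c("a", "b", "c"))
  structure(list(
    coefficients = cf,
    cos_theta = plane_cos_theta(cf),
    fitted.values = fit$fitted.values,
    residuals = fit$residuals,
    df.residual = nrow(points) - 3L,
    n = nrow(points)
  ), class = "wound_plane")
}

#' Cosine of the plane's tilt angle
#'
#' For the plane z = a x + b y + c with normal (a, b, -1), the angle theta
#' between the plane and the x-y plane satisfies
#' cos(theta) = 1 / sqrt(a^2 + b^2 + 1), always in (0, 1]. Its reciprocal
#' rescales the xy-shadow area of a polygon on the plane to the true
#' in-plane area.
#'
#' @param p A `"wound_plane"` fit, or a numeric vector whose first two
#'   elements are the slope coefficients a and b.
#' @return The tilt cosine, a scalar in (0, 1].
#' @examples
#' plane_cos_theta(c(a = 1, b = 0, c = 0))  # 1/sqrt(2)
#' @export
plane_cos_theta <- function(p) {
  cf <- if (inherits(p, "wound_plane")) p$coefficients else as.numeric(p)
  1 / sqrt(cf[[1L]]^2 + cf[[2L]]^2 + 1)
}

#' @export
print.wound_plane <- function(x, digits = 6, ...) {
  cf <- x$coefficients
  cat(sprintf("Least-squares plane: z = %s x + %s y + %s  (n = %d)\n",
              format(cf[["a"]], digits = digits),
              format(cf[["b"]], digits = digits),
              format(cf[["c"]], digits = digits), x$n))
  cat(sprintf("Tilt: %.2f deg from the image plane (cos theta = %.5f)\n",
              acos(x$cos_theta) * 180 / pi, x$cos_theta))
  invisible(x)
}

#' @export
summary.wound_plane <- function(object, ...) {
  rms <- sqrt(mean(object$residuals^2))
  structure(list(plane = object, rms_residual = rms),
            class = "summary.wound_plane")
}

#' @export
print.summary.wound_plane <- function(x, ...) {
  print(x$plane)
  cat(sprintf("RMS vertical residual: %.3g m over %d points\n",
              x$rms_residual, x$plane$n))
  invisible(x)
}

#' @export
predict.wound_plane <- function(object, newdata, ...) {
  cf <- object$coefficients
  if (missing(newdata)) return(object$fitted.values)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[, c("x", "y")])
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 2L)
  cf[["a"]] * newdata[, 1L] + cf[["b"]] * newdata[, 2L] + cf[["c"]]
}

#' Orthogonally project points onto a plane
#'
#' Projects each point along the plane normal n = (a, b, -1):
#' q' = q - ((a q_x + b q_y - q_z + c) / (a^2 + b^2 + 1)) n. Points already
#' on the plane are unchanged; vertex order is preserved.
#'
#' @param points An n x 3 matrix of 3D points.
#' @param plane A `"wound_plane"` fit or a coefficient vector (a, b, c).
#' @return An n x 3 matrix of points satisfying z' = a x' + b y' + c.
#' @export
project_onto_plane <- function(points, plane) {
  points <- as_xyz_matrix(points, "points")
  cf <- if (inherits(plane, "wound_plane")) plane$coefficients
        else as.numeric(plane)
  a <- cf[[1L]]; b <- cf[[2L]]; cc <- cf[[3L]]
  s <- (a * points[, 1L] + b * points[, 2L] - points[, 3L] + cc) /
    (a^2 + b^2 + 1)
  out <- points - cbind(s * a, s * b, -s)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Tilt-corrected shoelace area of an in-plane polygon
#'
#' Area of an ordered polygon lying on a fitted plane, computed as the
#' shoelace (cyclic 2x2 determinant) sum of the projected vertices' (x, y)
#' shadow, rescaled by 1 / cos(theta) to the true area on the plane. The
#' absolute value of the signed sum is taken, so vertex orientation does
#' not matter.
#'
#' @param projected An n x 3 (or n x 2) matrix of ordered vertices on the
#'   plane; only the x and y columns enter the determinant sum.
#' @param cos_theta The plane's tilt cosine, from [plane_cos_theta()].
#' @param min_cos_theta Guard against near-vertical planes, where 1/cos
#'   amplifies noise without bound; below this the function errors.
#' @return The polygon area in squared input units (m^2 for metric
#'   contours).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' plane_polygon_area(sq, 1)          # 1
#' plane_polygon_area(sq, 0.5)        # 2: the same shadow on a 60-deg plane
#' @export
plane_polygon_area <- function(projected, cos_theta, min_cos_theta = 0.1) {
  xy <- if (ncol(as.matrix(projected)) >= 3L) {
    as.matrix(projected)[, 1:2, drop = FALSE]
  } else as.matrix(projected)
  xy <- as_polygon_matrix(xy, name = "projected")
  check_number(cos_theta, "cos_theta", positive = TRUE)
  if (cos_theta < min_cos_theta) {
    stop_wa(sprintf(
      "plane too steep: cos(theta) = %.4f < %.2f; area rescaling is unreliable",
      cos_theta, min_cos_theta),
      c("wa_steep_plane", "wa_geometry_error"))
  }
  abs(signed_shoelace(xy)) / cos_theta
}

#' Cross-product area of a planar 3D polygon
#'
#' Independent area formula used to cross-check the tilt-corrected shoelace
#' computation: half the norm of the cyclic sum of vertex cross products,
#' 0.5 * || sum v_i x v_{i+1} ||. Valid for simple polygons whose vertices
#' are coplanar; the result is invariant under rigid motions of the
#' polygon.
#'
#' @param points An n x 3 matrix of ordered polygon vertices.
#' @return The polygon area in squared input units.
#' @export
polygon_area_3d <- function(points) {
  p <- as_xyz_matrix(points, "points")
  if (nrow(p) < 3L) {
    stop_wa("polygon area needs at least 3 vertices",
            c("wa_degenerate_polygon", "wa_geometry_error"))
  }
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  cr <- cbind(p[, 2L] * q[, 3L] - p[, 3L] * q[, 2L],
              p[, 3L] * q[, 1L] - p[, 1L] * q[, 3L],
              p[, 1L] * q[, 2L] - p[, 2L] * q[, 1L])
  s <- colSums(cr)
  sqrt(sum(s^2)) / 2
}
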