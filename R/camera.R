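# Pinhole camera model: intrinsics, extrinsics, back-projection.
#
# Conventions used throughout the package:
#   * Pixel coordinates (u, v) = (column, row), origin at the centre of the
#     top-left pixel, so integer coordinates are pixel centres and
#     u in [0, width - 1], v in [0, height - 1].
#   * Depth is the z-coordinate along the optical axis (not the Euclidean
#     ray length); see ray_length_to_z_depth() for converting range-style
#     depth sources.
#   * The extrinsics map world to camera: X_camera = R %*% X_world + t.
#     World coordinates are metres.

#' Camera intrinsic parameters
#'
#' The pinhole intrinsic matrix K maps camera-frame 3D points to pixels:
#' u = fx * x / z + ox, v = fy * y / z + oy. `fx`, `fy` are the pixel focal
#' lengths; `ox`, `oy` are the principal-point offsets from the top-left
#' corner of the image frame, all in pixels.
#'
#' @param fx,fy Pixel focal lengths; must be positive.
#' @param ox,oy Principal-point offsets (pixels).
#' @return An object of class `"camera_intrinsics"`.
#' @seealso [backproject_pixel()], [world_to_pixel()]
#' @export
camera_intrinsics <- function(fx, fy = fx, ox = 0, oy = 0) {
  check_number(fx, "fx", positive = TRUE)
  check_number(fy, "fy", positive = TRUE)
  check_number(ox, "ox")
  check_number(oy, "oy")
  structure(list(fx = fx, fy = fy, ox = ox, oy = oy),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Camera intrinsics: fx = %g, fy = %g, principal point (%g, %g)\n",
              x$fx, x$fy, x$ox, x$oy))
  invisible(x)
}

#' Intrinsics as a 3x3 matrix
#'
#' @param k A [camera_intrinsics()] object.
#' @return The 3x3 pinhole matrix K.
#' @export
intrinsic_matrix <- function(k) {
  stopifnot(inherits(k, "camera_intrinsics"))
  matrix(c(k$fx, 0, 0, 0, k$fy, 0, k$ox, k$oy, 1), 3L, 3L)
}

#' Camera extrinsic parameters
#'
#' Rigid transform between world and camera frames. The forward map is
#' X_camera = R X_world + t; its inverse, used when back-projecting depth
#' pixels into the world, is X_world = t(R) (X_camera - t). The default is
#' the identity transform: with no separate world frame the camera frame
#' *is* the world frame.
#'
#' @param R A 3x3 rotation matrix (orthonormal, determinant +1).
#' @param t A length-3 translation vector (metres).
#' @return An object of class `"camera_extrinsics"`.
#' @export
camera_extrinsics <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)) || anyNA(R)) {
    stop_wa("`R` must be a numeric 3x3 matrix",
            c("wa_invalid_extrinsics", "wa_input_error"))
  }
  if (length(t) != 3L || anyNA(t) || any(!is.finite(t))) {
    stop_wa("`t` must be a finite length-3 vector",
            c("wa_invalid_extrinsics", "wa_input_error"))
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop_wa("`R` is not a proper rotation (R'R = I, det R = 1 within 1e-9)",
            c("wa_invalid_extrinsics", "wa_input_error"))
  }
  structure(list(R = R, t = t), class = "camera_extrinsics")
}

#' @export
print.camera_extrinsics <- function(x, ...) {
  if (max(abs(x$R - diag(3))) == 0 && all(x$t == 0)) {
    cat("Camera extrinsics: identity (world frame = camera frame)\n")
  } else {
    cat("Camera extrinsics:\n  R =\n")
    print(round(x$R, 6))
    cat("  t =", format(x$t), "\n")
  }
  invisible(x)
}

is_identity_extrinsics <- function(e) {
  max(abs(e$R - diag(3))) == 0 && all(e$t == 0)
}

# --- coordinate transforms -------------------------------------------------

as_xyz_matrix <- function(p, name = "points") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.numeric(p) && is.null(dim(p)) && length(p) == 3L) {
    p <- matrix(p, 1L, 3L)
  }
  if (!is.matrix(p) || ncol(p) != 3L || !is.numeric(p)) {
    stop_wa(sprintf("`%s` must be an n x 3 numeric matrix", name),
            "wa_input_error")
  }
  storage.mode(p) <- "double"
  p
}

#' Back-project pixels into the camera frame
#'
#' Inverts the pinhole model with a known depth: given pixel coordinates
#' (u, v) and the z-depth of the surface seen there, recovers the 3D point
#' in the camera frame as x = (u - ox) z / fx, y = (v - oy) z / fy, z = z.
#' Back-projection is linear in depth: doubling z doubles x and y.
#'
#' @param uv An n x 2 matrix of pixel coordinates (u = column, v = row), or a
#'   length-2 vector for a single pixel.
#' @param depth_z Depth(s) in metres along the optical axis; length 1 or n.
#'   Must be positive and finite.
#' @param k A [camera_intrinsics()] object.
#' @return An n x 3 matrix of camera-frame points (metres), columns x, y, z.
#' @examples
#' k <- camera_intrinsics(500, 500, 320, 240)
#' backproject_pixel(c(420, 340), 2, k)  # (0.4, 0.4, 2.0)
#' @export
backproject_pixel <- function(uv, depth_z, k) {
  stopifnot(inherits(k, "camera_intrinsics"))
  if (is.numeric(uv) && is.null(dim(uv)) && length(uv) == 2L) {
    uv <- matrix(uv, 1L, 2L)
  }
  if (!is.matrix(uv) || ncol(uv) != 2L) {
    stop_wa("`uv` must be an n x 2 matrix of pixel coordinates",
            "wa_input_error")
  }
  depth_z <- as.numeric(depth_z)
  if (length(depth_z) == 1L) depth_z <- rep(depth_z, nrow(uv))
  if (length(depth_z) != nrow(uv)) {
    stop_wa("`depth_z` must have length 1 or nrow(uv)", "wa_input_error")
  }
  if (anyNA(depth_z) || any(!is.finite(depth_z)) || any(depth_z <= 0)) {
    stop_wa("depth values must be positive and finite",
            c("wa_invalid_depth", "wa_depth_error"))
  }
  cbind(x = (uv[, 1L] - k$ox) * depth_z / k$fx,
        y = (uv[, 2L] - k$oy) * depth_z / k$fy,
        z = depth_z)
}

#' Transform between camera and world frames
#'
#' `camera_to_world()` applies the inverse extrinsic transform
#' X_world = t(R) (X_camera - t); `world_to_camera()` applies the forward
#' transform X_camera = R X_world + t.
#'
#' @param p An n x 3 matrix of points (or a length-3 vector).
#' @param e A [camera_extrinsics()] object.
#' @return An n x 3 matrix of transformed points.
#' @export
camera_to_world <- function(p, e = camera_extrinsics()) {
  stopifnot(inherits(e, "camera_extrinsics"))
  p <- as_xyz_matrix(p)
  out <- sweep(p, 2L, e$t) %*% e$R  # (p - t) R == t(R'(p - t)')
  colnames(out) <- c("x", "y", "z")
  out
}

#' @rdname camera_to_world
#' @export
world_to_camera <- function(p, e = camera_extrinsics()) {
  stopifnot(inherits(e, "camera_extrinsics"))
  p <- as_xyz_matrix(p)
  out <- p %*% t(e$R) + matrix(e$t, nrow(p), 3L, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Project world points to pixel coordinates
#'
#' The forward pinhole map m = K [R|t] X_world followed by dehomogenization.
#' Used for rendering synthetic scenes and for round-trip testing of the
#' back-projection.
#'
#' @param w An n x 3 matrix of world points (metres).
#' @param k A [camera_intrinsics()] object.
#' @param e A [camera_extrinsics()] object.
#' @return An n x 2 matrix of pixel coordinates (u, v).
#' @export
world_to_pixel <- function(w, k, e = camera_extrinsics()) {
  stopifnot(inherits(k, "camera_intrinsics"))
  p <- world_to_camera(w, e)
  if (any(p[, 3L] <= 0)) {
    stop_wa("point at or behind the camera plane cannot be projected",
            c("wa_projection_error", "wa_geometry_error"))
  }
  cbind(u = k$fx * p[, 1L] / p[, 3L] + k$ox,
        v = k$fy * p[, 2L] / p[, 3L] + k$oy)
}

#' Convert ray-length depth to z-depth
#'
#' Some range sensors report the Euclidean distance along the viewing ray
#' rather than the z-coordinate. This package's depth convention is z-depth;
#' divide the ray length by the ray norm to convert.
#'
#' @param range_depth Ray length(s) in metres.
#' @param uv Pixel coordinates (n x 2) of each sample.
#' @param k A [camera_intrinsics()] object.
#' @return z-depth values of the same length.
#' @export
ray_length_to_z_depth <- function(range_depth, uv, k) {
  stopifnot(inherits(k, "camera_intrinsics"))
  if (is.numeric(uv) && is.null(dim(uv)) && length(uv) == 2L) {
    uv <- matrix(uv, 1L, 2L)
  }
  dx <- (uv[, 1L] - k$ox) / k$fx
  dy <- (uv[, 2L] - k$oy) / k$fy
  as.numeric(range_depth) / sqrt(dx^2 + dy^2 + 1)
}

# --- depth images ----------------------------------------------------------

#' Depth image container
#'
#' A per-pixel range map in metres with a validity mask. Matrix element
#' `[r, c]` corresponds to pixel (u, v) = (c - 1, r - 1).
#'
#' @param depth A numeric matrix of z-depths in metres.
#' @param valid Optional logical matrix of the same dimensions; defaults to
#'   finite, positive depth entries.
#' @return An object of class `"depth_image"` with elements `depth`, `valid`,
#'   `width`, `height`.
#' @export
depth_image <- function(depth, valid = NULL) {
  if (!is.matrix(depth) || !is.numeric(depth)) {
    stop_wa("`depth` must be a numeric matrix",
            c("wa_invalid_depth", "wa_depth_error"))
  }
  if (is.null(valid)) {
    valid <- is.finite(depth) & depth > 0
  }
  if (!is.logical(valid) || !identical(dim(valid), dim(depth))) {
    stop_wa("`valid` must be a logical matrix matching `depth`",
            c("wa_invalid_depth", "wa_depth_error"))
  }
  valid <- valid & is.finite(depth) & depth > 0
  structure(list(depth = depth, valid = valid,
                 width = ncol(depth), height = nrow(depth)),
            class = "depth_image")
}

#' @export
print.depth_image <- function(x, ...) {
  rng <- range(x$depth[x$valid])
  cat(sprintf("Depth image %d x %d px, %.1f%% valid, range %.4f-%.4f m\n",
              x$width, x$height, 100 * mean(x$valid), rng[1L], rng[2L]))
  invisible(x)
}

as_depth_image <- function(d) {
  if (inherits(d, "depth_image")) d else depth_image(d)
}

# Sample z-depth at (possibly non-integer) pixel locations: nearest pixel,
# falling back to the median of valid depths in the 3x3 neighbourhood, NA if
# neither yields a valid value.
sample_depth <- function(d, uv) {
  d <- as_depth_image(d)
  H <- d$height; W <- d$width
  r <- round(uv[, 2L]) + 1L
  c <- round(uv[, 1L]) + 1L
  z <- rep(NA_real_, nrow(uv))
  inb <- r >= 1L & r <= H & c >= 1L & c <= W
  idx <- (c[inb] - 1L) * H + r[inb]
  ok <- d$valid[idx]
  z[inb][ok] <- d$depth[idx][ok]
  for (i in which(is.na(z) & inb)) {
    rr <- max(1L, r[i] - 1L):min(H, r[i] + 1L)
    cc <- max(1L, c[i] - 1L):min(W, c[i] + 1L)
    nb <- d$depth[rr, cc][d$valid[rr, cc]]
    if (length(nb)) z[i] <- median(nb)
  }
  z
}

#' Back-project a 2D contour into world coordinates
#'
#' Samples the depth image at every contour vertex (nearest pixel, with a
#' 3x3-median fallback over valid neighbours), back-projects each vertex
#' through the pinhole model and transforms into the world frame. Vertex
#' order is preserved; vertices with no recoverable depth are dropped.
#'
#' @param contour An n x 2 matrix of ordered pixel coordinates (u, v),
#'   n >= 3.
#' @param depth A [depth_image()] (or plain depth matrix in metres) paired
#'   with the mask frame.
#' @param k A [camera_intrinsics()] object.
#' @param e A [camera_extrinsics()] object; identity by default.
#' @param max_drop_fraction Error if more than this fraction of vertices has
#'   no valid depth.
#' @return An m x 3 matrix of world points (metres) with attributes
#'   `n_dropped` (vertices lost to invalid depth) and `kept` (indices into
#'   the input contour).
#' @export
backproject_contour <- function(contour, depth, k, e = camera_extrinsics(),
                                max_drop_fraction = 0.5) {
  contour <- as_polygon_matrix(contour, name = "contour")
  z <- sample_depth(depth, contour)
  keep <- !is.na(z)
  n_drop <- sum(!keep)
  if (n_drop > max_drop_fraction * nrow(contour) || sum(keep) < 3L) {
    stop_wa(sprintf(
      "insufficient depth coverage: %d of %d contour vertices have no valid depth",
      n_drop, nrow(contour)),
      c("wa_insufficient_depth", "wa_depth_error"))
  }
  cam <- backproject_pixel(contour[keep, , drop = FALSE], z[keep], k)
  w <- camera_to_world(cam, e)
  attr(w, "n_dropped") <- n_drop
  attr(w, "kept") <- which(keep)
  w
}
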