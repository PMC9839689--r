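# Synthetic RGB-D scene generator: planar polygonal "wounds" of known area
# rendered into a depth image + mask, for validating the measurement
# pipeline with exact ground truth.

#' Specify a synthetic planar-wound scene
#'
#' A scene is a simple polygon drawn on a plane placed in the world, viewed
#' by a pinhole camera. The polygon is given in plane-local coordinates
#' (metres); its pose maps local (xi, eta, 0) to world coordinates via
#' `plane_rotation %*% c(xi, eta, 0) + plane_origin`.
#'
#' @param polygon An n x 2 matrix of plane-local vertices (metres); simple,
#'   with positive area.
#' @param plane_rotation A 3x3 rotation matrix; its first two columns are
#'   the in-plane axes, its third the plane normal.
#' @param plane_origin Length-3 world position of the plane-local origin
#'   (metres).
#' @param intrinsics A [camera_intrinsics()] object.
#' @param extrinsics A [camera_extrinsics()] object (identity by default).
#' @param image_size Image width/height in pixels (length 1 or 2,
#'   width then height).
#' @param depth_noise_sd Gaussian depth noise standard deviation (metres);
#'   0 for a noiseless scene.
#' @param depth_quantum Depth quantization step (metres); 0 disables.
#' @param seed Seed for the noise field; NULL leaves the RNG alone.
#' @return An object of class `"scene_spec"`.
#' @seealso [tilted_wound_scene()] for a convenient parametric front end,
#'   [render_scene()] to rasterize.
#' @export
scene_spec <- function(polygon, plane_rotation = diag(3),
                       plane_origin = c(0, 0, 0.5),
                       intrinsics = camera_intrinsics(1000, 1000,
                                                      255.5, 255.5),
                       extrinsics = camera_extrinsics(),
                       image_size = c(512L, 512L),
                       depth_noise_sd = 0, depth_quantum = 0, seed = NULL) {
  polygon <- as_polygon_matrix(polygon)
  if (shoelace_area(polygon) <= 0) {
    stop_wa("scene polygon must have positive area",
            c("wa_degenerate_polygon", "wa_geometry_error"))
  }
  Rp <- as.matrix(plane_rotation)
  if (!identical(dim(Rp), c(3L, 3L)) ||
      max(abs(crossprod(Rp) - diag(3))) > 1e-9 || abs(det(Rp) - 1) > 1e-9) {
    stop_wa("`plane_rotation` must be a proper 3x3 rotation matrix",
            "wa_input_error")
  }
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            inherits(extrinsics, "camera_extrinsics"))
  image_size <- as.integer(rep(image_size, length.out = 2L))
  if (any(image_size < 8L)) {
    stop_wa("`image_size` must be at least 8 pixels", "wa_input_error")
  }
  check_number(depth_noise_sd, "depth_noise_sd")
  check_number(depth_quantum, "depth_quantum")
  if (depth_noise_sd < 0 || depth_quantum < 0) {
    stop_wa("noise parameters must be non-negative", "wa_input_error")
  }
  structure(list(
    polygon = polygon, plane_rotation = Rp,
    plane_origin = as.numeric(plane_origin),
    intrinsics = intrinsics, extrinsics = extrinsics,
    image_size = image_size,
    depth_noise_sd = depth_noise_sd, depth_quantum = depth_quantum,
    seed = seed
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic scene: %d-gon of %.2f cm^2, image %d x %d px, noise sd %g m\n",
    nrow(x$polygon), shoelace_area(x$polygon) * 1e4,
    x$image_size[1L], x$image_size[2L], x$depth_noise_sd))
  invisible(x)
}

# Plane z = a x + b y + c (in the camera frame) from a normal and a point.
plane_from_normal_point <- function(n, p) {
  if (abs(n[3L]) < 1e-12) {
    stop_wa("plane contains the optical axis direction: not representable as z = a x + b y + c",
            c("wa_projection_error", "wa_geometry_error"))
  }
  c(a = -n[1L] / n[3L], b = -n[2L] / n[3L], c = sum(n * p) / n[3L])
}

#' z-depth of the pixel ray's intersection with a plane
#'
#' Casts the ray through the pixel centre and intersects it with the plane
#' z = a x + b y + c (camera frame). With ray direction
#' ((u - ox)/fx, (v - oy)/fy, 1), the intersection depth has the closed
#' form z = c / (1 - a (u - ox)/fx - b (v - oy)/fy).
#'
#' @param uv An n x 2 matrix of pixel coordinates (or a length-2 vector).
#' @param k A [camera_intrinsics()] object.
#' @param plane Coefficients (a, b, c) of the plane in the camera frame.
#' @return z-depths in metres; an error if any ray is parallel to the
#'   plane or intersects it behind the camera.
#' @export
ray_plane_depth <- function(uv, k, plane) {
  stopifnot(inherits(k, "camera_intrinsics"))
  if (is.numeric(uv) && is.null(dim(uv)) && length(uv) == 2L) {
    uv <- matrix(uv, 1L, 2L)
  }
  plane <- as.numeric(plane)
  dx <- (uv[, 1L] - k$ox) / k$fx
  dy <- (uv[, 2L] - k$oy) / k$fy
  den <- 1 - plane[1L] * dx - plane[2L] * dy
  z <- plane[3L] / den
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop_wa("ray parallel to the plane or intersection behind the camera",
            c("wa_projection_error", "wa_geometry_error"))
  }
  z
}

#' Add noise and quantization to a depth image
#'
#' Adds seeded Gaussian noise to every valid depth sample, then rounds to
#' the quantization grid. Validity flags are preserved.
#'
#' @param d A [depth_image()].
#' @param sd Noise standard deviation (metres); 0 for none.
#' @param quantum Grid step (metres); 0 for none.
#' @param seed Optional RNG seed; the caller's RNG state is restored.
#' @return A new [depth_image()].
#' @export
perturb_depth <- function(d, sd = 0, quantum = 0, seed = NULL) {
  d <- as_depth_image(d)
  check_number(sd, "sd")
  check_number(quantum, "quantum")
  dep <- d$depth
  with_seed(seed, {
    if (sd > 0) {
      dep[d$valid] <- dep[d$valid] + rnorm(sum(d$valid), 0, sd)
    }
  })
  if (quantum > 0) dep <- round(dep / quantum) * quantum
  depth_image(dep, d$valid)
}

#' Render a synthetic scene into a depth image and mask
#'
#' For every pixel, casts the ray through the pixel centre, intersects it
#' with the scene plane and records the z-depth; the mask pixel is set iff
#' the intersection point lies inside the wound polygon (even-odd rule in
#' plane-local coordinates). Depth noise and quantization are applied
#' afterwards, with the spec's seed. Pixels whose ray misses the plane's
#' front side are marked invalid.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `"synthetic_scene"`: a list with `depth`
#'   (a [depth_image()]), `mask` (logical matrix), `truth_area_cm2` (the
#'   exact polygon area), `truth_plane` (coefficients a, b, c of the plane
#'   in world coordinates plus `cos_theta`), and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  k <- spec$intrinsics
  W <- spec$image_size[1L]; H <- spec$image_size[2L]

  # plane in the camera frame
  Q <- spec$extrinsics$R %*% spec$plane_rotation
  o <- as.numeric(spec$extrinsics$R %*% spec$plane_origin + spec$extrinsics$t)
  n_cam <- Q[, 3L]
  if (o[3L] <= 0) {
    stop_wa("plane origin is behind the camera",
            c("wa_projection_error", "wa_geometry_error"))
  }
  pl <- plane_from_normal_point(n_cam, o)

  u <- rep(0:(W - 1L), each = H)
  v <- rep(0:(H - 1L), times = W)
  dx <- (u - k$ox) / k$fx
  dy <- (v - k$oy) / k$fy
  den <- 1 - pl[1L] * dx - pl[2L] * dy
  z <- pl[3L] / den
  ok <- is.finite(z) & z > 0
  if (!any(ok)) {
    stop_wa("plane is not visible from the camera",
            c("wa_projection_error", "wa_geometry_error"))
  }

  # plane-local coordinates of each intersection, for the polygon test
  px <- dx * z; py <- dy * z
  rel <- cbind(px - o[1L], py - o[2L], z - o[3L])
  xi <- rel %*% Q[, 1L]
  eta <- rel %*% Q[, 2L]
  inside <- ok & points_in_polygon(as.numeric(xi), as.numeric(eta),
                                   spec$polygon)

  dep <- matrix(NA_real_, H, W)
  dep[cbind(v + 1L, u + 1L)] <- ifelse(ok, z, NA_real_)
  mask <- matrix(FALSE, H, W)
  mask[cbind(v + 1L, u + 1L)] <- inside

  d <- depth_image(dep)
  if (spec$depth_noise_sd > 0 || spec$depth_quantum > 0) {
    d <- perturb_depth(d, spec$depth_noise_sd, spec$depth_quantum,
                       seed = spec$seed)
  }

  # ground-truth plane in world coordinates
  nw <- spec$plane_rotation[, 3L]
  pw <- plane_from_normal_point(nw, spec$plane_origin)
  structure(list(
    depth = d,
    mask = mask,
    truth_area_cm2 = shoelace_area(spec$polygon) * 1e4,
    truth_plane = c(pw, cos_theta = as.numeric(plane_cos_theta(pw))),
    spec = spec
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic scene: truth area %.2f cm^2, mask fill %.1f%%, %d x %d px\n",
    x$truth_area_cm2, 100 * mean(x$mask),
    ncol(x$mask), nrow(x$mask)))
  invisible(x)
}

# Rotation by `tilt` about the camera x-axis: in-plane axes
# e1 = (1,0,0), e2 = (0, cos t, sin t); normal (0, -sin t, cos t).
tilt_rotation <- function(tilt) {
  cbind(c(1, 0, 0),
        c(0, cos(tilt), sin(tilt)),
        c(0, -sin(tilt), cos(tilt)))
}

#' Parametric tilted-wound scene
#'
#' Builds a [scene_spec()] for a planar wound of a given true area, plane
#' tilt and frame-fill fraction. The wound polygon is constructed as the
#' exact preimage, on the tilted plane, of a centred square drawn in the
#' image whose pixel area equals the requested fill fraction; the viewing
#' distance then follows in closed form from the requested area (the
#' preimage scales linearly with distance, its area quadratically). This
#' realizes any combination of area, tilt below 90 degrees and fill
#' fraction below 1 without the wound ever clipping the frame -- at steep
#' tilts the on-plane polygon simply becomes an elongated quadrilateral,
#' as a steeply viewed wound would.
#'
#' @param area_cm2 Ground-truth wound area (cm^2).
#' @param tilt_deg Angle between the wound plane and the image plane
#'   (degrees, 0 <= tilt < 90; beyond about 65 degrees the default field
#'   of view starts to cut the plane's horizon and rendering fails).
#' @param fill_fraction Fraction of the frame the wound covers (0 to 0.8).
#' @param image_rotation_deg In-image rotation of the wound square
#'   (degrees, default 5). A square exactly aligned with the pixel grid
#'   rasterizes with a systematic pixel-count error of up to one pixel row
#'   per edge; a few degrees of rotation de-aligns the edges so the count
#'   error stays sub-pixel, which matters when validating sub-percent
#'   recovery.
#' @param intrinsics,image_size Camera model; defaults to a 512 x 512
#'   frame with 1000 px focal length (a moderate ~29 degree field of
#'   view, so that steep tilts keep the wound well away from the plane's
#'   horizon in the image).
#' @param depth_noise_sd,depth_quantum,seed Passed to [scene_spec()].
#' @return A [scene_spec()] whose rendered mask covers `fill_fraction` of
#'   the frame and whose `truth_area_cm2` is exactly `area_cm2`.
#' @examples
#' sc <- render_scene(tilted_wound_scene(20, 40, 0.3))
#' sc$truth_area_cm2
#' @export
tilted_wound_scene <- function(area_cm2, tilt_deg = 0, fill_fraction = 0.4,
                               image_rotation_deg = 5,
                               intrinsics = camera_intrinsics(1000, 1000,
                                                              255.5, 255.5),
                               image_size = c(512L, 512L),
                               depth_noise_sd = 0, depth_quantum = 0,
                               seed = NULL) {
  check_number(area_cm2, "area_cm2", positive = TRUE)
  check_number(tilt_deg, "tilt_deg")
  if (tilt_deg < 0 || tilt_deg >= 90) {
    stop_wa("`tilt_deg` must be in [0, 90)", "wa_input_error")
  }
  check_number(fill_fraction, "fill_fraction", positive = TRUE)
  check_number(image_rotation_deg, "image_rotation_deg")
  image_size <- as.integer(rep(image_size, length.out = 2L))
  W <- image_size[1L]; H <- image_size[2L]
  k <- intrinsics
  tilt <- tilt_deg * pi / 180
  Rp <- tilt_rotation(tilt)

  # centred, slightly rotated image square of the requested pixel area
  side <- sqrt(fill_fraction * W * H)
  rot <- image_rotation_deg * pi / 180
  if (side / 2 * (abs(cos(rot)) + abs(sin(rot))) > min(W, H) / 2 - 2) {
    stop_wa("`fill_fraction` too large: the wound square would clip the frame",
            "wa_input_error")
  }
  cu <- (W - 1) / 2; cv <- (H - 1) / 2
  corners <- cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)) * side / 2
  rotm <- cbind(c(cos(rot), sin(rot)), c(-sin(rot), cos(rot)))
  corners <- corners %*% t(rotm)
  img_poly <- cbind(u = cu + corners[, 1L], v = cv + corners[, 2L])

  # preimage of the image square on the tilted plane at unit distance
  pl1 <- plane_from_normal_point(Rp[, 3L], c(0, 0, 1))
  dx <- (img_poly[, 1L] - k$ox) / k$fx
  dy <- (img_poly[, 2L] - k$oy) / k$fy
  den <- 1 - pl1[1L] * dx - pl1[2L] * dy
  if (any(den <= 0.02)) {
    stop_wa("tilt too steep for this field of view: the frame cuts the plane horizon",
            c("wa_projection_error", "wa_geometry_error"))
  }
  z1 <- pl1[3L] / den
  cam1 <- cbind(dx * z1, dy * z1, z1)
  rel1 <- sweep(cam1, 2L, c(0, 0, 1))
  local1 <- cbind(rel1 %*% Rp[, 1L], rel1 %*% Rp[, 2L])
  s1 <- shoelace_area(local1)

  # preimage scales linearly with distance => area quadratically
  d <- sqrt((area_cm2 * 1e-4) / s1)
  scene_spec(polygon = local1 * d,
             plane_rotation = Rp,
             plane_origin = c(0, 0, d),
             intrinsics = k,
             image_size = image_size,
             depth_noise_sd = depth_noise_sd,
             depth_quantum = depth_quantum,
             seed = seed)
}
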