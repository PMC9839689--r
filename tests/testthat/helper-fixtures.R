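# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# A random proper rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# A random simple (star-shaped) polygon in the plane z = a x + b y + c.
# Sorted angles with positive radii guarantee simplicity.
random_planar_polygon <- function(n = 8L, a = 0, b = 0, c = 0,
                                  radius = 1) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.3, 1) * radius
  x <- r * cos(ang)
  y <- r * sin(ang)
  cbind(x = x, y = y, z = a * x + b * y + c)
}

# Brute-force confusion tally: the double loop the vectorized version must
# reproduce.
brute_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (r in seq_len(nrow(pred))) {
    for (c in seq_len(ncol(pred))) {
      if (pred[r, c] && truth[r, c]) tp <- tp + 1L
      else if (pred[r, c] && !truth[r, c]) fp <- fp + 1L
      else if (!pred[r, c] && truth[r, c]) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Normal-equations plane fit: literally the regression (A'A) x = A'B.
# Kept independent of fit_plane()'s QR path.
normal_equations_plane <- function(points) {
  A <- cbind(points[, 1L], points[, 2L], 1)
  B <- points[, 3L]
  drop(solve(crossprod(A), crossprod(A, B)))
}

# A filled disk mask.
disk_mask <- function(size, radius_frac = 0.3) {
  ctr <- (size - 1) / 2
  u <- matrix(rep(0:(size - 1L), each = size), size)
  v <- matrix(rep(0:(size - 1L), times = size), size)
  (u - ctr)^2 + (v - ctr)^2 <= (radius_frac * size)^2
}

# Minimal LabelMe JSON document written to a temp file.
write_labelme_fixture <- function(path, shapes) {
  doc <- list(
    version = "5.0.1",
    shapes = shapes,
    imageWidth = 64L,
    imageHeight = 48L
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

labelme_shape <- function(points, label = "wound",
                          shape_type = "polygon") {
  list(label = label,
       points = lapply(seq_len(nrow(points)),
                       function(i) as.list(points[i, ])),
       shape_type = shape_type)
}
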