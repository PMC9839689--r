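# Internal helpers: structured conditions, polygon primitives, small validators.
#
# Error taxonomy (all inherit "wa_error"; the CLI maps the group classes to
# exit codes):
#   wa_io_error         file missing / unreadable / unwritable
#   wa_parse_error      malformed file content (also wa_input_error)
#   wa_input_error      invalid argument values, dimension mismatches
#   wa_depth_error      invalid or insufficient depth data
#   wa_geometry_error   degenerate geometry (plane, polygon, projection)

stop_wa <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "wa_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

warn_wa <- function(message, class = character()) {
  warning(structure(
    class = c(class, "wa_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_wa(sprintf("`%s` must be a single finite number", name),
            "wa_input_error")
  }
  if (positive && x <= 0) {
    stop_wa(sprintf("`%s` must be positive (got %g)", name, x),
            "wa_input_error")
  }
  invisible(x)
}

# Coerce polygon-ish input (n x 2 matrix, data.frame, list of pairs) to a
# plain numeric matrix with n >= min_vertices rows.
as_polygon_matrix <- function(x, min_vertices = 3L, name = "polygon") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, lapply(x, as.numeric))
  if (!is.matrix(x) || ncol(x) != 2L || !is.numeric(x)) {
    stop_wa(sprintf("`%s` must be an n x 2 numeric matrix of vertices", name),
            "wa_input_error")
  }
  storage.mode(x) <- "double"
  # drop an explicitly repeated closing vertex
  n <- nrow(x)
  if (n >= 2L && all(x[1L, ] == x[n, ])) x <- x[-n, , drop = FALSE]
  if (nrow(x) < min_vertices || anyNA(x) || any(!is.finite(x))) {
    stop_wa(sprintf("`%s` must have at least %d finite vertices",
                    name, min_vertices),
            c("wa_degenerate_polygon", "wa_geometry_error"))
  }
  x
}

# Signed shoelace area of a closed 2D polygon (positive = counter-clockwise
# in a y-up frame; image frames are y-down, so the sign flips there --
# callers that care about magnitude use shoelace_area()).
signed_shoelace <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L]) / 2
}

#' Shoelace area of a 2D polygon
#'
#' Absolute polygon area as half the cyclic sum of 2x2 vertex determinants.
#' Vertex orientation (clockwise or counter-clockwise) does not matter.
#'
#' @param xy An n x 2 numeric matrix of ordered polygon vertices (the closing
#'   edge from the last vertex back to the first is implicit).
#' @return The enclosed area, in squared units of the vertex coordinates.
#' @examples
#' shoelace_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
shoelace_area <- function(xy) {
  xy <- as_polygon_matrix(xy, name = "xy")
  abs(signed_shoelace(xy))
}

# Even-odd (crossing-count) point-in-polygon test, vectorized over points.
# Points exactly on a horizontal edge follow the half-open convention; this
# is the classic PNPOLY formulation.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Does the closed polygon have any pair of non-adjacent edges that intersect?
# O(n^2); callers guard against large n.
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(FALSE)
  a <- xy
  b <- xy[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
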