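# Binary masks, contour extraction, and annotation handling.
#
# Masks are logical H x W matrices; element [r, c] is pixel
# (u, v) = (c - 1, r - 1). Contours are ordered n x 2 matrices of (u, v)
# pixel coordinates tracing the wound border, implicitly closed.

as_mask <- function(m, name = "mask") {
  if (is.matrix(m) && is.numeric(m)) m <- m > 0.5
  if (!is.matrix(m) || !is.logical(m)) {
    stop_wa(sprintf("`%s` must be a logical (or 0/1 numeric) matrix", name),
            "wa_input_error")
  }
  m
}

#' Fraction of the frame covered by the mask
#'
#' Wounds should fill a reasonable share of the frame for the measurement
#' to be reliable; the measurement pipeline attaches a quality-control
#' warning when the fill fraction is below 20% (a small, distant wound is
#' prone to segmentation failure and depth noise).
#'
#' @param mask A logical matrix (TRUE = wound pixel).
#' @return The true-pixel count divided by the total pixel count.
#' @export
frame_fill_fraction <- function(mask) {
  mask <- as_mask(mask)
  mean(mask)
}

# --- connected components --------------------------------------------------

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a small union-find over
# label ids.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1L, -1L])),  # down-right
    cbind(as.vector(lab[-H, -1L]), as.vector(lab[-1L, -W]))   # down-left
  )
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nlab)
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1L]; while (parent[a] != a) a <- parent[a]
      b <- pairs[i, 2L]; while (parent[b] != b) b <- parent[b]
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), function(i) {
    while (parent[i] != i) i <- parent[i]; i
  }, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# --- Moore-neighbour boundary tracing --------------------------------------

# Clockwise neighbour offsets starting from West, in (dr, dc).
.moore_dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
.moore_dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)

# Trace the outer boundary of the TRUE region containing the
# topmost-leftmost pixel, returning ordered (row, col) indices. Uses the
# Moore neighbourhood with Jacob's stopping criterion (stop when the start
# pixel is re-entered from the same backtrack direction).
moore_trace <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  start <- NULL
  for (r in seq_len(H)) {
    cs <- which(mask[r, ])
    if (length(cs)) { start <- c(r, cs[1L]); break }
  }
  r0 <- start[1L]; c0 <- start[2L]
  rs <- integer(0L); cs <- integer(0L)
  p_r <- r0; p_c <- c0
  bdir <- 1L  # entered from the West
  first_bdir <- NA_integer_
  maxit <- 4L * (H * W + 4L)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop_wa("boundary tracing failed to terminate",
                            "wa_geometry_error")
    found <- 0L
    for (s in 0:7) {
      k <- ((bdir - 1L + s) %% 8L) + 1L
      nr <- p_r + .moore_dr[k]; nc <- p_c + .moore_dc[k]
      if (nr >= 1L && nr <= H && nc >= 1L && nc <= W && mask[nr, nc]) {
        found <- k
        break
      }
    }
    if (found == 0L) {  # isolated pixel
      rs <- p_r; cs <- p_c
      break
    }
    # backtrack becomes the neighbour just before the found one (clockwise)
    prev_k <- ((found - 2L) %% 8L) + 1L
    b_r <- p_r + .moore_dr[prev_k]; b_c <- p_c + .moore_dc[prev_k]
    new_r <- p_r + .moore_dr[found]; new_c <- p_c + .moore_dc[found]
    # direction index of (b - new) seen from the new pixel
    dr <- b_r - new_r; dc <- b_c - new_c
    nbdir <- which(.moore_dr == dr & .moore_dc == dc)
    if (length(nbdir) == 0L) nbdir <- 1L  # b not adjacent: restart from West
    if (p_r == r0 && p_c == c0) {
      if (is.na(first_bdir)) {
        first_bdir <- found
      } else if (found == first_bdir && length(rs)) {
        break  # start re-entered with the same first move: closed
      }
    }
    rs <- c(rs, p_r); cs <- c(cs, p_c)
    p_r <- new_r; p_c <- new_c; bdir <- nbdir
  }
  cbind(rs, cs)
}

#' Extract the ordered boundary contour of a mask
#'
#' Selects the largest 8-connected component of the mask and traces its
#' outer boundary with Moore-neighbour tracing into an ordered, closed
#' polygon of pixel-centre coordinates. Interior holes are ignored: only
#' the outer margin is traced.
#'
#' @param mask A logical matrix (TRUE = wound pixel).
#' @param component `"largest"` (default) traces the largest component
#'   only; an integer selects the component with that label (components
#'   are labelled in raster order).
#' @return An n x 2 matrix of (u, v) pixel coordinates in traversal order,
#'   with attributes `n_pixels` (pixel count of the traced component) and
#'   `n_components` (number of 8-connected components in the mask).
#' @export
extract_contour <- function(mask, component = "largest") {
  mask <- as_mask(mask)
  if (!any(mask)) {
    stop_wa("mask is empty: no wound pixels to trace",
            c("wa_empty_mask", "wa_input_error"))
  }
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  sel <- if (identical(component, "largest")) which.max(sizes)
         else as.integer(component)
  if (is.na(sel) || sel < 1L || sel > length(sizes)) {
    stop_wa("no such component", "wa_input_error")
  }
  comp <- lab == sel
  rc <- moore_trace(comp)
  if (nrow(rc) < 3L) {
    stop_wa(sprintf(
      "component of %d pixel(s) is too small to form a boundary polygon",
      sizes[sel]),
      c("wa_degenerate_polygon", "wa_geometry_error"))
  }
  out <- cbind(u = rc[, 2L] - 1, v = rc[, 1L] - 1)
  attr(out, "n_pixels") <- sizes[sel]
  attr(out, "n_components") <- length(sizes)
  out
}

#' Rasterize a polygon into a binary mask
#'
#' A pixel is set if and only if its centre lies inside the polygon under
#' the even-odd rule, so vertex orientation and self-overlap follow the
#' standard crossing-count semantics.
#'
#' @param polygon An n x 2 matrix of (u, v) vertices in pixel coordinates.
#' @param width,height Output mask dimensions in pixels.
#' @return A `height` x `width` logical matrix.
#' @export
polygon_to_mask <- function(polygon, width, height) {
  polygon <- as_polygon_matrix(polygon)
  if (shoelace_area(polygon) == 0) {
    stop_wa("degenerate polygon: zero area",
            c("wa_degenerate_polygon", "wa_geometry_error"))
  }
  check_number(width, "width", positive = TRUE)
  check_number(height, "height", positive = TRUE)
  u <- rep(0:(width - 1L), each = height)
  v <- rep(0:(height - 1L), times = width)
  matrix(points_in_polygon(u, v, polygon), nrow = height, ncol = width)
}

# --- resizing --------------------------------------------------------------

#' Resize images, masks and depth maps
#'
#' Photographs are resized with bilinear interpolation; masks and depth
#' maps use nearest-neighbour so that no fractional labels or invented
#' depths appear at boundaries. The clinical pipeline standardized all
#' inputs to 512 x 512 pixels, which is the default here. Non-square
#' inputs are distorted to the target aspect; the returned object carries
#' an `aspect_distorted` attribute so pipelines can flag it.
#'
#' @param x A numeric matrix (image or depth, possibly with a third channel
#'   dimension for `resize_image`), or a logical matrix for `resize_mask`,
#'   or a [depth_image()] for `resize_depth`.
#' @param width,height Target size in pixels (default 512 x 512).
#' @return The resized object, same type as the input.
#' @export
resize_image <- function(x, width = 512L, height = 512L) {
  out <- EBImage::resize(x, w = height, h = width, filter = "bilinear")
  attr(out, "aspect_distorted") <- !isTRUE(all.equal(
    nrow(x) / ncol(x), height / width))
  out
}

#' @rdname resize_image
#' @export
resize_mask <- function(x, width = 512L, height = 512L) {
  x <- as_mask(x)
  out <- EBImage::resize(x * 1, w = height, h = width, filter = "none") > 0.5
  attr(out, "aspect_distorted") <- !isTRUE(all.equal(
    nrow(x) / ncol(x), height / width))
  out
}

#' @rdname resize_image
#' @export
resize_depth <- function(x, width = 512L, height = 512L) {
  d <- as_depth_image(x)
  dep <- EBImage::resize(d$depth, w = height, h = width, filter = "none")
  val <- EBImage::resize(d$valid * 1, w = height, h = width,
                         filter = "none") > 0.5
  depth_image(dep, val)
}

# --- LabelMe annotations ---------------------------------------------------

#' Read a LabelMe polygon annotation file
#'
#' Parses the JSON format written by the LabelMe annotation tool: a list of
#' `shapes`, each with a `label`, a `points` list of (x, y) pairs and a
#' `shape_type`. Only polygon shapes are kept (in drawing order);
#' non-polygon shapes are skipped with a warning.
#'
#' @param path Path to a LabelMe `.json` file.
#' @return An object of class `"labelme_annotations"`: a list with
#'   `shapes` (each a list with `label` and `points`, an n x 2 matrix),
#'   `width`, `height`, and `n_skipped`.
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) {
    stop_wa(sprintf("file not found: %s", path), "wa_io_error")
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_wa(sprintf("malformed JSON in %s: %s",
                                    path, conditionMessage(e)),
                            c("wa_parse_error", "wa_input_error"))
                  })
  if (is.null(doc$shapes) || !length(doc$shapes)) {
    stop_wa(sprintf("no shapes in LabelMe file %s", path),
            c("wa_parse_error", "wa_input_error"))
  }
  shapes <- list()
  skipped <- 0L
  for (sh in doc$shapes) {
    type <- if (is.null(sh$shape_type)) "polygon" else sh$shape_type
    if (!identical(type, "polygon")) {
      skipped <- skipped + 1L
      next
    }
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(p[1:2])))
    pts <- as_polygon_matrix(pts, name = "LabelMe polygon")
    shapes[[length(shapes) + 1L]] <- list(
      label = if (is.null(sh$label)) "" else as.character(sh$label),
      points = pts
    )
  }
  if (skipped > 0L) {
    warn_wa(sprintf("skipped %d non-polygon shape(s) in %s", skipped, path))
  }
  if (!length(shapes)) {
    stop_wa(sprintf("no polygon shapes in LabelMe file %s", path),
            c("wa_parse_error", "wa_input_error"))
  }
  structure(list(
    shapes = shapes,
    width = if (is.null(doc$imageWidth)) NA_integer_
            else as.integer(doc$imageWidth),
    height = if (is.null(doc$imageHeight)) NA_integer_
             else as.integer(doc$imageHeight),
    n_skipped = skipped
  ), class = "labelme_annotations")
}

#' @export
print.labelme_annotations <- function(x, ...) {
  cat(sprintf("LabelMe annotations: %d polygon(s), image %s x %s px\n",
              length(x$shapes), x$width, x$height))
  for (sh in x$shapes) {
    cat(sprintf("  '%s': %d vertices\n", sh$label, nrow(sh$points)))
  }
  invisible(x)
}
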