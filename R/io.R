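# File I/O: camera configs (JSON), binary masks (PNG), depth maps
# (16-bit grayscale PNG or plain-text matrix), measurement reports
# (JSON + CSV log), contour CSV export.

# --- camera configuration --------------------------------------------------

#' Read and write camera configuration files
#'
#' The camera configuration is a JSON object with required keys `fx`,
#' `fy`, `ox`, `oy`, and optional `R` (3x3 rotation, row-major flat or
#' nested), `t` (length-3 translation, metres), `depth_scale` (metres per
#' stored depth unit, default 1e-3) and `depth_invalid` (stored value
#' meaning "no return", default 0). Validation is strict: a malformed or
#' non-orthonormal rotation is an error.
#'
#' @param path Path to the JSON file.
#' @return `read_camera_config()` returns a list with elements
#'   `intrinsics` ([camera_intrinsics()]), `extrinsics`
#'   ([camera_extrinsics()]), `depth_scale` and `depth_invalid`.
#' @export
read_camera_config <- function(path) {
  if (!file.exists(path)) {
    stop_wa(sprintf("camera config not found: %s", path), "wa_io_error")
  }
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_wa(sprintf("malformed camera config %s: %s", path,
                                    conditionMessage(e)),
                            c("wa_parse_error", "wa_input_error"))
                  })
  for (key in c("fx", "fy", "ox", "oy")) {
    if (is.null(doc[[key]]) || !is_scalar_number(doc[[key]])) {
      stop_wa(sprintf("camera config %s: missing or non-numeric `%s`",
                      path, key),
              c("wa_parse_error", "wa_input_error"))
    }
  }
  k <- camera_intrinsics(doc$fx, doc$fy, doc$ox, doc$oy)
  e <- if (!is.null(doc$R) || !is.null(doc$t)) {
    R <- if (is.null(doc$R)) diag(3) else {
      r <- doc$R
      if (is.list(r)) r <- do.call(rbind, r)
      if (is.null(dim(r))) r <- matrix(as.numeric(r), 3L, 3L, byrow = TRUE)
      as.matrix(r)
    }
    camera_extrinsics(R, if (is.null(doc$t)) c(0, 0, 0) else doc$t)
  } else {
    camera_extrinsics()
  }
  list(intrinsics = k, extrinsics = e,
       depth_scale = doc$depth_scale %||% 1e-3,
       depth_invalid = doc$depth_invalid %||% 0)
}

#' @rdname read_camera_config
#' @param k A [camera_intrinsics()] object.
#' @param e A [camera_extrinsics()] object.
#' @param depth_scale,depth_invalid Depth encoding declaration stored with
#'   the camera parameters.
#' @export
write_camera_config <- function(path, k, e = camera_extrinsics(),
                                depth_scale = 1e-3, depth_invalid = 0) {
  stopifnot(inherits(k, "camera_intrinsics"))
  stopifnot(inherits(e, "camera_extrinsics"))
  doc <- list(fx = k$fx, fy = k$fy, ox = k$ox, oy = k$oy,
              depth_scale = depth_scale, depth_invalid = depth_invalid)
  if (!is_identity_extrinsics(e)) {
    doc$R <- as.numeric(t(e$R))  # row-major
    doc$t <- e$t
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rescale intrinsics when the paired image is resized from one frame size
# to another (pixel centres at integers, so offsets shift by half a pixel).
scale_intrinsics <- function(k, from, to) {
  sx <- to[1L] / from[1L]
  sy <- to[2L] / from[2L]
  camera_intrinsics(fx = k$fx * sx, fy = k$fy * sy,
                    ox = (k$ox + 0.5) * sx - 0.5,
                    oy = (k$oy + 0.5) * sy - 0.5)
}

# --- masks -----------------------------------------------------------------

#' Read and write binary masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with 0 = background and
#' 255 = wound; on reading, any channel value above 0.5 counts as wound.
#'
#' @param path PNG file path.
#' @param mask A logical matrix.
#' @return `read_mask()` returns a logical matrix; `write_mask()` returns
#'   the path invisibly.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop_wa(sprintf("mask not found: %s", path), "wa_io_error")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

# --- depth maps ------------------------------------------------------------

#' Read and write depth maps
#'
#' Two on-disk formats are supported. `.png` is 16-bit grayscale with a
#' declared scale (default: millimetres per unit, so stored value 500 is
#' 0.5 m); the stored `invalid` value (default 0) marks pixels with no
#' depth return. Any other extension is a plain-text numeric matrix of
#' z-depths in metres (tab-separated, `NA` for invalid pixels).
#'
#' @param path File path; the extension selects the format.
#' @param scale Metres per stored unit for PNG depth (ignored for text).
#' @param invalid Stored value treated as invalid for PNG depth.
#' @return `read_depth()` returns a [depth_image()].
#' @export
read_depth <- function(path, scale = 1e-3, invalid = 0) {
  if (!file.exists(path)) {
    stop_wa(sprintf("depth file not found: %s", path), "wa_io_error")
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    raw_units <- round(img * 65535)
    valid <- raw_units != invalid
    depth_image(raw_units * scale, valid)
  } else {
    m <- tryCatch(
      as.matrix(utils::read.table(path, header = FALSE)),
      error = function(e) {
        stop_wa(sprintf("cannot parse depth matrix %s: %s", path,
                        conditionMessage(e)),
                c("wa_parse_error", "wa_input_error"))
      })
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    depth_image(m, is.finite(m) & m > 0)
  }
}

#' @rdname read_depth
#' @param d A [depth_image()] (or a plain numeric matrix in metres).
#' @export
write_depth <- function(d, path, scale = 1e-3, invalid = 0) {
  d <- as_depth_image(d)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    units <- round(d$depth / scale)
    units[!d$valid | !is.finite(units)] <- invalid
    if (any(units < 0 | units > 65535, na.rm = TRUE)) {
      stop_wa("depth out of range for 16-bit encoding at this scale",
              "wa_input_error")
    }
    write_png16(matrix(as.integer(units), nrow(d$depth), ncol(d$depth)),
                path)
  } else {
    m <- d$depth
    m[!d$valid] <- NA_real_
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE,
                       sep = "\t")
  }
  invisible(path)
}

# --- minimal 16-bit grayscale PNG encoder ----------------------------------
# png::writePNG quantizes to 8 bits, which is too coarse for depth (256
# levels over the working range). PNG is simple enough to emit directly:
# zlib-wrapped deflate (re-using memCompress's gzip deflate stream) plus
# CRC32/Adler32 checksums.

.crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- numeric(256L)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (c %% 2 == 1) bitxor32(floor(c / 2), 3988292384) # 0xEDB88320
             else floor(c / 2)
      }
      t[n + 1L] <- c
    }
    tab <<- t
    tab
  }
})

# 32-bit XOR on doubles (R integers are signed 32-bit; 0xEDB88320 overflows)
bitxor32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(ah, bh) * 65536 + bitwXor(al, bl)
}

crc32 <- function(bytes) {
  tab <- .crc32_table()
  c <- 4294967295 # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (i in seq_along(v)) {
    c <- bitxor32(tab[bitwXor(c %% 256, v[i]) + 1L], floor(c / 256))
  }
  bitxor32(c, 4294967295)
}

u32be <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256,
           x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

# memCompress(type = "gzip") emits an RFC 1950 zlib stream (0x78 header +
# Adler32 trailer), which is exactly what PNG's IDAT requires.
zlib_compress <- function(bytes) {
  memCompress(bytes, type = "gzip")
}

# `units`: integer matrix (rows x cols) of 16-bit values in [0, 65535].
write_png16 <- function(units, path) {
  H <- nrow(units); W <- ncol(units)
  hi <- as.raw(t(units) %/% 256L)
  lo <- as.raw(t(units) %% 256L)
  rows <- raw((2L * W + 1L) * H)
  pix <- raw(2L * W * H)
  pix[seq(1L, length(pix), by = 2L)] <- hi
  pix[seq(2L, length(pix), by = 2L)] <- lo
  dim(pix) <- NULL
  for (r in seq_len(H)) {
    off <- (r - 1L) * (2L * W + 1L)
    rows[off + 1L] <- as.raw(0L)  # filter type: none
    rows[off + 1L + seq_len(2L * W)] <-
      pix[(r - 1L) * 2L * W + seq_len(2L * W)]
  }
  ihdr <- c(u32be(W), u32be(H),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # 16-bit grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(rows)),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# --- reports ---------------------------------------------------------------

#' Write a measurement report
#'
#' Serializes a [measure_wound_area()] result as a JSON report and,
#' optionally, appends one row to a CSV measurement log (created with a
#' header if absent). The log row records the timestamp, the input file
#' names and their content hashes when supplied, the area, the plane
#' coefficients and the QC flags, so a measurement session is
#' reconstructible from the log alone.
#'
#' @param m A `"wound_measurement"` object.
#' @param json_path Output JSON path, or NULL to skip.
#' @param log_csv CSV log to append to, or NULL to skip.
#' @param inputs Optional named character vector of input file paths
#'   recorded (with md5 hashes) in the log.
#' @return The report list, invisibly.
#' @export
write_measurement_report <- function(m, json_path = NULL, log_csv = NULL,
                                     inputs = NULL) {
  stopifnot(inherits(m, "wound_measurement"))
  rep <- measurement_report(m)
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(log_csv)) {
    hashes <- if (is.null(inputs)) "" else {
      paste(sprintf("%s=%s", names(inputs), vapply(inputs, function(f) {
        if (file.exists(f)) unname(tools::md5sum(f)) else "missing"
      }, character(1L))), collapse = ";")
    }
    row <- data.frame(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      inputs = hashes,
      area_cm2 = m$area_cm2,
      a = m$plane$coefficients[["a"]],
      b = m$plane$coefficients[["b"]],
      c = m$plane$coefficients[["c"]],
      cos_theta = m$cos_theta,
      n_vertices = m$n_vertices_used,
      frame_fill = m$frame_fill,
      qc_flags = paste(m$qc_flags, collapse = ";")
    )
    write.table(row, log_csv, sep = ",", row.names = FALSE,
                col.names = !file.exists(log_csv), append = file.exists(log_csv),
                qmethod = "double")
  }
  invisible(rep)
}

#' Export a contour as CSV
#'
#' @param contour An n x 2 matrix of (u, v) pixel coordinates.
#' @param path Output CSV path.
#' @export
write_contour_csv <- function(contour, path) {
  contour <- as_polygon_matrix(contour, name = "contour")
  df <- data.frame(u = contour[, 1L], v = contour[, 2L])
  write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}
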