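# File-level entry points: one function per command of the bundled CLI
# (measure, evaluate-seg, evaluate-area, simulate). Each takes file paths,
# runs the in-memory functions, and writes machine-readable outputs.

#' Measure a wound from files
#'
#' Reads a segmentation mask (PNG) or a LabelMe polygon annotation, a
#' depth map (16-bit PNG or plain-text matrix) and a camera configuration,
#' optionally resizes everything to a common frame (rescaling the
#' intrinsics accordingly), and runs [measure_wound_area()]. The result
#' can be written as a JSON report and appended to a CSV measurement log.
#'
#' @param mask Path to a binary mask PNG (exclusive with `labelme`).
#' @param labelme Path to a LabelMe JSON annotation; the first polygon (or
#'   the one whose label equals `label`) is used.
#' @param label Optional label selecting a LabelMe polygon.
#' @param depth Path to the depth file.
#' @param camera Path to the camera configuration JSON.
#' @param config A [measurement_config()]; its `depth_scale` and
#'   `invalid_value` are overridden by the camera file when that declares
#'   them.
#' @param out_json,log_csv Optional output paths.
#' @return The `"wound_measurement"` object, invisibly.
#' @export
measure_wound_file <- function(mask = NULL, labelme = NULL, label = NULL,
                               depth, camera,
                               config = measurement_config(),
                               out_json = NULL, log_csv = NULL) {
  if (is.null(mask) == is.null(labelme)) {
    stop_wa("supply exactly one of `mask` or `labelme`", "wa_input_error")
  }
  cam <- read_camera_config(camera)
  d <- read_depth(depth, scale = cam$depth_scale, invalid = cam$depth_invalid)
  k <- cam$intrinsics

  if (!is.null(mask)) {
    m <- read_mask(mask)
    if (!is.null(config$resize_to)) {
      sz <- config$resize_to
      k <- scale_intrinsics(k, from = c(ncol(m), nrow(m)), to = c(sz, sz))
      distorted <- nrow(m) != ncol(m)
      m <- resize_mask(m, sz, sz)
      d <- resize_depth(d, sz, sz)
      attr(m, "aspect_distorted") <- distorted
    }
    input <- m
  } else {
    ann <- read_labelme(labelme)
    sh <- if (is.null(label)) ann$shapes[[1L]] else {
      hit <- Filter(function(s) identical(s$label, label), ann$shapes)
      if (!length(hit)) {
        stop_wa(sprintf("no polygon labelled '%s' in %s", label, labelme),
                "wa_input_error")
      }
      hit[[1L]]
    }
    input <- sh$points
    if (!is.null(config$resize_to)) {
      sz <- config$resize_to
      from <- c(ann$width, ann$height)
      if (anyNA(from)) {
        stop_wa("LabelMe file lacks imageWidth/imageHeight; cannot resize",
                c("wa_parse_error", "wa_input_error"))
      }
      k <- scale_intrinsics(k, from = from, to = c(sz, sz))
      input <- cbind((input[, 1L] + 0.5) * sz / from[1L] - 0.5,
                     (input[, 2L] + 0.5) * sz / from[2L] - 0.5)
      d <- resize_depth(d, sz, sz)
    }
  }

  m <- measure_wound_area(input, d, k, cam$extrinsics, config)
  inputs <- c(mask = mask, labelme = labelme, depth = depth, camera = camera)
  write_measurement_report(m, json_path = out_json, log_csv = log_csv,
                           inputs = inputs[!vapply(inputs, is.null,
                                                   logical(1L))])
  invisible(m)
}

# Pair two mask paths or two directories of masks by file name.
pair_mask_files <- function(pred, truth) {
  if (dir.exists(pred) && dir.exists(truth)) {
    pf <- sort(list.files(pred, pattern = "\\.png$", ignore.case = TRUE))
    tf <- sort(list.files(truth, pattern = "\\.png$", ignore.case = TRUE))
    if (!length(pf)) {
      stop_wa(sprintf("no PNG masks in %s", pred), "wa_input_error")
    }
    missing_t <- setdiff(pf, tf)
    missing_p <- setdiff(tf, pf)
    if (length(missing_t) || length(missing_p)) {
      stop_wa(sprintf(
        "unpaired masks: %s",
        paste(c(sprintf("%s (prediction only)", missing_t),
                sprintf("%s (truth only)", missing_p)), collapse = ", ")),
        "wa_input_error")
    }
    list(pred = file.path(pred, pf), truth = file.path(truth, pf),
         names = pf)
  } else if (file.exists(pred) && file.exists(truth)) {
    list(pred = pred, truth = truth, names = basename(pred))
  } else {
    stop_wa("prediction/truth inputs must both be files or both directories",
            "wa_io_error")
  }
}

#' Evaluate segmentation masks from files
#'
#' Takes a predicted and a ground-truth mask (or two directories of
#' paired masks, matched by file name) and computes the five pixel
#' metrics per image plus their aggregate.
#'
#' @param pred,truth Mask PNG paths or directories.
#' @param average Aggregation mode, `"macro"` or `"micro"`; see
#'   [batch_seg_metrics()].
#' @param out_csv Optional path for the per-image metric table.
#' @param out_json Optional path for the aggregate report.
#' @return The [batch_seg_metrics()] result, invisibly.
#' @export
evaluate_seg_files <- function(pred, truth, average = c("macro", "micro"),
                               out_csv = NULL, out_json = NULL) {
  average <- match.arg(average)
  paired <- pair_mask_files(pred, truth)
  preds <- lapply(paired$pred, read_mask)
  truths <- lapply(paired$truth, read_mask)
  names(preds) <- paired$names
  res <- batch_seg_metrics(preds, truths, average = average)
  if (!is.null(out_csv)) {
    tab <- cbind(image = rownames(res$per_image), res$per_image)
    write.table(tab, out_csv, sep = ",", row.names = FALSE,
                qmethod = "double")
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(average = average, mean = as.list(unclass(res$mean)),
           n_images = nrow(res$per_image)),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Evaluate area measurements from a CSV table
#'
#' Reads a CSV with columns `wound_id`, `manual_area_cm2`,
#' `auto_area_cm2` and optionally `re_percent` and `outlier`, and
#' computes the mean relative error and SD, with and without exclusions.
#' Alternatively, `clinical` selects a model column of the bundled
#' clinical reference table instead of reading a file.
#'
#' @param csv Path to the measurement CSV (ignored when `clinical` is
#'   given).
#' @param clinical `"unet"` or `"maskrcnn"` to evaluate the bundled
#'   clinical table.
#' @param exclude Wound ids to exclude (e.g. flagged outliers); the
#'   string `"outliers"` excludes the records whose `outlier` column is
#'   TRUE.
#' @param use_printed_re Prefer a pre-computed `re_percent` column over
#'   re-deriving errors from the areas.
#' @param out_json Optional output path for the summary.
#' @return The `"area_evaluation"` object, invisibly.
#' @export
evaluate_area_file <- function(csv = NULL, clinical = NULL, exclude = NULL,
                               use_printed_re = TRUE, out_json = NULL) {
  records <- if (!is.null(clinical)) {
    area_records(clinical)
  } else {
    if (is.null(csv) || !file.exists(csv)) {
      stop_wa(sprintf("measurement CSV not found: %s", csv %||% "<none>"),
              "wa_io_error")
    }
    df <- tryCatch(read.csv(csv), error = function(e) {
      stop_wa(sprintf("cannot parse %s: %s", csv, conditionMessage(e)),
              c("wa_parse_error", "wa_input_error"))
    })
    bad <- which(!stats::complete.cases(
      df[, intersect(c("wound_id", "manual_area_cm2", "manual_area"),
                     names(df)), drop = FALSE]))
    if (length(bad)) {
      stop_wa(sprintf("malformed rows in %s: %s", csv,
                      paste(bad, collapse = ", ")),
              c("wa_parse_error", "wa_input_error"))
    }
    df
  }
  if (identical(exclude, "outliers")) {
    if (is.null(records$outlier)) {
      stop_wa("no `outlier` column to exclude by", "wa_input_error")
    }
    exclude <- records$wound_id[as.logical(records$outlier)]
  }
  res <- evaluate_area_measurements(records, exclude = exclude,
                                    use_printed_re = use_printed_re)
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(mre_percent = res$mre_percent, sd_re = res$sd_re,
           n_used = res$n_used, excluded_ids = res$excluded_ids),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Render a synthetic scene to files
#'
#' Generates a [tilted_wound_scene()], renders it, and writes the depth
#' map (16-bit millimetre PNG), the mask (PNG), the camera configuration
#' (JSON) and a ground-truth JSON (area, plane, pose parameters) into a
#' directory.
#'
#' @param out_dir Output directory (created if needed).
#' @inheritParams tilted_wound_scene
#' @return A named list of the written file paths, invisibly.
#' @export
simulate_scene_files <- function(out_dir, area_cm2 = 20, tilt_deg = 30,
                                 fill_fraction = 0.4,
                                 depth_noise_sd = 0, depth_quantum = 0,
                                 seed = NULL) {
  spec <- tilted_wound_scene(area_cm2, tilt_deg, fill_fraction,
                             depth_noise_sd = depth_noise_sd,
                             depth_quantum = depth_quantum, seed = seed)
  scene <- render_scene(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(depth = file.path(out_dir, "depth.png"),
                mask = file.path(out_dir, "mask.png"),
                camera = file.path(out_dir, "camera.json"),
                truth = file.path(out_dir, "truth.json"))
  write_depth(scene$depth, paths$depth, scale = 1e-3)
  write_mask(scene$mask, paths$mask)
  write_camera_config(paths$camera, spec$intrinsics, spec$extrinsics,
                      depth_scale = 1e-3, depth_invalid = 0)
  jsonlite::write_json(
    list(truth_area_cm2 = scene$truth_area_cm2,
         truth_plane = as.list(scene$truth_plane),
         area_cm2 = area_cm2, tilt_deg = tilt_deg,
         fill_fraction = fill_fraction,
         depth_noise_sd = depth_noise_sd, depth_quantum = depth_quantum,
         seed = seed),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
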