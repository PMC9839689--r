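# End-to-end measurement: mask/polygon input, QC flags, error paths,
# file-level pipeline.

test_that("a fronto-parallel 4 x 5 cm rectangle measures 20 cm^2", {
  # rectangle rotated in-plane so its edges are not pixel-grid aligned
  rect <- cbind(c(-0.02, 0.02, 0.02, -0.02), c(-0.025, -0.025, 0.025, 0.025))
  th <- 9 * pi / 180
  rect <- rect %*% cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  spec <- scene_spec(rect, plane_origin = c(0, 0, 0.25),
                     intrinsics = camera_intrinsics(1000, 1000, 255.5, 255.5))
  sc <- render_scene(spec)
  m <- measure_wound_area(sc$mask, sc$depth, spec$intrinsics)
  expect_lt(abs(m$area_cm2 - 20) / 20, 0.01)
  expect_equal(m$cos_theta, 1, tolerance = 1e-9)
})

test_that("a 40-degree tilted wound measures within 1 percent", {
  spec <- tilted_wound_scene(20, 40, 0.4)
  sc <- render_scene(spec)
  m <- measure_wound_area(sc$mask, sc$depth, spec$intrinsics)
  expect_lt(abs(m$area_cm2 - 20) / 20, 0.01)
  expect_equal(acos(m$cos_theta) * 180 / pi, 40, tolerance = 0.2)
})

test_that("polygon input bypasses rasterization and accepts LabelMe vertices", {
  spec <- tilted_wound_scene(12, 20, 0.3)
  sc <- render_scene(spec)
  ct <- extract_contour(sc$mask)
  m <- measure_wound_area(ct, sc$depth, spec$intrinsics,
                          config = measurement_config(
                            boundary_correction = FALSE))
  # without the pixel-count correction the contour under-measures slightly
  expect_lt(abs(m$area_cm2 - 12) / 12, 0.02)
  expect_equal(m$boundary_correction, 1)
})

test_that("QC flags fire for low fill, drops, extra components, bowties", {
  spec <- tilted_wound_scene(5, 10, 0.1)  # deliberately small in frame
  sc <- render_scene(spec)
  mask2 <- sc$mask
  mask2[2:3, 2:3] <- TRUE  # a speck far from the wound
  d2 <- sc$depth
  # punch a hole through part of the border to force vertex drops
  ct <- extract_contour(sc$mask)
  hole <- ct[1:4, ] + 1
  d2$valid[cbind(hole[, 2L], hole[, 1L])] <- FALSE
  dd <- d2$depth; dd[!d2$valid] <- NA
  # enlarge the hole so the 3x3 fallback cannot rescue every vertex
  rr <- range(hole[, 2L]); cc <- range(hole[, 1L])
  dd[max(1, rr[1] - 2):(rr[2] + 2), max(1, cc[1] - 2):(cc[2] + 2)] <- NA
  m <- measure_wound_area(mask2, depth_image(dd), spec$intrinsics)
  expect_true("low_frame_fill" %in% m$qc_flags)
  expect_true("multiple_components" %in% m$qc_flags)
  expect_true("dropped_vertices" %in% m$qc_flags)
  expect_gt(m$n_vertices_dropped, 0L)

  # self-intersecting polygon input
  bow <- rbind(c(100, 100), c(200, 200), c(200, 100), c(100, 200))
  mb <- measure_wound_area(bow, sc$depth, spec$intrinsics)
  expect_true("self_intersecting_contour" %in% mb$qc_flags)
})

test_that("degenerate inputs raise stage-specific errors", {
  spec <- tilted_wound_scene(10, 0, 0.3)
  sc <- render_scene(spec)
  empty <- matrix(FALSE, nrow(sc$mask), ncol(sc$mask))
  expect_error(measure_wound_area(empty, sc$depth, spec$intrinsics),
               class = "wa_empty_mask")
  small <- matrix(FALSE, 64L, 64L)
  expect_error(measure_wound_area(small, sc$depth, spec$intrinsics),
               class = "wa_input_error")

  # a plane steeper than the guard: depth drawn from z = 12 x + 0.5
  k <- camera_intrinsics(1000, 1000, 31.5, 31.5)
  uv <- expand.grid(u = 0:63, v = 0:63)
  z <- ray_plane_depth(as.matrix(uv), k, c(12, 0, 0.5))
  dd <- matrix(NA_real_, 64L, 64L)
  dd[cbind(uv$v + 1L, uv$u + 1L)] <- z
  mask <- matrix(FALSE, 64L, 64L); mask[20:45, 20:45] <- TRUE
  expect_error(measure_wound_area(mask, depth_image(dd), k),
               class = "wa_steep_plane")
})

test_that("contour subsampling still measures accurately", {
  spec <- tilted_wound_scene(30, 30, 0.5)
  sc <- render_scene(spec)
  m_all <- measure_wound_area(sc$mask, sc$depth, spec$intrinsics)
  m_sub <- measure_wound_area(sc$mask, sc$depth, spec$intrinsics,
                              config = measurement_config(contour_step = 5L))
  expect_lt(m_sub$n_vertices_used, m_all$n_vertices_used / 4)
  expect_lt(abs(m_sub$area_cm2 - 30) / 30, 0.01)
})

test_that("measurement objects print, summarize and expose coefficients", {
  spec <- tilted_wound_scene(20, 40, 0.4)
  sc <- render_scene(spec)
  m <- measure_wound_area(sc$mask, sc$depth, spec$intrinsics)
  expect_output(print(m), "Wound area")
  expect_output(print(summary(m)), "boundary correction")
  expect_named(coef(m), c("a", "b", "c"))
})

test_that("the file-level pipeline round-trips through disk", {
  out <- file.path(tempdir(), "scene-e2e")
  paths <- simulate_scene_files(out, area_cm2 = 20, tilt_deg = 30,
                                fill_fraction = 0.4)
  rep_json <- file.path(out, "report.json")
  log_csv <- file.path(out, "log.csv")
  m <- measure_wound_file(mask = paths$mask, depth = paths$depth,
                          camera = paths$camera,
                          out_json = rep_json, log_csv = log_csv)
  truth <- jsonlite::read_json(paths$truth)
  expect_lt(abs(m$area_cm2 - truth$truth_area_cm2) / truth$truth_area_cm2,
            0.01)
  rep <- jsonlite::read_json(rep_json)
  expect_equal(rep$area_cm2, m$area_cm2, tolerance = 1e-9)
  log <- read.csv(log_csv)
  expect_equal(nrow(log), 1L)
  expect_equal(log$area_cm2, m$area_cm2, tolerance = 1e-9)

  # LabelMe polygon input against the same depth
  ct <- extract_contour(read_mask(paths$mask))
  lm_file <- file.path(out, "ann.json")
  doc <- list(shapes = list(list(label = "wound",
                                 points = lapply(seq_len(nrow(ct)),
                                                 function(i) as.list(ct[i, ])),
                                 shape_type = "polygon")),
              imageWidth = 512L, imageHeight = 512L)
  jsonlite::write_json(doc, lm_file, auto_unbox = TRUE, digits = NA)
  m2 <- measure_wound_file(labelme = lm_file, depth = paths$depth,
                           camera = paths$camera)
  expect_lt(abs(m2$area_cm2 - truth$truth_area_cm2) /
              truth$truth_area_cm2, 0.02)

  expect_error(measure_wound_file(mask = paths$mask,
                                  depth = file.path(out, "nope.png"),
                                  camera = paths$camera),
               class = "wa_io_error")
  unlink(out, recursive = TRUE)
})

test_that("segmentation evaluation from files pairs and aggregates", {
  dir_p <- file.path(tempdir(), "seg-pred")
  dir_t <- file.path(tempdir(), "seg-truth")
  dir.create(dir_p, showWarnings = FALSE)
  dir.create(dir_t, showWarnings = FALSE)
  on.exit(unlink(c(dir_p, dir_t), recursive = TRUE))
  m1 <- disk_mask(64L, 0.3)
  m2 <- disk_mask(64L, 0.2)
  write_mask(m1, file.path(dir_p, "a.png"))
  write_mask(m1, file.path(dir_t, "a.png"))
  write_mask(m2, file.path(dir_p, "b.png"))
  write_mask(m1, file.path(dir_t, "b.png"))
  out_json <- tempfile(fileext = ".json")
  res <- evaluate_seg_files(dir_p, dir_t, out_json = out_json)
  expect_equal(res$per_image["a.png", "dice"], 1)
  expect_lt(res$per_image["b.png", "dice"], 1)
  js <- jsonlite::read_json(out_json)
  expect_equal(js$mean$dice, unname(res$mean[["dice"]]), tolerance = 1e-12)

  write_mask(m2, file.path(dir_p, "c.png"))  # unpaired
  expect_error(evaluate_seg_files(dir_p, dir_t), class = "wa_input_error")
})

test_that("area evaluation from CSV and the bundled table agree", {
  f <- tempfile(fileext = ".csv")
  rec <- area_records("maskrcnn")
  names(rec) <- c("wound_id", "manual_area_cm2", "auto_area_cm2",
                  "re_percent", "outlier")
  write.csv(rec, f, row.names = FALSE)
  from_csv <- evaluate_area_file(csv = f)
  from_tab <- evaluate_area_file(clinical = "maskrcnn")
  expect_equal(from_csv$mre_percent, from_tab$mre_percent)
  excl <- evaluate_area_file(csv = f, exclude = "outliers")
  expect_equal(excl$n_used, 18L)
  expect_error(evaluate_area_file(csv = tempfile()), class = "wa_io_error")
})
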