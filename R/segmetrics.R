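# Pixel-level segmentation evaluation: confusion counts, Dice, IoU,
# precision, recall, accuracy, and the epsilon-smoothed Dice loss.

#' Pixel confusion counts between two masks
#'
#' Tallies true positives (wound pixels predicted as wound), false
#' positives, false negatives and true negatives between a predicted and a
#' ground-truth binary mask of identical dimensions.
#'
#' @param pred,truth Logical (or 0/1 numeric) matrices of the same size.
#' @return An object of class `"confusion_counts"`: a list with integer
#'   fields `tp`, `fp`, `fn`, `tn` summing to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_mask(pred, "pred")
  truth <- as_mask(truth, "truth")
  if (!identical(dim(pred), dim(truth))) {
    stop_wa(sprintf("mask dimensions differ: %s vs %s",
                    paste(dim(pred), collapse = "x"),
                    paste(dim(truth), collapse = "x")),
            "wa_input_error")
  }
  structure(list(
    tp = sum(pred & truth),
    fp = sum(pred & !truth),
    fn = sum(!pred & truth),
    tn = sum(!pred & !truth)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Pixel confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "confusion_counts")) return(x)
  if (is.numeric(x) && !is.null(names(x)) &&
      all(c("tp", "fp", "fn") %in% names(x))) {
    return(structure(list(tp = x[["tp"]], fp = x[["fp"]], fn = x[["fn"]],
                          tn = if ("tn" %in% names(x)) x[["tn"]] else 0),
                     class = "confusion_counts"))
  }
  stop_wa("expected confusion counts (or a named vector with tp/fp/fn[/tn])",
          "wa_input_error")
}

metric_ratio <- function(num, den, empty) {
  if (den > 0) return(num / den)
  if (identical(empty, "one")) {
    warn_wa("metric undefined (empty denominator); returning 1 by convention")
    return(1)
  }
  stop_wa("metric undefined: zero denominator", "wa_input_error")
}

#' Segmentation overlap and classification metrics
#'
#' The five standard pixel metrics on a confusion-count tally:
#' \describe{
#'   \item{`dice()`}{2TP / (2TP + FP + FN): twice the overlap divided by
#'     the sum of the two mask areas.}
#'   \item{`iou()`}{TP / (TP + FP + FN): overlap divided by union. Related
#'     to Dice by DC = 2 IoU / (1 + IoU).}
#'   \item{`precision()`}{TP / (TP + FP), the positive predictive value.}
#'   \item{`recall()`}{TP / (TP + FN), the sensitivity.}
#'   \item{`accuracy()`}{(TP + TN) / all pixels.}
#' }
#' When the defining denominator is zero (e.g. both masks empty for Dice)
#' the value is, by convention, 1 with a warning; set `empty = "error"` to
#' fail instead. This convention matches the behaviour of the
#' epsilon-smoothed [dice_loss()] in the empty/empty limit.
#'
#' @param x A [confusion_counts()] object (or a named vector with elements
#'   tp, fp, fn and optionally tn).
#' @param empty Zero-denominator policy: `"one"` (default) or `"error"`.
#' @return A fraction in \code{[0, 1]}.
#' @examples
#' cc <- structure(list(tp = 6, fp = 2, fn = 2, tn = 90),
#'                 class = "confusion_counts")
#' dice(cc)   # 0.75
#' iou(cc)    # 0.6
#' @export
dice <- function(x, empty = c("one", "error")) {
  x <- as_counts(x)
  metric_ratio(2 * x$tp, 2 * x$tp + x$fp + x$fn, match.arg(empty))
}

#' @rdname dice
#' @export
iou <- function(x, empty = c("one", "error")) {
  x <- as_counts(x)
  metric_ratio(x$tp, x$tp + x$fp + x$fn, match.arg(empty))
}

#' @rdname dice
#' @export
precision <- function(x, empty = c("one", "error")) {
  x <- as_counts(x)
  metric_ratio(x$tp, x$tp + x$fp, match.arg(empty))
}

#' @rdname dice
#' @export
recall <- function(x, empty = c("one", "error")) {
  x <- as_counts(x)
  metric_ratio(x$tp, x$tp + x$fn, match.arg(empty))
}

#' @rdname dice
#' @export
accuracy <- function(x, empty = c("one", "error")) {
  x <- as_counts(x)
  metric_ratio(x$tp + x$tn, x$tp + x$fp + x$fn + x$tn, match.arg(empty))
}

#' Smoothed Dice loss
#'
#' The training loss 1 - (2TP + eps) / (2TP + FP + FN + eps). The epsilon
#' term guards the 0/0 case when both prediction and ground truth are
#' empty, for which the loss is 0 (a perfect match).
#'
#' @param x A [confusion_counts()] object.
#' @param epsilon Smoothing constant, > 0.
#' @return The loss, in \code{[0, 1)}.
#' @examples
#' dice_loss(structure(list(tp = 6, fp = 2, fn = 2, tn = 0),
#'                     class = "confusion_counts"), epsilon = 1)  # 4/17
#' @export
dice_loss <- function(x, epsilon = 1) {
  x <- as_counts(x)
  check_number(epsilon, "epsilon", positive = TRUE)
  1 - (2 * x$tp + epsilon) / (2 * x$tp + x$fp + x$fn + epsilon)
}

#' All five segmentation metrics at once
#'
#' @param pred,truth Binary masks, or pass a [confusion_counts()] object as
#'   `pred` and omit `truth`.
#' @inheritParams dice
#' @return An object of class `"seg_metrics"`: a named numeric vector with
#'   elements `dice`, `iou`, `precision`, `recall`, `accuracy`.
#' @export
seg_metrics <- function(pred, truth = NULL, empty = c("one", "error")) {
  empty <- match.arg(empty)
  cc <- if (inherits(pred, "confusion_counts") && is.null(truth)) pred
        else confusion_counts(pred, truth)
  structure(c(dice = dice(cc, empty), iou = iou(cc, empty),
              precision = precision(cc, empty), recall = recall(cc, empty),
              accuracy = accuracy(cc, empty)),
            class = "seg_metrics", counts = cc)
}

#' @export
print.seg_metrics <- function(x, digits = 4, ...) {
  cat("Segmentation metrics:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Aggregate segmentation metrics over paired masks
#'
#' Computes per-image metrics for each (prediction, ground truth) pair and
#' aggregates them. `"macro"` (the default) averages the per-image metric
#' values with equal weight per image, the usual convention for reporting
#' a mean Dice coefficient; `"micro"` pools the pixel confusion counts
#' across images first and computes the metrics once on the pooled tally.
#' The two differ whenever image difficulty correlates with wound size.
#'
#' @param pred,truth Lists of binary masks, pairwise of identical sizes.
#' @param average `"macro"` or `"micro"`.
#' @inheritParams dice
#' @return A list with `per_image` (a data frame of per-image metrics),
#'   `mean` (a `"seg_metrics"` vector), and `average`.
#' @export
batch_seg_metrics <- function(pred, truth, average = c("macro", "micro"),
                              empty = c("one", "error")) {
  average <- match.arg(average)
  empty <- match.arg(empty)
  if (!is.list(pred) || !is.list(truth) || length(pred) != length(truth) ||
      length(pred) == 0L) {
    stop_wa("`pred` and `truth` must be non-empty lists of equal length",
            "wa_input_error")
  }
  counts <- Map(confusion_counts, pred, truth)
  per <- do.call(rbind, lapply(counts, function(cc) {
    as.data.frame(as.list(unclass(seg_metrics(cc, empty = empty))))
  }))
  rownames(per) <- names(pred) %||% seq_along(pred)
  mean_metrics <- if (average == "macro") {
    structure(colMeans(per), class = "seg_metrics")
  } else {
    pooled <- structure(list(
      tp = sum(vapply(counts, `[[`, 0, "tp")),
      fp = sum(vapply(counts, `[[`, 0, "fp")),
      fn = sum(vapply(counts, `[[`, 0, "fn")),
      tn = sum(vapply(counts, `[[`, 0, "tn"))
    ), class = "confusion_counts")
    seg_metrics(pooled, empty = empty)
  }
  list(per_image = per, mean = mean_metrics, average = average)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
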