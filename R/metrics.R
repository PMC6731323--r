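#' Pixel confusion counts between predicted and ground-truth masks
#'
#' Positive = tumour.  By default only tissue pixels enter the counts
#' (glass background would otherwise inflate the true-negative count);
#' pass `tissue = NULL` to evaluate over all pixels.
#'
#' @param pred logical matrix of predicted tumour pixels.
#' @param truth logical matrix of ground-truth tumour pixels (same
#'   dimensions).
#' @param tissue optional logical matrix restricting evaluation to
#'   tissue pixels.
#' @return A `confusion_counts` object with fields `TP`, `FP`, `TN`,
#'   `FN` summing to the number of evaluated pixels.
#' @export
confusion_counts <- function(pred, truth, tissue = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stopf("prediction (%s) and truth (%s) dimensions differ",
          paste(dim(pred), collapse = "x"), paste(dim(truth), collapse = "x"))
  if (!is.null(tissue)) {
    if (!identical(dim(tissue), dim(truth)))
      stopf("tissue mask dimensions differ from the masks under evaluation")
    pred <- pred[tissue]; truth <- truth[tissue]
  }
  structure(list(TP = sum(pred & truth), FP = sum(pred & !truth),
                 TN = sum(!pred & !truth), FN = sum(!pred & truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

metric_formulas <- function(cc) {
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  with(cc, c(TPR = safe(TP, TP + FN), TNR = safe(TN, TN + FP),
             FPR = safe(FP, FP + TN), FNR = safe(FN, FN + TP),
             PPV = safe(TP, TP + FP), NPV = safe(TN, TN + FN),
             Dice = safe(2 * TP, 2 * TP + FP + FN)))
}

#' Validation metric report
#'
#' Computes TPR, TNR, FPR, FNR, PPV, NPV and the Dice coefficient from
#' confusion counts.  For a list of per-slide counts the cohort summary
#' is the unweighted mean and standard deviation over slides.  Metrics
#' with a zero denominator are reported as `NA` ("undefined"), with a
#' warning, and excluded from cohort means.
#'
#' @param counts a `confusion_counts` object or a (optionally named)
#'   list of them, one per slide.
#' @return A `metric_report` with `per_slide` (data frame of metric
#'   values) and `summary` (mean and sd per metric; single-slide reports
#'   have an all-`NA` sd).
#' @export
metric_report <- function(counts) {
  if (inherits(counts, "confusion_counts")) counts <- list(counts)
  if (!length(counts) || !all(vapply(counts, inherits, TRUE, "confusion_counts")))
    stopf("counts must be one or more confusion_counts objects")
  per <- t(vapply(counts, metric_formulas, numeric(7)))
  rownames(per) <- if (!is.null(names(counts))) names(counts)
                   else paste0("slide", seq_along(counts))
  if (anyNA(per))
    warning("metrics with zero denominators are undefined and reported as NA")
  summary <- rbind(mean = colMeans(per, na.rm = TRUE),
                   sd = apply(per, 2, sd, na.rm = TRUE))
  structure(list(per_slide = as.data.frame(per), summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metric_report> %d slide(s)\n", nrow(x$per_slide)))
  m <- x$summary["mean", ]; s <- x$summary["sd", ]
  for (i in seq_along(m))
    cat(sprintf("  %-4s %s%s\n", names(m)[i], format(round(m[i], digits)),
                if (!is.na(s[i])) paste0(" ± ", format(round(s[i], digits)))
                else ""))
  invisible(x)
}

#' Four-colour confusion overlay
#'
#' Renders the pixel-level comparison of prediction and truth in the
#' conventional colour key: true positives green, false negatives pink,
#' false positives yellow, true negatives blue.
#'
#' @param pred,truth logical matrices (same dimensions).
#' @param thumb optional RGB array at the same resolution to blend
#'   under the overlay.
#' @param opacity overlay opacity when `thumb` is given.
#' @return RGB array.
#' @export
render_confusion_overlay <- function(pred, truth, thumb = NULL,
                                     opacity = 1) {
  if (!identical(dim(pred), dim(truth)))
    stopf("prediction and truth dimensions differ")
  key <- list(TP = c(0, 0.7, 0), FN = c(1, 0.6, 0.8),
              FP = c(1, 1, 0), TN = c(0.25, 0.35, 0.9))
  sel <- list(TP = pred & truth, FN = !pred & truth,
              FP = pred & !truth, TN = !pred & !truth)
  out <- if (is.null(thumb)) array(0, c(dim(pred), 3)) else thumb
  for (ch in 1:3) {
    plane <- out[, , ch]
    for (nm in names(key)) {
      v <- key[[nm]][ch]
      plane[sel[[nm]]] <- if (is.null(thumb)) v
        else plane[sel[[nm]]] * (1 - opacity) + v * opacity
    }
    out[, , ch] <- plane
  }
  out
}
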