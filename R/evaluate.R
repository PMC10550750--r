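#' Pixel-level confusion matrix between predicted and annotated polygons
#'
#' Both polygon sets are rasterized over the evaluation region with
#' pixel-center inclusion at the given raster step and compared pixel by
#' pixel: TP are pixels inside both sets, FP inside the prediction only,
#' FN inside the annotation only, TN inside neither. The four counts
#' always sum to the raster pixel count of the region.
#'
#' @param pred,truth `pcead_polyset` objects on the same slide.
#' @param region `c(x0, y0, x1, y1)` half-open level-0 rectangle
#'   (typically the slide's tissue bounding box).
#' @param downsample raster step (1 = exact pixel counts).
#' @return A `pcead_confusion` with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
pixel_confusion <- function(pred, truth, region, downsample = 1) {
  stopifnot(length(region) == 4L, downsample >= 1)
  if (region[3] <= region[1] || region[4] <= region[2])
    stop("evaluation region is empty or inverted")
  if (length(pred$polygons) && length(truth$polygons) &&
      !identical(pred$slide, truth$slide))
    stop("prediction and annotation come from different slides")
  pm <- rasterize_polygons(pred, region, downsample)
  tm <- rasterize_polygons(truth, region, downsample)
  structure(list(tp = sum(pm & tm), fp = sum(pm & !tm),
                 fn = sum(!pm & tm), tn = sum(!pm & !tm),
                 region = region, downsample = downsample,
                 slide = pred$slide),
            class = "pcead_confusion")
}

#' @export
print.pcead_confusion <- function(x, ...) {
  cat(sprintf("<pcead_confusion TP %d FP %d FN %d TN %d (d = %g)>\n",
              x$tp, x$fp, x$fn, x$tn, x$downsample))
  invisible(x)
}

#' Per-slide metrics from a confusion matrix
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)` and
#' `F1 = 2 TP / (2 TP + FP + FN)`. A `0/0` ratio (e.g. sensitivity on a
#' slide without annotated tumor) is reported as `NA`, the explicit
#' undefined marker, and excluded from cohort summaries.
#'
#' @param conf a `pcead_confusion`.
#' @param slide optional slide identifier carried into the result.
#' @return A `pcead_metrics` list with `sensitivity`, `specificity`, `f1`.
#' @export
confusion_metrics <- function(conf, slide = conf$slide %||% "slide") {
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(slide = slide,
                 sensitivity = rat(conf$tp, conf$tp + conf$fn),
                 specificity = rat(conf$tn, conf$tn + conf$fp),
                 f1 = rat(2 * conf$tp, 2 * conf$tp + conf$fp + conf$fn)),
            class = "pcead_metrics")
}

#' Slide-level tumor presence call
#'
#' A slide is called positive when its total predicted tumor area reaches
#' `min_area` (boundary inclusive); with the default `min_area = 0` any
#' nonempty prediction is positive and an empty one negative.
#'
#' @param pred a `pcead_polyset` of predictions.
#' @param min_area minimum total area (level-0 px^2) for a positive call.
#' @return `"positive"` or `"negative"`.
#' @export
slide_level_call <- function(pred, min_area = 0) {
  if (length(pred$polygons) > 0L && total_area(pred) >= min_area)
    "positive" else "negative"
}

#' Cohort summary of per-slide metrics
#'
#' Mean and sample standard deviation (denominator `n - 1`) of each metric
#' over the slides where it is defined; undefined (`NA`) values are
#' excluded with a warning naming the slides. Order of slides does not
#' affect the summary.
#'
#' @param per_slide list of `pcead_metrics`.
#' @return List with `table` (per-slide data frame) and `summary`
#'   (data frame of metric, mean, sd, n_defined).
#' @export
summarize_cohort <- function(per_slide) {
  stopifnot(length(per_slide) >= 1L)
  tab <- data.frame(
    slide = vapply(per_slide, function(m) m$slide, ""),
    sensitivity = vapply(per_slide, function(m) m$sensitivity, 0),
    specificity = vapply(per_slide, function(m) m$specificity, 0),
    f1 = vapply(per_slide, function(m) m$f1, 0),
    stringsAsFactors = FALSE)
  summ <- lapply(c("sensitivity", "specificity", "f1"), function(met) {
    v <- tab[[met]]
    bad <- is.na(v)
    if (all(bad))
      stop("metric '", met, "' is undefined on every slide")
    if (any(bad))
      warning(sprintf("excluding %d slide(s) with undefined %s: %s",
                      sum(bad), met,
                      paste(tab$slide[bad], collapse = ", ")))
    v <- v[!bad]
    data.frame(metric = met, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n_defined = length(v), stringsAsFactors = FALSE)
  })
  list(table = tab, summary = do.call(rbind, summ))
}
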