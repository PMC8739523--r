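# Confusion-matrix segmentation metrics, fold aggregation, CNV volumetry.

#' One-vs-rest confusion counts for a class
#'
#' @param pred_labels,gt_labels integer label matrices (or arrays) of equal
#'   extents with values in `0 .. num_classes - 1`.
#' @param class_id the class evaluated as positive.
#' @param num_classes label range upper bound used for validation
#'   (default 9).
#' @return List with `class_id`, `TP`, `TN`, `FP`, `FN` (integers summing
#'   to the evaluated pixel count).
#' @export
confusion_counts <- function(pred_labels, gt_labels, class_id,
                             num_classes = 9L) {
  if (!identical(dim(pred_labels), dim(gt_labels))) {
    stop("prediction and gold-standard extents differ")
  }
  rng <- range(c(pred_labels, gt_labels))
  if (rng[1] < 0 || rng[2] > num_classes - 1L) {
    stop("labels outside 0..", num_classes - 1L)
  }
  p <- pred_labels == class_id
  g <- gt_labels == class_id
  list(class_id = class_id,
       TP = sum(p & g), TN = sum(!p & !g),
       FP = sum(p & !g), FN = sum(!p & g))
}

#' The five segmentation metrics from confusion counts
#'
#' DSC = 2TP/(2TP+FP+FN), IoU = TP/(TP+FP+FN), Acc = (TP+TN)/total,
#' Sen = TP/(TP+FN), Pre = TP/(TP+FP), all as percentages.
#'
#' Zero-denominator convention: when the class is absent from both
#' prediction and gold standard (TP+FP+FN = 0), the overlap metrics are
#' recorded as 100 and the result is flagged `degenerate`; when it is
#' absent from exactly one side, a zero numerator already yields 0.
#'
#' @param counts a list with `TP`, `TN`, `FP`, `FN` (see
#'   [confusion_counts()]).
#' @return Named numeric vector `c(DSC, IoU, Acc, Sen, Pre)` in percent,
#'   with attribute `degenerate`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  degenerate <- (TP + FP + FN) == 0
  ratio <- function(num, den) if (den == 0) 1 else num / den
  out <- c(
    DSC = ratio(2 * TP, 2 * TP + FP + FN),
    IoU = ratio(TP, TP + FP + FN),
    Acc = ratio(TP + TN, total),
    Sen = ratio(TP, TP + FN),
    Pre = ratio(TP, TP + FP)
  ) * 100
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-class metric report for a set of images
#'
#' Confusion counts are accumulated over all images of the set and the
#' five metrics are computed per class, together with macro averages over
#' the foreground classes (all classes but background), over the layer
#' classes only, and the lesion-class row separately.
#'
#' @param pred_list,gt_list lists of label matrices (paired).
#' @param num_classes total classes (default 9).
#' @param cnv_class label id of the lesion class (default
#'   `num_classes - 1`).
#' @return A `dw_metric_report`: list with `per_class` (data.frame of
#'   class, the five metrics, degenerate flag), `macro` (foreground mean),
#'   `macro_layers` (layer classes only), `cnv` (lesion row), `n_images`.
#' @export
metric_report <- function(pred_list, gt_list, num_classes = 9L,
                          cnv_class = num_classes - 1L) {
  stopifnot(length(pred_list) == length(gt_list), length(pred_list) >= 1L)
  rows <- list()
  for (cls in 0:(num_classes - 1L)) {
    acc <- list(class_id = cls, TP = 0, TN = 0, FP = 0, FN = 0)
    for (idx in seq_along(pred_list)) {
      cc <- confusion_counts(pred_list[[idx]], gt_list[[idx]], cls, num_classes)
      acc$TP <- acc$TP + cc$TP; acc$TN <- acc$TN + cc$TN
      acc$FP <- acc$FP + cc$FP; acc$FN <- acc$FN + cc$FN
    }
    m <- compute_metrics(acc)
    rows[[cls + 1L]] <- data.frame(class = cls, t(m),
                                   degenerate = attr(m, "degenerate"))
  }
  per_class <- do.call(rbind, rows)
  metric_cols <- c("DSC", "IoU", "Acc", "Sen", "Pre")
  fg <- per_class$class > 0
  layers <- per_class$class > 0 & per_class$class != cnv_class
  report <- list(
    per_class = per_class,
    macro = colMeans(per_class[fg, metric_cols, drop = FALSE]),
    macro_layers = colMeans(per_class[layers, metric_cols, drop = FALSE]),
    cnv = unlist(per_class[per_class$class == cnv_class, metric_cols]),
    n_images = length(pred_list)
  )
  class(report) <- "dw_metric_report"
  report
}

#' Aggregate fold-wise metric reports as mean and SD
#'
#' @param reports list of `dw_metric_report` objects (one per fold) or of
#'   named numeric vectors of metrics; at least 2.
#' @param which when reports are `dw_metric_report`s, which summary to
#'   aggregate: `"macro"`, `"macro_layers"` or `"cnv"`.
#' @return data.frame with columns `metric`, `mean`, `sd` (sample SD,
#'   n - 1 denominator).
#' @export
aggregate_folds <- function(reports, which = c("macro", "macro_layers", "cnv")) {
  if (length(reports) < 2L) stop("need at least 2 fold reports")
  which <- match.arg(which)
  vecs <- lapply(reports, function(r) {
    if (inherits(r, "dw_metric_report")) r[[which]] else r
  })
  m <- do.call(rbind, vecs)
  data.frame(metric = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             row.names = NULL)
}

#' CNV volume of a mask stack
#'
#' Counts lesion-labeled voxels across the B-scans of a volume and scales
#' by the voxel size.  The default voxel dimensions follow the scanner
#' geometry of a 6 x 2 x 6 mm field sampled at 512 x 1024 x 128 voxels.
#'
#' @param mask_stack list of label matrices (the slices of one volume),
#'   all of equal extents.
#' @param voxel_dims numeric length-3 `(dx, dy, dz)` in mm; default
#'   `c(6/512, 2/1024, 6/128)`.
#' @param cnv_class lesion label id (default 8).
#' @return Volume in mm^3.
#' @export
cnv_volume <- function(mask_stack, voxel_dims = c(6 / 512, 2 / 1024, 6 / 128),
                       cnv_class = 8L) {
  stopifnot(length(voxel_dims) == 3L, all(voxel_dims > 0))
  if (length(mask_stack) == 0L) return(0)
  d0 <- dim(mask_stack[[1]])
  n <- 0
  for (m in mask_stack) {
    if (!identical(dim(m), d0)) stop("inconsistent extents across the stack")
    n <- n + sum(m == cnv_class)
  }
  n * prod(voxel_dims)
}
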