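# Evaluation metrics: MAE and MAPE over the four quantitative biophysical
# properties per sample, a tabular report mirroring the per-sample layout
# of a GT/prediction comparison, and mask average precision for external
# instance-segmentation outputs.

QUANT_PROPS <- c("FL", "FW", "VL", "VW")

# coerce a one-row data frame / named list / named vector to the named
# quantitative property vector
as_property_values <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  if (is.list(x)) x <- unlist(x[names(x) %in% c(QUANT_PROPS, names(x))])
  if (is.null(names(x))) {
    if (length(x) != 4L)
      stop("unnamed property vector must have exactly 4 entries", call. = FALSE)
    names(x) <- QUANT_PROPS
  }
  miss <- setdiff(QUANT_PROPS, names(x))
  if (length(miss))
    stop("property set mismatch: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- as.numeric(x[QUANT_PROPS])
  names(v) <- QUANT_PROPS
  if (any(!is.finite(v)))
    stop("property values must be finite", call. = FALSE)
  v
}

#' Mean absolute error over the quantitative properties
#'
#' `MAE = mean(|y_i - yhat_i|)` over the N = 4 quantitative properties
#' (FL, FW, VL, VW) of one sample.
#'
#' @param gt,pred ground-truth and predicted values: named vectors, named
#'   lists or one-row data frames carrying `FL, FW, VL, VW`.
#' @return Mean absolute error (same units as the inputs).
#' @export
mae <- function(gt, pred) {
  y <- as_property_values(gt)
  yh <- as_property_values(pred)
  mean(abs(y - yh))
}

#' Mean absolute percentage error over the quantitative properties
#'
#' `MAPE = mean(|y_i - yhat_i| / y_i) * 100` over the N = 4 quantitative
#' properties of one sample. Undefined when any ground-truth entry is
#' zero.
#'
#' @inheritParams mae
#' @return MAPE in percent.
#' @export
mape <- function(gt, pred) {
  y <- as_property_values(gt)
  yh <- as_property_values(pred)
  zero <- names(y)[y == 0]
  if (length(zero))
    stop("MAPE undefined: ground truth is zero for ",
         paste(zero, collapse = ", "), call. = FALSE)
  mean(abs(y - yh) / abs(y)) * 100
}

#' Evaluate a table of predicted vs ground-truth records
#'
#' Computes per-sample MAE, MAPE and a peel-color match flag, plus
#' unweighted means across samples and the overall peel-color match
#' fraction. Values are kept at full precision; round for display.
#'
#' @param gt,pred data frames with columns `sample_id, FL, FW, VL, VW,
#'   FPC`, one row per sample; the two must carry the same sample ids.
#' @return List with `per_sample` (data frame: `sample_id, mae, mape_pct,
#'   fpc_match`) and `summary` (list: `mean_mae, mean_mape_pct,
#'   fpc_match_rate, n_samples`).
#' @export
evaluate_table <- function(gt, pred) {
  req <- c("sample_id", QUANT_PROPS, "FPC")
  for (nm in list(gt = gt, pred = pred)) {
    miss <- setdiff(req, names(nm))
    if (length(miss))
      stop("table is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  only_gt <- setdiff(gt$sample_id, pred$sample_id)
  only_pr <- setdiff(pred$sample_id, gt$sample_id)
  if (length(only_gt) || length(only_pr))
    stop("sample ids differ between tables: ",
         paste(c(only_gt, only_pr), collapse = ", "), call. = FALSE)
  pred <- pred[match(gt$sample_id, pred$sample_id), , drop = FALSE]
  per <- data.frame(sample_id = gt$sample_id,
                    mae = NA_real_, mape_pct = NA_real_, fpc_match = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gt))) {
    per$mae[i] <- mae(gt[i, ], pred[i, ])
    per$mape_pct[i] <- mape(gt[i, ], pred[i, ])
    per$fpc_match[i] <- identical(as.character(gt$FPC[i]),
                                  as.character(pred$FPC[i]))
  }
  list(per_sample = per,
       summary = list(mean_mae = mean(per$mae),
                      mean_mape_pct = mean(per$mape_pct),
                      fpc_match_rate = mean(per$fpc_match),
                      n_samples = nrow(per)))
}

#' Read or write a property table CSV
#'
#' The CSV schema is `sample_id, FL, FW, VL, VW, FPC`.
#'
#' @param path CSV file path.
#' @return `read_property_table` returns a data frame;
#'   `write_property_table` returns `path` invisibly.
#' @export
read_property_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mm <- paste0(QUANT_PROPS, "_mm")
  hit <- mm %in% names(df)
  names(df)[match(mm[hit], names(df))] <- QUANT_PROPS[hit]
  miss <- setdiff(c("sample_id", QUANT_PROPS, "FPC"), names(df))
  if (length(miss))
    stop("property table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_property_table
#' @param df property data frame.
#' @export
write_property_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Intersection over union of two masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @return Pixel-set IoU in `[0, 1]` (0 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' Mask average precision over classes
#'
#' Per class, predictions are sorted by descending confidence and matched
#' greedily one-to-one to the unmatched ground-truth mask of highest IoU,
#' counting a true positive when that IoU reaches `iou_threshold`. AP is
#' the area under the all-point interpolated precision-recall curve; mAP
#' is the unweighted mean over classes that have at least one ground-truth
#' instance (classes without ground truth are excluded).
#'
#' @param preds list of predictions, each a list with `mask` (logical
#'   matrix), `score` in `[0, 1]` and `category`.
#' @param gts list of ground-truth instances, each a list with `mask` and
#'   `category`.
#' @param iou_threshold mask-IoU matching threshold, default 0.5.
#' @return List with `per_class` (named AP vector) and `mAP`.
#' @export
mask_average_precision <- function(preds, gts, iou_threshold = 0.5) {
  for (p in preds) {
    if (p$score < 0 || p$score > 1)
      stop("prediction scores must lie in [0, 1]", call. = FALSE)
  }
  gt_classes <- unique(vapply(gts, function(g) as.character(g$category),
                              character(1)))
  if (length(gt_classes) == 0L)
    stop("no ground-truth instances", call. = FALSE)
  ap <- vapply(gt_classes, function(cl) {
    cls_gt <- Filter(function(g) g$category == cl, gts)
    cls_pred <- Filter(function(p) p$category == cl, preds)
    average_precision_class(cls_pred, cls_gt, iou_threshold)
  }, numeric(1))
  names(ap) <- gt_classes
  list(per_class = ap, mAP = mean(ap))
}

# AP of one class: greedy matching + all-point interpolated PR area.
average_precision_class <- function(preds, gts, iou_threshold) {
  n_gt <- length(gts)
  if (length(preds) == 0L) return(0)
  scores <- vapply(preds, function(p) p$score, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  matched <- rep(FALSE, n_gt)
  tp <- numeric(length(preds))
  for (k in seq_along(ord)) {
    p <- preds[[ord[k]]]
    ious <- vapply(seq_len(n_gt), function(j) {
      if (matched[j]) -1 else mask_iou(p$mask, gts[[j]]$mask)
    }, numeric(1))
    best <- which.max(ious)
    if (n_gt > 0 && ious[best] >= iou_threshold) {
      matched[best] <- TRUE
      tp[k] <- 1
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  pr_curve_area(precision, recall)
}

# all-point interpolation: precision envelope from the right, integrate
# over recall increments
pr_curve_area <- function(precision, recall) {
  prec <- c(precision, 0)
  rec <- c(0, recall)
  prec_env <- rev(cummax(rev(prec)))
  sum(diff(rec) * prec_env[-length(prec_env)])
}
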