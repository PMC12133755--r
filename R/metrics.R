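# Detection/segmentation evaluation: greedy confidence-ordered matching,
# precision/recall, average precision with the all-point precision envelope
# (101-point interpolation available), mAP over an IoU threshold grid, and
# the regression-style ratio error metrics.

#' Match predictions to ground truth at an IoU threshold
#'
#' Predictions are processed in descending confidence (ties broken by input
#' order). Each prediction claims the unmatched ground-truth object of
#' highest IoU provided that IoU reaches `threshold`; otherwise it is a
#' false positive. Ground-truth objects left unmatched are false negatives.
#' This is the greedy single-match protocol standard for detector
#' evaluation.
#'
#' @param preds list of prediction objects (masks or `bbox`es).
#' @param truths list of ground-truth objects of the same kind.
#' @param confidences numeric vector, one per prediction.
#' @param iou_fn pairwise overlap function, [mask_iou()] or [box_iou()].
#' @param threshold IoU threshold in (0, 1\].
#' @return a list of class `match_table`: `assignments` data frame
#'   (`pred, truth, confidence, is_tp` in confidence order), counts `tp`,
#'   `fp`, `fn`, and `threshold`.
#' @export
match_predictions <- function(preds, truths, confidences,
                              iou_fn = box_iou, threshold = 0.5) {
  np <- length(preds); nt <- length(truths)
  stopifnot(length(confidences) == np)
  ord <- order(-confidences, seq_len(np))
  taken <- rep(FALSE, nt)
  assign <- data.frame(pred = integer(np), truth = rep(NA_integer_, np),
                       confidence = double(np), is_tp = logical(np))
  for (k in seq_len(np)) {
    i <- ord[k]
    best_j <- NA_integer_; best_iou <- -1
    for (j in seq_len(nt)) {
      if (taken[j]) next
      o <- iou_fn(preds[[i]], truths[[j]])
      if (o > best_iou) { best_iou <- o; best_j <- j }
    }
    tp <- !is.na(best_j) && best_iou >= threshold
    if (tp) taken[best_j] <- TRUE
    assign$pred[k] <- i
    assign$truth[k] <- if (tp) best_j else NA_integer_
    assign$confidence[k] <- confidences[i]
    assign$is_tp[k] <- tp
  }
  structure(list(assignments = assign,
                 tp = sum(assign$is_tp), fp = sum(!assign$is_tp),
                 fn = nt - sum(assign$is_tp),
                 n_truth = nt, threshold = threshold),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table @IoU>=%.2f: TP %d, FP %d, FN %d>\n",
              x$threshold, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision and recall from a match table
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`, with the conventions
#' `P = 1` when there are no predictions and `R = 1` when there is no ground
#' truth.
#'
#' @param table a `match_table` (or any list with `tp`, `fp`, `fn`).
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(table) {
  p <- if (table$tp + table$fp == 0L) 1 else table$tp / (table$tp + table$fp)
  r <- if (table$tp + table$fn == 0L) 1 else table$tp / (table$tp + table$fn)
  c(precision = p, recall = r)
}

#' Average precision at one IoU threshold
#'
#' Builds the precision-recall curve over descending-confidence prediction
#' prefixes, applies the precision envelope (each recall level gets the
#' maximum precision attained at that recall or beyond), and integrates:
#' exactly for `interpolation = "all-point"`, or by averaging the envelope
#' at 101 equally spaced recalls for `"101-point"`. With no ground truth,
#' AP is 1 if there are also no predictions, else 0.
#'
#' @inheritParams match_predictions
#' @param interpolation `"all-point"` (default) or `"101-point"`.
#' @return a list of class `pr_curve`: `ap`, `curve` (recall, precision per
#'   prefix), and the inputs' counts.
#' @export
average_precision <- function(preds, truths, confidences,
                              iou_fn = box_iou, threshold = 0.5,
                              interpolation = c("all-point", "101-point")) {
  interpolation <- match.arg(interpolation)
  nt <- length(truths)
  if (nt == 0L) {
    ap <- if (length(preds) == 0L) 1 else 0
    return(structure(list(ap = ap,
                          curve = data.frame(recall = double(),
                                             precision = double()),
                          n_pred = length(preds), n_truth = 0L,
                          threshold = threshold),
                     class = "pr_curve"))
  }
  mt <- match_predictions(preds, truths, confidences, iou_fn, threshold)
  tp_flags <- mt$assignments$is_tp  # already in descending-confidence order
  cum_tp <- cumsum(tp_flags)
  cum_fp <- cumsum(!tp_flags)
  recall <- cum_tp / nt
  precision <- cum_tp / (cum_tp + cum_fp)
  ap <- ap_from_curve(recall, precision, interpolation)
  structure(list(ap = ap,
                 curve = data.frame(recall = recall, precision = precision),
                 n_pred = length(preds), n_truth = nt, threshold = threshold),
            class = "pr_curve")
}

ap_from_curve <- function(recall, precision, interpolation) {
  if (length(recall) == 0L) return(0)
  r <- c(0, recall)
  p <- c(0, precision)
  # precision envelope from the right
  env <- rev(cummax(rev(p)))
  if (interpolation == "all-point") {
    sum(diff(r) * env[-1L])
  } else {
    grid <- seq(0, 1, length.out = 101L)
    # envelope precision at recall >= g
    vals <- vapply(grid, function(g) {
      idx <- which(r >= g)
      if (length(idx) == 0L) 0 else max(env[idx])
    }, 0)
    mean(vals)
  }
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve: AP %.4f at IoU>=%.2f (%d preds, %d truths)>\n",
              x$ap, x$threshold, x$n_pred, x$n_truth))
  invisible(x)
}

#' Plot a precision-recall curve
#' @param x a `pr_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pr_curve <- function(x, ...) {
  graphics::plot(c(0, x$curve$recall), c(1, x$curve$precision), type = "s",
                 xlim = c(0, 1), ylim = c(0, 1), xlab = "Recall",
                 ylab = "Precision",
                 main = sprintf("AP = %.3f (IoU >= %.2f)", x$ap, x$threshold),
                 ...)
  invisible(x)
}

#' Mean average precision over classes
#'
#' The arithmetic mean of per-class AP values; with a single class mAP
#' equals that class's AP.
#'
#' @param per_class_aps numeric vector of per-class AP values (>= 1 class).
#' @return scalar mAP.
#' @export
mean_average_precision <- function(per_class_aps) {
  if (length(per_class_aps) == 0L) stopf("mAP needs at least one class AP")
  mean(per_class_aps)
}

#' mAP averaged over an IoU threshold grid
#'
#' The COCO-style `mAP@0.5:0.95`: the mean of AP evaluated at IoU thresholds
#' 0.50, 0.55, ..., 0.95 (10 values) by default.
#'
#' @inheritParams average_precision
#' @param thresholds IoU threshold grid.
#' @return list with `map` (the mean), and `ap_by_threshold`.
#' @export
map_range <- function(preds, truths, confidences, iou_fn = box_iou,
                      thresholds = seq(0.5, 0.95, by = 0.05),
                      interpolation = "all-point") {
  aps <- vapply(thresholds, function(th) {
    average_precision(preds, truths, confidences, iou_fn, th,
                      interpolation)$ap
  }, 0)
  list(map = mean(aps),
       ap_by_threshold = stats::setNames(aps, sprintf("%.2f", thresholds)))
}

#' Ratio error metrics: RMSE, MAE and MAPE
#'
#' `RMSE = sqrt(mean((predicted - truth)^2))`,
#' `MAE = mean(|predicted - truth|)`, and
#' `MAPE = 100 * mean(|truth - predicted| / |truth|)` in percent. Samples
#' with zero ground truth are excluded from MAPE and their count is
#' reported.
#'
#' @param predicted,truth equal-length numeric vectors (length >= 1).
#' @return list `rmse`, `mae`, `mape` (percent), `n`, `n_excluded_mape`.
#' @export
error_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stopf("length mismatch: %d predicted vs %d truth",
          length(predicted), length(truth))
  }
  if (length(truth) == 0L) stopf("error metrics need at least one pair")
  d <- predicted - truth
  nz <- truth != 0
  mape <- if (!any(nz)) {
    stopf("MAPE undefined: all ground-truth values are zero")
  } else {
    100 * mean(abs(d[nz]) / abs(truth[nz]))
  }
  list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)), mape = mape,
       n = length(truth), n_excluded_mape = sum(!nz))
}

#' Evaluate prediction label files against ground-truth label files
#'
#' Pairs files by image id, rasterizes polygons when `kind = "polygon"`,
#' and reports precision/recall at 0.5 plus mAP at 0.5 and over 0.5:0.95.
#' Ids present on only one side are listed and excluded.
#'
#' @param pred_sets,truth_sets named lists of [annotation_set()]s keyed by
#'   image id.
#' @param kind `"box"` or `"polygon"`.
#' @param dims named list of `c(h, w)` grids per image id (needed for
#'   polygon rasterization).
#' @param interpolation AP interpolation rule.
#' @return list with `precision`, `recall`, `map50`, `map50_95`,
#'   `per_image`, `unmatched_ids`.
#' @export
evaluate_sets <- function(pred_sets, truth_sets, kind = c("box", "polygon"),
                          dims = NULL, interpolation = "all-point") {
  kind <- match.arg(kind)
  ids <- intersect(names(truth_sets), names(pred_sets))
  unmatched <- union(setdiff(names(truth_sets), ids),
                     setdiff(names(pred_sets), ids))
  preds <- list(); truths <- list(); confs <- double()
  per_image <- list()
  iou_fn <- if (kind == "box") box_iou else mask_iou
  for (id in ids) {
    ps <- extract_objects(pred_sets[[id]], kind, dims[[id]])
    ts <- extract_objects(truth_sets[[id]], kind, dims[[id]])
    # offset objects per image so cross-image pairs never match: tag by id
    preds <- c(preds, lapply(ps$objects, function(o) list(id = id, obj = o)))
    truths <- c(truths, lapply(ts$objects, function(o) list(id = id, obj = o)))
    confs <- c(confs, ps$confidences)
    per_image[[id]] <- c(n_pred = length(ps$objects),
                         n_truth = length(ts$objects))
  }
  tagged_iou <- function(a, b) {
    if (!identical(a$id, b$id)) return(0)
    iou_fn(a$obj, b$obj)
  }
  pr <- if (length(truths) == 0L && length(preds) == 0L) {
    c(precision = 1, recall = 1)
  } else {
    precision_recall(match_predictions(preds, truths, confs, tagged_iou, 0.5))
  }
  mr <- map_range(preds, truths, confs, tagged_iou,
                  interpolation = interpolation)
  ap50 <- average_precision(preds, truths, confs, tagged_iou, 0.5,
                            interpolation)$ap
  list(precision = unname(pr["precision"]), recall = unname(pr["recall"]),
       map50 = ap50, map50_95 = mr$map,
       ap_by_threshold = mr$ap_by_threshold,
       per_image = per_image, unmatched_ids = unmatched)
}

extract_objects <- function(set, kind, dim_hw) {
  if (kind == "box") {
    n <- nrow(set$boxes)
    objs <- vector("list", n)
    if (n > 0) {
      w <- dim_hw[2L]; h <- dim_hw[1L]
      for (i in seq_len(n)) {
        b <- set$boxes[i, ]
        objs[[i]] <- norm_box_to_bbox(b, w, h)
      }
    }
    confs <- if (n > 0) ifelse(is.na(set$boxes$confidence), 1,
                               set$boxes$confidence) else double()
    list(objects = objs, confidences = confs)
  } else {
    if (is.null(dim_hw)) stopf("polygon evaluation needs image dimensions")
    objs <- lapply(set$polygons, rasterize_polygon,
                   width = dim_hw[2L], height = dim_hw[1L])
    confs <- vapply(set$polygons, function(p) p$confidence %||% 1, 0)
    list(objects = objs, confidences = confs)
  }
}

# normalized center-size record -> pixel bbox (rounded to the half-open grid)
norm_box_to_bbox <- function(b, w, h) {
  x0 <- round((b$cx - b$w / 2) * w); x1 <- round((b$cx + b$w / 2) * w)
  y0 <- round((b$cy - b$h / 2) * h); y1 <- round((b$cy + b$h / 2) * h)
  bbox(max(0L, x0), max(0L, y0), min(w, max(x1, x0 + 1)),
       min(h, max(y1, y0 + 1)))
}
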