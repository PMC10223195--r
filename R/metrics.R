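# Pixel-classification metric suite for vessel segmentation: confusion
# counts, sensitivity/specificity/accuracy/FDR, Cohen's kappa (via the
# expected-agreement expansion from the confusion-matrix marginals), G-mean,
# Dice, rank-based AUC, and dataset-level aggregation.
#
# Degenerate denominators yield NA ("undefined"), never a silent zero.

#' Confusion counts between a binary prediction and ground truth
#'
#' @param pred_mask,gt_mask equal-shaped arrays of 0/1 values.
#' @return list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)) ||
      length(pred_mask) != length(gt_mask)) {
    stop("confusion_counts: shape mismatch")
  }
  p <- as.logical(pred_mask)
  g <- as.logical(gt_mask)
  if (anyNA(p) || anyNA(g)) stop("confusion_counts: masks must be binary")
  list(tp = sum(p & g), fp = sum(p & !g), tn = sum(!p & !g), fn = sum(!p & g))
}

rate <- function(num, den) if (den > 0) num / den else NA_real_

#' Sensitivity, specificity, accuracy and false discovery rate
#'
#' sen = TP/(TP+FN), spe = TN/(TN+FP), acc = (TP+TN)/total,
#' fdr = FP/(FP+TP). Undefined ratios (zero denominator) are `NA`.
#'
#' @param c confusion counts from [confusion_counts()].
#' @return named list `sen`, `spe`, `acc`, `fdr`.
#' @export
basic_rates <- function(c) {
  list(sen = rate(c$tp, c$tp + c$fn),
       spe = rate(c$tn, c$tn + c$fp),
       acc = rate(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn),
       fdr = rate(c$fp, c$fp + c$tp))
}

#' Cohen's kappa from confusion counts
#'
#' Chance agreement is expanded from the marginals,
#' `pe = ((TP+FN)(TP+FP) + (TN+FP)(TN+FN)) / total^2`, and
#' `kappa = (acc - pe) / (1 - pe)`; `NA` when `pe = 1` (both prediction and
#' truth constant).
#'
#' @param c confusion counts.
#' @return kappa in `[-1, 1]`, or `NA`.
#' @export
kappa_score <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot == 0) return(NA_real_)
  pe <- ((c$tp + c$fn) * (c$tp + c$fp) + (c$tn + c$fp) * (c$tn + c$fn)) / tot^2
  if (pe >= 1) return(NA_real_)
  acc <- (c$tp + c$tn) / tot
  (acc - pe) / (1 - pe)
}

#' G-mean of sensitivity and specificity
#'
#' The geometric mean `sqrt(sen * spe)`; `no_sqrt = TRUE` returns the plain
#' product instead.
#'
#' @param c confusion counts.
#' @param no_sqrt return `sen * spe` without the square root.
#' @return G-mean in `[0, 1]`, or `NA` when either rate is undefined.
#' @export
g_mean <- function(c, no_sqrt = FALSE) {
  r <- basic_rates(c)
  if (is.na(r$sen) || is.na(r$spe)) return(NA_real_)
  if (no_sqrt) r$sen * r$spe else sqrt(r$sen * r$spe)
}

#' Dice coefficient from confusion counts
#'
#' `2 TP / (FP + FN + 2 TP)`; `NA` when both masks are empty.
#'
#' @param c confusion counts.
#' @return Dice in `[0, 1]`, or `NA`.
#' @export
dice <- function(c) {
  rate(2 * c$tp, c$fp + c$fn + 2 * c$tp)
}

#' Rank-based AUC of pixel scores against a binary ground truth
#'
#' Mann-Whitney statistic: the probability that a random vessel pixel scores
#' above a random background pixel, ties counted half. `NA` when the ground
#' truth has a single class.
#'
#' @param scores real-valued score grid.
#' @param gt_mask binary grid of the same shape.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc_score <- function(scores, gt_mask) {
  if (length(scores) != length(gt_mask)) stop("auc_score: shape mismatch")
  g <- as.logical(gt_mask)
  np <- sum(g); nn <- sum(!g)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(as.vector(scores), ties.method = "average")
  (sum(r[g]) - np * (np + 1) / 2) / (np * nn)
}

metric_row <- function(scores, gt, threshold, gmean_no_sqrt) {
  cc <- confusion_counts(scores >= threshold, gt)
  r <- basic_rates(cc)
  list(auc = auc_score(scores, gt), acc = r$acc,
       g_mean = g_mean(cc, no_sqrt = gmean_no_sqrt), kappa = kappa_score(cc),
       dice = dice(cc), fdr = r$fdr, sen = r$sen, spe = r$spe)
}

metric_names <- c("auc", "acc", "g_mean", "kappa", "dice", "fdr", "sen", "spe")

#' Evaluate a set of score maps against ground-truth masks
#'
#' Binary metrics are computed at `threshold`; per-image metrics are averaged
#' (`aggregation = "per_image_mean"`, undefined values dropped per metric) or
#' all pixels are pooled into a single confusion matrix
#' (`aggregation = "pooled"`).
#'
#' @param pred_score_maps list of score grids in `[0, 1]`.
#' @param gt_masks list of matching binary masks.
#' @param threshold binarization threshold on the scores (default 0.5).
#' @param aggregation `"per_image_mean"` or `"pooled"`.
#' @param gmean_no_sqrt report the G-mean as the bare product `sen * spe`.
#' @return a `metrics_report`: data frame with one row per image plus an
#'   `"aggregate"` row, columns `auc, acc, g_mean, kappa, dice, fdr, sen, spe`.
#' @export
evaluate_dataset <- function(pred_score_maps, gt_masks, threshold = 0.5,
                             aggregation = c("per_image_mean", "pooled"),
                             gmean_no_sqrt = FALSE) {
  aggregation <- match.arg(aggregation)
  if (length(pred_score_maps) == 0L) stop("evaluate_dataset: empty dataset")
  if (length(pred_score_maps) != length(gt_masks)) {
    stop("evaluate_dataset: prediction/ground-truth lists differ in length")
  }
  rows <- lapply(seq_along(pred_score_maps), function(i) {
    metric_row(pred_score_maps[[i]], gt_masks[[i]], threshold, gmean_no_sqrt)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (aggregation == "per_image_mean") {
    agg <- as.data.frame(lapply(df, function(x) mean(x, na.rm = TRUE)))
  } else {
    pooled_pred <- unlist(lapply(pred_score_maps, as.vector))
    pooled_gt <- unlist(lapply(gt_masks, as.vector))
    agg <- as.data.frame(metric_row(pooled_pred, pooled_gt, threshold,
                                    gmean_no_sqrt))
  }
  out <- rbind(df, agg)
  out <- cbind(image = c(sprintf("img_%03d", seq_along(rows)), "aggregate"),
               out)
  rownames(out) <- NULL
  structure(out, class = c("metrics_report", "data.frame"),
            aggregation = aggregation, threshold = threshold)
}

#' Write a metrics report to CSV or JSON
#'
#' @param report a `metrics_report` from [evaluate_dataset()].
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
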