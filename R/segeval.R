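# Evaluation of instance segmenters against ground truth: mask IoU, greedy
# instance matching, precision, AP@[.5:.95] and the per-image trait
# correlation protocol.

#' Mask intersection over union
#'
#' `IoU = |a AND b| / |a OR b|` over foreground pixels; 0 for disjoint
#' masks. Both masks must share the grid shape; two empty masks have no
#' defined IoU (an `instance_mask` is never empty, but raw logical matrices
#' are accepted too).
#'
#' @param a,b `instance_mask` objects or logical matrices of equal dimension.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  ma <- if (inherits(a, "instance_mask")) a$mask else a != 0
  mb <- if (inherits(b, "instance_mask")) b$mask else b != 0
  if (!all(dim(ma) == dim(mb))) stop("masks must share the same grid shape")
  uni <- sum(ma | mb)
  if (uni == 0L) stop("IoU is undefined for two empty masks")
  sum(ma & mb) / uni
}

#' Match predicted to ground-truth instances at one IoU threshold
#'
#' Per class, predictions are visited in order of descending confidence
#' (ties broken by list position) and each is assigned to the not yet
#' matched ground-truth instance of the same class with the largest IoU,
#' provided that IoU is at least `threshold` (a prediction meeting the
#' threshold exactly counts as a true positive). Unassigned predictions are
#' false positives, unmatched truths are false negatives, so per class
#' `TP + FN` equals the number of ground-truth instances.
#'
#' @param preds,truths lists of `instance_mask` objects.
#' @param threshold IoU threshold in (0, 1).
#' @param iou_matrix optional precomputed IoU matrix (`length(preds)` x
#'   `length(truths)`) to avoid recomputation across thresholds.
#' @return An object of class `match_result`: per-class `tp`, `fp`, `fn`
#'   counts, the matched `(pred, truth, iou)` triples, and the IoU matrix.
#' @export
match_instances <- function(preds, truths, threshold = 0.5, iou_matrix = NULL) {
  classes <- unique(c(vapply(truths, `[[`, character(1), "label"),
                      vapply(preds, `[[`, character(1), "label")))
  if (is.null(iou_matrix)) iou_matrix <- iou_matrix(preds, truths)
  pl <- vapply(preds, `[[`, character(1), "label")
  tl <- vapply(truths, `[[`, character(1), "label")
  conf <- vapply(preds, `[[`, numeric(1), "confidence")

  tp <- fp <- fn <- stats::setNames(integer(length(classes)), classes)
  pairs <- list()
  matched_truth <- rep(FALSE, length(truths))
  for (cl in classes) {
    p_idx <- which(pl == cl)
    p_idx <- p_idx[order(-conf[p_idx])]            # stable: ties keep order
    t_idx <- which(tl == cl)
    for (pi in p_idx) {
      cand <- t_idx[!matched_truth[t_idx]]
      if (length(cand) > 0L) {
        ious <- iou_matrix[pi, cand]
        best <- which.max(ious)
        if (ious[best] >= threshold) {
          matched_truth[cand[best]] <- TRUE
          tp[cl] <- tp[cl] + 1L
          pairs[[length(pairs) + 1L]] <-
            list(pred = pi, truth = cand[best], iou = ious[best], class = cl)
          next
        }
      }
      fp[cl] <- fp[cl] + 1L
    }
    fn[cl] <- sum(tl == cl) - tp[cl]
  }
  structure(list(threshold = threshold, tp = tp, fp = fp, fn = fn,
                 pairs = pairs, iou_matrix = iou_matrix, classes = classes),
            class = "match_result")
}

#' IoU matrix between two mask lists
#'
#' @param preds,truths lists of `instance_mask` objects.
#' @return `length(preds)` x `length(truths)` matrix of IoU values (0 where
#'   the class labels differ).
#' @export
iou_matrix <- function(preds, truths) {
  m <- matrix(0, nrow = length(preds), ncol = length(truths))
  for (i in seq_along(preds)) for (j in seq_along(truths)) {
    if (preds[[i]]$label == truths[[j]]$label)
      m[i, j] <- mask_iou(preds[[i]], truths[[j]])
  }
  m
}

#' Precision of a match result
#'
#' `P = TP / (TP + FP)` pooled over classes. With zero predictions the
#' precision is undefined and returned as `NA`.
#'
#' @param m a `match_result`.
#' @return Precision in \[0, 1\], or `NA` if there were no predictions.
#' @export
precision <- function(m) {
  stopifnot(inherits(m, "match_result"))
  tp <- sum(m$tp); fp <- sum(m$fp)
  if (tp + fp == 0L) return(NA_real_)
  tp / (tp + fp)
}

#' Average precision over IoU thresholds 0.50-0.95
#'
#' Computes precision from [match_instances()] at the ten IoU thresholds
#' 0.50, 0.55, ..., 0.95 for each ground-truth class and reports
#' `AP@[.5:.95] = 100 x mean` over thresholds and classes. The default
#' aggregation is the plain mean precision per class and threshold
#' (macro-averaged over classes); `average = "micro"` pools TP/FP over
#' classes instead, and `style = "coco"` replaces mean precision by the
#' COCO-style area under the precision-recall curve at each threshold, for
#' comparability with detection benchmarks. A class with ground truth but no
#' prediction contributes precision 0.
#'
#' @param preds,truths lists of `instance_mask` objects; `truths` must be
#'   non-empty.
#' @param average `"macro"` (default) or `"micro"` class aggregation.
#' @param style `"mean_precision"` (default) or `"coco"`.
#' @return An object of class `eval_report`: `ap` on the 0-100 scale,
#'   `per_threshold` data frame (threshold, class, tp, fp, fn, precision),
#'   and the IoU matrix.
#' @export
ap_range <- function(preds, truths, average = c("macro", "micro"),
                     style = c("mean_precision", "coco")) {
  average <- match.arg(average)
  style <- match.arg(style)
  if (length(truths) == 0L) stop("AP needs at least one ground-truth instance")
  thresholds <- seq(0.5, 0.95, by = 0.05)
  classes <- unique(vapply(truths, `[[`, character(1), "label"))
  if (length(preds) == 0L) {
    warning("no predictions: AP is 0")
    iom <- matrix(0, 0, length(truths))
  } else iom <- iou_matrix(preds, truths)

  rows <- list()
  for (th in thresholds) {
    m <- if (length(preds) > 0L)
      match_instances(preds, truths, th, iou_matrix = iom) else NULL
    for (cl in classes) {
      tp <- if (is.null(m)) 0L else m$tp[cl]
      fp <- if (is.null(m)) 0L else m$fp[cl]
      fn <- if (is.null(m)) sum(vapply(truths, `[[`, character(1), "label") == cl)
            else m$fn[cl]
      prec <- if (style == "coco") {
        coco_ap_class(preds, truths, cl, th, iom)
      } else if (tp + fp == 0L) 0 else tp / (tp + fp)
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, class = cl, tp = as.integer(tp), fp = as.integer(fp),
        fn = as.integer(fn), precision = prec)
    }
  }
  pt <- do.call(rbind, rows)
  ap <- if (average == "macro") {
    100 * mean(vapply(split(pt$precision, pt$class), mean, numeric(1)))
  } else {
    pooled <- vapply(split(pt, pt$threshold), function(d) {
      tp <- sum(d$tp); fp <- sum(d$fp)
      if (style == "coco") mean(d$precision)
      else if (tp + fp == 0L) 0 else tp / (tp + fp)
    }, numeric(1))
    100 * mean(pooled)
  }
  structure(list(ap = ap, per_threshold = pt, thresholds = thresholds,
                 average = average, style = style, iou_matrix = iom),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: AP@[.5:.95] = %.2f (%s, %s)>\n",
              x$ap, x$average, x$style))
  invisible(x)
}

# COCO-style AP for one class at one threshold: all-point interpolated area
# under the precision-recall curve over confidence-ranked predictions.
coco_ap_class <- function(preds, truths, cl, th, iom) {
  tl <- vapply(truths, `[[`, character(1), "label")
  n_true <- sum(tl == cl)
  if (n_true == 0L) return(0)
  pl <- vapply(preds, `[[`, character(1), "label")
  p_idx <- which(pl == cl)
  if (length(p_idx) == 0L) return(0)
  conf <- vapply(preds, `[[`, numeric(1), "confidence")
  p_idx <- p_idx[order(-conf[p_idx])]
  matched <- rep(FALSE, length(truths))
  is_tp <- logical(length(p_idx))
  t_idx <- which(tl == cl)
  for (i in seq_along(p_idx)) {
    cand <- t_idx[!matched[t_idx]]
    if (length(cand) > 0L) {
      ious <- iom[p_idx[i], cand]
      best <- which.max(ious)
      if (ious[best] >= th) { matched[cand[best]] <- TRUE; is_tp[i] <- TRUE }
    }
  }
  cum_tp <- cumsum(is_tp)
  prec <- cum_tp / seq_along(p_idx)
  rec <- cum_tp / n_true
  # precision envelope, integrate over recall steps
  for (i in rev(seq_len(length(prec) - 1))) prec[i] <- max(prec[i], prec[i + 1])
  sum(diff(c(0, rec)) * prec)
}

#' Per-image trait correlation protocol
#'
#' Benchmarks a segmenter the way field comparisons do: per image, the mean
#' length and mean diameter over ALL predicted cobs (false positives
#' included, which penalizes spurious detections) is compared to the mean
#' over the true cobs, and the Pearson correlation across images is reported
#' separately per trait. Images present in only one of the two tables are
#' dropped; at least 3 shared images are required.
#'
#' @param pred_traits,true_traits data frames of per-cob records with
#'   columns `image_id`, `length`, `diameter` (e.g. from
#'   [phenotype_image()] and from scene ground truth).
#' @return A list with `r_length`, `r_diameter`, `n_images`, and the
#'   per-image mean table.
#' @export
correlation_protocol <- function(pred_traits, true_traits) {
  per_image <- function(df) {
    agg <- stats::aggregate(df[, c("length", "diameter")],
                            by = list(image_id = df$image_id), FUN = mean)
    agg
  }
  p <- per_image(pred_traits); tr <- per_image(true_traits)
  merged <- merge(p, tr, by = "image_id", suffixes = c("_pred", "_true"))
  if (nrow(merged) < 3L)
    stop("correlation needs at least 3 images with predictions and truth")
  for (v in c("length_pred", "length_true", "diameter_pred", "diameter_true"))
    if (stats::sd(merged[[v]]) == 0)
      stop("correlation undefined: zero variance in ", v)
  list(r_length = stats::cor(merged$length_pred, merged$length_true),
       r_diameter = stats::cor(merged$diameter_pred, merged$diameter_true),
       n_images = nrow(merged), per_image = merged)
}
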