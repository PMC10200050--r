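#' Match predicted boxes to ground truth
#'
#' Greedy one-to-one matching: all truth/prediction pairs with IoU
#' strictly greater than `iou_threshold` are candidates; pairs are taken
#' in descending IoU order (ties broken by truth index, then prediction
#' index) with each box used at most once. Matched pairs are true
#' positives; unmatched truths are missed detections; unmatched
#' predictions are false positives.
#'
#' @param truth,pred Box tables.
#' @param iou_threshold Match when IoU is strictly above (so IoU exactly
#'   at the threshold does not match).
#' @return A `match_result`: `pairs` (data.frame `truth_index,
#'   pred_index, iou`, 1-based), `tp`, `fp`, `missed`.
#' @export
match_boxes <- function(truth, pred, iou_threshold = 0.5) {
  truth <- validate_boxes(truth)
  pred <- validate_boxes(pred)
  nt <- nrow(truth)
  np <- nrow(pred)
  pairs <- data.frame(truth_index = integer(), pred_index = integer(),
                      iou = numeric())
  if (nt && np) {
    m <- iou_matrix(truth, pred)
    cand <- which(m > iou_threshold, arr.ind = TRUE)
    if (nrow(cand)) {
      vals <- m[cand]
      ord <- order(-vals, cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      vals <- vals[ord]
      used_t <- logical(nt)
      used_p <- logical(np)
      for (i in seq_len(nrow(cand))) {
        ti <- cand[i, 1]
        pi <- cand[i, 2]
        if (!used_t[ti] && !used_p[pi]) {
          used_t[ti] <- TRUE
          used_p[pi] <- TRUE
          pairs <- rbind(pairs, data.frame(truth_index = ti, pred_index = pi,
                                           iou = vals[i]))
        }
      }
    }
  }
  structure(list(pairs = pairs, tp = nrow(pairs),
                 fp = np - nrow(pairs), missed = nt - nrow(pairs)),
            class = "match_result")
}

#' Object-level detection metrics
#'
#' Precision is the fraction of detected objects that are true eggs,
#' recall the fraction of true eggs that are detected, and the F1 score
#' their harmonic mean.
#'
#' @param m A [match_boxes()] result.
#' @return An `object_metrics` list with `precision`, `recall`, `f1`
#'   (each in `[0, 1]`, or `NA` when undefined).
#' @export
object_metrics <- function(m) {
  stopifnot(inherits(m, "match_result"))
  n_pred <- m$tp + m$fp
  n_truth <- m$tp + m$missed
  if (n_pred == 0L && n_truth == 0L) {
    warning("no truths and no predictions: metrics undefined")
    return(structure(list(precision = NA_real_, recall = NA_real_,
                          f1 = NA_real_), class = "object_metrics"))
  }
  precision <- if (n_pred == 0L) NA_real_ else m$tp / n_pred
  recall <- if (n_truth == 0L) NA_real_ else m$tp / n_truth
  f1 <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "object_metrics")
}

#' Image-level counting metrics
#'
#' `counting_error` is the signed relative difference `(TC - AC) / TC`
#' between the true count TC and automatic count AC; `counting_accuracy`
#' is `1 - |TC - AC| / TC`, the agreement form in which a perfect count
#' scores 1; `miss_rate` is the fraction of true eggs with no matched
#' detection. Both error forms are reported because the relative
#' difference alone conflates over- and under-counting with accuracy.
#'
#' @param TC True (manual) count, positive.
#' @param AC Automatic count, non-negative.
#' @param missed Number of missed detections, `<= TC`.
#' @return An `image_metrics` list with `counting_error`,
#'   `counting_accuracy`, `miss_rate`, `TC`, `AC`.
#' @export
image_metrics <- function(TC, AC, missed = 0L) {
  if (TC == 0L) {
    warning("TC = 0: image-level metrics undefined; image should be excluded")
    return(structure(list(counting_error = NA_real_,
                          counting_accuracy = NA_real_,
                          miss_rate = NA_real_, TC = 0L, AC = AC),
                     class = "image_metrics"))
  }
  stopifnot(TC >= 1, AC >= 0, missed >= 0, missed <= TC)
  structure(list(
    counting_error = (TC - AC) / TC,
    counting_accuracy = 1 - abs(TC - AC) / TC,
    miss_rate = missed / TC,
    TC = TC, AC = AC
  ), class = "image_metrics")
}

#' Coefficient of determination between true and predicted counts
#'
#' By default the squared Pearson correlation of the two count vectors,
#' the convention for predicted-vs-true scatter plots; `method =
#' "identity"` instead scores agreement with the identity line
#' (`1 - SS_res / SS_tot`, which can be negative).
#'
#' @param true_counts,predicted_counts Equal-length numeric vectors
#'   (length >= 2).
#' @param method `"pearson"` (default) or `"identity"`.
#' @return A single numeric value (`NA` with a warning if the true counts
#'   are constant).
#' @export
r_squared <- function(true_counts, predicted_counts,
                      method = c("pearson", "identity")) {
  method <- match.arg(method)
  stopifnot(length(true_counts) == length(predicted_counts),
            length(true_counts) >= 2)
  if (stats::var(true_counts) == 0 ||
      (method == "pearson" && stats::var(predicted_counts) == 0)) {
    warning("constant count vector: r-squared undefined")
    return(NA_real_)
  }
  if (method == "pearson") {
    stats::cor(true_counts, predicted_counts)^2
  } else {
    1 - sum((predicted_counts - true_counts)^2) /
      sum((true_counts - mean(true_counts))^2)
  }
}

#' Confidence-threshold sweep
#'
#' Re-applies the confidence filter to retained raw (unthresholded)
#' detections at each grid value of tau, re-matches against ground truth,
#' and aggregates per-image metrics by their unweighted mean. The default
#' grid 0.3 to 0.7 in steps of 0.05 has 9 rows.
#'
#' @param detections A list of box tables (with confidences), one per
#'   image, before confidence thresholding.
#' @param truths A list of ground-truth box tables, parallel to
#'   `detections`.
#' @param tau_min,tau_max,step Sweep grid.
#' @param match_iou IoU threshold used for matching.
#' @return A data.frame with one row per tau: `tau`, `mean_f1`,
#'   `mean_miss_rate`, `mean_counting_accuracy`; the attribute
#'   `"best_tau"` holds the tau maximizing mean F1 (ties broken toward
#'   the smaller tau).
#' @export
threshold_sweep <- function(detections, truths, tau_min = 0.3,
                            tau_max = 0.7, step = 0.05, match_iou = 0.5) {
  stopifnot(is.list(detections), is.list(truths),
            length(detections) == length(truths))
  if (!length(detections)) stop("empty test set")
  taus <- seq(tau_min, tau_max, by = step)
  rows <- lapply(taus, function(tau) {
    per_image <- lapply(seq_along(detections), function(i) {
      pred <- filter_confidence(detections[[i]], tau)
      m <- match_boxes(truths[[i]], pred, match_iou)
      om <- suppressWarnings(object_metrics(m))
      im <- suppressWarnings(
        image_metrics(nrow(truths[[i]]), nrow(pred), m$missed))
      c(f1 = om$f1, miss_rate = im$miss_rate,
        counting_accuracy = im$counting_accuracy)
    })
    v <- do.call(rbind, per_image)
    data.frame(tau = tau,
               mean_f1 = mean(v[, "f1"], na.rm = TRUE),
               mean_miss_rate = mean(v[, "miss_rate"], na.rm = TRUE),
               mean_counting_accuracy = mean(v[, "counting_accuracy"],
                                             na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  best <- out$tau[which.max(out$mean_f1)]
  attr(out, "best_tau") <- best
  out
}
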