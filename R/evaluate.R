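#' Open-set confusion counts
#'
#' Tallies acceptance decisions under the open-set convention: a decision
#' is *positive* when the query is accepted as authorized. TP = authorized
#' query accepted (identity correctness is tracked separately as
#' \code{tp_correct_id}), FN = authorized query rejected, FP = unauthorized
#' query accepted, TN = unauthorized query rejected.
#'
#' @param truth true subject labels; \code{NA} or \code{"unknown"} marks an
#'   unauthorized query.
#' @param predicted predicted labels; \code{NA} or \code{"unknown"} marks a
#'   rejection.
#' @return object of class \code{confusion_counts}.
#' @export
confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  unk <- function(x) is.na(x) | x == "unknown"
  authorized <- !unk(truth)
  accepted <- !unk(predicted)
  tp <- sum(authorized & accepted)
  correct <- authorized & accepted & !unk(predicted) &
    as.character(truth) == as.character(predicted)
  structure(list(
    tp = tp,
    fp = sum(!authorized & accepted),
    fn = sum(authorized & !accepted),
    tn = sum(!authorized & !accepted),
    tp_correct_id = sum(correct, na.rm = TRUE),
    n = length(truth)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d (correct id %d), FP %d, FN %d, TN %d (n = %d)\n",
              x$tp, x$tp_correct_id, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' False rejection rate, FN / (FN + TP)
#' @param c a \code{confusion_counts}.
#' @return FRR in [0, 1]; \code{NA} with a warning when no authorized
#'   attempts exist (undefined, never silently 0).
#' @export
frr <- function(c) {
  if (c$fn + c$tp == 0) {
    warning("FRR undefined: no authorized attempts (FN + TP = 0)")
    return(NA_real_)
  }
  c$fn / (c$fn + c$tp)
}

#' False acceptance rate, FP / (FP + TN)
#' @param c a \code{confusion_counts}.
#' @return FAR in [0, 1]; \code{NA} with a warning when no unauthorized
#'   attempts exist.
#' @export
far <- function(c) {
  if (c$fp + c$tn == 0) {
    warning("FAR undefined: no unauthorized attempts (FP + TN = 0)")
    return(NA_real_)
  }
  c$fp / (c$fp + c$tn)
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = harmonic mean of precision and recall.
#' Undefined ratios (zero denominators) are returned as \code{NA} and
#' listed in \code{undefined}.
#'
#' @param c a \code{confusion_counts}.
#' @return list with \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{undefined}.
#' @export
classification_metrics <- function(c) {
  und <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { und <<- c(und, what); return(NA_real_) }
    num / den
  }
  acc <- ratio(c$tp + c$tn, c$tp + c$fp + c$fn + c$tn, "accuracy")
  prec <- ratio(c$tp, c$tp + c$fp, "precision")
  rec <- ratio(c$tp, c$tp + c$fn, "recall")
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
    und <- c(und, "f1"); NA_real_
  } else 2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       undefined = und)
}

#' F1 score from precision and recall
#'
#' Harmonic mean \code{2 * p * r / (p + r)}; accepts either proportions or
#' percentages (the result is on the same scale).
#'
#' @param precision,recall non-negative scalars on a common scale.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) {
    warning("F1 undefined: precision + recall = 0")
    return(NA_real_)
  }
  2 * precision * recall / (precision + recall)
}

#' Macro-averaged multiclass metrics
#'
#' One-vs-rest confusion counts per class, macro-averaged accuracy,
#' precision, recall and F1, for closed-set classification.
#'
#' @param truth,predicted label vectors of equal length.
#' @return list with overall \code{accuracy} (fraction of exact matches),
#'   macro \code{precision}, \code{recall}, \code{f1}, and the per-class
#'   table.
#' @export
macro_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(truth))
  per <- lapply(classes, function(k) {
    tp <- sum(truth == k & predicted == k)
    fp <- sum(truth != k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    data.frame(class = k, tp = tp, fp = fp, fn = fn,
               precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(accuracy = mean(truth == predicted),
       precision = mean(per$precision, na.rm = TRUE),
       recall = mean(per$recall, na.rm = TRUE),
       f1 = mean(per$f1, na.rm = TRUE),
       per_class = per)
}

# #{v < t} for each t, v sorted ascending
count_below <- function(v_sorted, t) findInterval(t, v_sorted, left.open = TRUE)

#' Sweep the acceptance threshold over genuine and impostor scores
#'
#' For every threshold t: FAR(t) = fraction of impostor scores >= t,
#' FRR(t) = fraction of genuine scores < t (accept iff score >= threshold,
#' as in \code{\link{identify}}). The equal error rate is the common value
#' of the two curves linearly interpolated between the adjacent grid
#' thresholds where FAR - FRR changes sign; the default grid is the sorted
#' unique scores plus an upper sentinel, which makes the crossing always
#' bracketed. Accuracy-vs-threshold curves for the known cohort
#' (acceptance, optionally requiring correct identity via
#' \code{genuine_correct}), the unknown cohort (rejection), and overall are
#' included.
#'
#' @param genuine scores of authorized queries (non-empty).
#' @param impostor scores of unauthorized queries (non-empty).
#' @param grid optional threshold grid (ascending); default = sorted unique
#'   scores.
#' @param genuine_correct optional logical vector along \code{genuine}:
#'   whether the best-matching identity was correct.
#' @return object of class \code{threshold_sweep}: thresholds, far_curve,
#'   frr_curve, acc_known, acc_unknown, acc_overall, \code{eer},
#'   \code{eer_threshold}.
#' @export
sweep_thresholds <- function(genuine, impostor, grid = NULL,
                             genuine_correct = NULL) {
  if (length(genuine) == 0 || length(impostor) == 0)
    stop("both score sets must be non-empty")
  gs <- sort(genuine); is <- sort(impostor)
  if (is.null(grid)) {
    grid <- sort(unique(c(gs, is)))
    grid <- c(grid, grid[length(grid)] + 1)  # sentinel: FAR 0, FRR 1
  } else grid <- sort(grid)
  ng <- length(gs); ni <- length(is)
  far_c <- (ni - count_below(is, grid)) / ni
  frr_c <- count_below(gs, grid) / ng

  acc_known <- if (is.null(genuine_correct)) 1 - frr_c else {
    stopifnot(length(genuine_correct) == length(genuine))
    vapply(grid, function(t) mean(genuine >= t & genuine_correct), 0)
  }
  acc_unknown <- count_below(is, grid) / ni
  acc_overall <- (ng * acc_known + ni * acc_unknown) / (ng + ni)

  d <- far_c - frr_c
  k <- which(d[-length(d)] > 0 & d[-1] <= 0)
  if (length(k) > 0) {
    k <- k[1]
    lam <- d[k] / (d[k] - d[k + 1])
    eer <- far_c[k] + lam * (far_c[k + 1] - far_c[k])
    eer_thr <- grid[k] + lam * (grid[k + 1] - grid[k])
  } else {
    j <- which.min(abs(d))
    eer <- (far_c[j] + frr_c[j]) / 2
    eer_thr <- grid[j]
  }
  structure(list(thresholds = grid, far_curve = far_c, frr_curve = frr_c,
                 acc_known = acc_known, acc_unknown = acc_unknown,
                 acc_overall = acc_overall,
                 eer = eer, eer_threshold = eer_thr,
                 n_genuine = ng, n_impostor = ni),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf(
    "Threshold sweep over %d thresholds (%d genuine, %d impostor scores)\n  EER %.4f at threshold %.4f\n",
    length(x$thresholds), x$n_genuine, x$n_impostor, x$eer,
    x$eer_threshold))
  invisible(x)
}

#' @export
plot.threshold_sweep <- function(x, ...) {
  plot(x$thresholds, x$far_curve, type = "l", ylim = c(0, 1),
       xlab = "threshold", ylab = "rate", main = "FAR / FRR", ...)
  graphics::lines(x$thresholds, x$frr_curve, lty = 2)
  graphics::abline(v = x$eer_threshold, h = x$eer, col = "grey70")
  graphics::legend("right", c("FAR", "FRR"), lty = 1:2, bty = "n")
  invisible(x)
}

#' FAR/FRR and accuracies at one operating threshold
#'
#' @inheritParams sweep_thresholds
#' @param threshold operating threshold.
#' @return list with far, frr, acc_known, acc_known_accept (acceptance
#'   only), acc_unknown, acc_overall.
#' @export
threshold_metrics <- function(genuine, impostor, threshold,
                              genuine_correct = NULL) {
  acc_gen <- mean(genuine >= threshold)
  acc_known <- if (is.null(genuine_correct)) acc_gen
               else mean(genuine >= threshold & genuine_correct)
  acc_unknown <- mean(impostor < threshold)
  ng <- length(genuine); ni <- length(impostor)
  list(far = mean(impostor >= threshold),
       frr = mean(genuine < threshold),
       acc_known = acc_known,
       acc_known_accept = acc_gen,
       acc_unknown = acc_unknown,
       acc_overall = (ng * acc_known + ni * acc_unknown) / (ng + ni))
}

#' Empirical ROC curve
#'
#' Acceptance-rate pairs (FPR, TPR) as the threshold passes every unique
#' score, from (0, 0) to (1, 1); tied genuine/impostor scores move the
#' curve diagonally.
#'
#' @inheritParams sweep_thresholds
#' @return data.frame with columns threshold, fpr, tpr.
#' @export
roc_curve <- function(genuine, impostor) {
  if (length(genuine) == 0 || length(impostor) == 0)
    stop("both score sets must be non-empty")
  th <- sort(unique(c(genuine, impostor)), decreasing = TRUE)
  gs <- sort(genuine); is <- sort(impostor)
  tpr <- (length(gs) - count_below(gs, th)) / length(gs)
  fpr <- (length(is) - count_below(is, th)) / length(is)
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of the empirical ROC; equals the probability that a
#' random genuine score exceeds a random impostor score, ties counting one
#' half.
#'
#' @inheritParams sweep_thresholds
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(genuine, impostor) {
  rc <- roc_curve(genuine, impostor)
  sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
}

#' Misclassification attribution report
#'
#' Aggregates closed-set identification errors by (actual, predicted)
#' subject pair and annotates each pair with the attributes the two
#' subjects share: \code{"Shoe Size"} when their shoe sizes are equal and
#' \code{"Weight"} when their weights differ by at most
#' \code{weight_tolerance_kg}.
#'
#' @param decisions data.frame with columns \code{true} and \code{predicted}
#'   (subject ids; rejections are ignored).
#' @param subjects data.frame with columns \code{subject_id},
#'   \code{weight_kg}, \code{shoe_size_us}.
#' @param weight_tolerance_kg similarity tolerance on weight (default 5).
#' @return data.frame sorted by descending count with columns count,
#'   actual_id, predicted_id, actual_weight, predicted_weight,
#'   actual_shoe_size, predicted_shoe_size, common_points.
#' @export
misclassification_report <- function(decisions, subjects,
                                     weight_tolerance_kg = 5) {
  stopifnot(all(c("true", "predicted") %in% names(decisions)),
            all(c("subject_id", "weight_kg", "shoe_size_us") %in%
                  names(subjects)))
  err <- decisions[!is.na(decisions$predicted) &
                     decisions$predicted != "unknown" &
                     decisions$true != decisions$predicted, , drop = FALSE]
  if (nrow(err) == 0)
    return(data.frame(count = integer(0), actual_id = integer(0),
                      predicted_id = integer(0), actual_weight = numeric(0),
                      predicted_weight = numeric(0),
                      actual_shoe_size = numeric(0),
                      predicted_shoe_size = numeric(0),
                      common_points = character(0)))
  agg <- stats::aggregate(list(count = rep(1L, nrow(err))),
                          by = list(actual_id = err$true,
                                    predicted_id = err$predicted),
                          FUN = sum)
  look <- function(id, col) subjects[[col]][match(id, subjects$subject_id)]
  agg$actual_weight <- look(agg$actual_id, "weight_kg")
  agg$predicted_weight <- look(agg$predicted_id, "weight_kg")
  agg$actual_shoe_size <- look(agg$actual_id, "shoe_size_us")
  agg$predicted_shoe_size <- look(agg$predicted_id, "shoe_size_us")
  agg$common_points <- vapply(seq_len(nrow(agg)), function(i) {
    pts <- character(0)
    if (isTRUE(agg$actual_shoe_size[i] == agg$predicted_shoe_size[i]))
      pts <- c(pts, "Shoe Size")
    if (isTRUE(abs(agg$actual_weight[i] - agg$predicted_weight[i]) <=
               weight_tolerance_kg))
      pts <- c(pts, "Weight")
    paste(pts, collapse = ", ")
  }, "")
  agg <- agg[order(-agg$count, agg$actual_id), ]
  rownames(agg) <- NULL
  agg[, c("count", "actual_id", "predicted_id", "actual_weight",
          "predicted_weight", "actual_shoe_size", "predicted_shoe_size",
          "common_points")]
}
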