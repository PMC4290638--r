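#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic:
#' the probability that a random positive outscores a random negative,
#' with tied scores contributing half credit.  O(n log n) via midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1) with at least one of each class.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' ROC curve over all score thresholds
#'
#' Operating points `(1 - specificity, sensitivity)` for every distinct
#' score threshold, anchored at (0,0) and (1,1).  Tied scores are collapsed
#' into a single step, so the trapezoidal integral of the curve equals the
#' half-credit Mann-Whitney AUC exactly.
#'
#' @inheritParams auc_mw
#' @return an object of class `roc_curve`: data.frame `points` with columns
#'   `fpr`, `tpr`, and the scalar `auc`.
#' @export
compute_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("ROC needs both classes present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # collapse tie groups to single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve>", nrow(x$points), "points, AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}
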