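# Average precision (step-wise precision-recall integration) and its mean
# over targets.

#' Average precision
#'
#' Step-wise integral of the precision-recall curve:
#' `AP = sum_k (R_k - R_{k-1}) P_k` over the list ranked by descending score.
#' Ties keep the stable sort order of the input.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels of the same length; at least one positive.
#' @return AP in `[0, 1]`.
#' @export
#' @examples
#' average_precision(c(0.2, 0.9), c(1, 0))  # 0.5
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  if (npos == 0) stop("average precision undefined without positives", call. = FALSE)
  ord <- order(-scores)   # radix sort: stable for ties
  l <- labels[ord]
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  sum(prec[l == 1]) / npos
}

#' Mean average precision
#'
#' Arithmetic mean of per-target average precisions.
#'
#' @param aps Numeric vector of APs, or a list of evaluation reports carrying
#'   an `ap` element.
#' @return mAP.
#' @export
mean_average_precision <- function(aps) {
  if (is.list(aps)) aps <- vapply(aps, function(r) r$ap, numeric(1))
  if (length(aps) == 0) stop("no reports", call. = FALSE)
  mean(aps)
}
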