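#' Confusion counts
#'
#' @param TP,FP,TN,FN Nonnegative integers.
#' @return Named integer vector of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0L, FP = 0L, TN = 0L, FN = 0L) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0)) stop("confusion counts must be nonnegative", call. = FALSE)
  structure(as.integer(v), names = names(v), class = "confusion_counts")
}

#' Precision, recall and accuracy from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, each as a percentage reported to
#' two decimals. A zero denominator yields `NA` (the undefined-metric
#' marker), never zero and never an error.
#'
#' @param counts A [confusion_counts()] (or named vector with TP/FP/TN/FN).
#' @return Named numeric vector `precision`, `recall`, `accuracy` (percent,
#'   2 decimals; `NA` where undefined).
#' @export
compute_metrics <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 2)
  c(precision = pct(TP, TP + FP),
    recall = pct(TP, TP + FN),
    accuracy = pct(TP + TN, TP + FP + TN + FN))
}

#' Column-wise mean of per-position metric rows
#'
#' Unweighted arithmetic mean of each metric column over camera positions,
#' rounded to two decimals as reported.
#'
#' @param rows Data frame (or matrix) whose columns are metrics and whose
#'   rows are positions.
#' @param digits Decimals to round to.
#' @return Named numeric vector of column means.
#' @export
aggregate_positions <- function(rows, digits = 2) {
  rows <- as.data.frame(rows)
  num <- vapply(rows, is.numeric, logical(1))
  vapply(rows[num], function(col) round(mean(col), digits), numeric(1))
}

#' Recover integer confusion counts from printed percentages
#'
#' Exhaustively searches `TP in 0..n_pos`, `FP in 0..n_neg` for the counts
#' whose recall/precision/accuracy round to the printed row, under a
#' balanced design with `n_pos` positive and `n_neg` negative samples.
#'
#' @param recall,precision,accuracy Printed percentages (2 decimals).
#' @param n_pos,n_neg Positive and negative sample counts.
#' @return A [confusion_counts()]; errors if no or multiple solutions.
#' @export
recover_counts <- function(recall, precision, accuracy,
                           n_pos = 80L, n_neg = 80L) {
  hits <- list()
  for (TP in 0:n_pos) {
    FN <- n_pos - TP
    for (FP in 0:n_neg) {
      TN <- n_neg - FP
      m <- compute_metrics(c(TP = TP, FP = FP, TN = TN, FN = FN))
      if (isTRUE(all.equal(m[["recall"]], recall)) &&
          isTRUE(all.equal(m[["precision"]], precision)) &&
          isTRUE(all.equal(m[["accuracy"]], accuracy))) {
        hits[[length(hits) + 1L]] <- confusion_counts(TP, FP, TN, FN)
      }
    }
  }
  if (length(hits) == 0L) stop("no integer counts reproduce the printed row",
                               call. = FALSE)
  if (length(hits) > 1L) stop("printed row is ambiguous: multiple count sets",
                              call. = FALSE)
  hits[[1]]
}
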