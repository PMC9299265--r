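# Evaluation metrics ---------------------------------------------------------

#' Confusion counts for binary +1/-1 predictions
#'
#' Malignant is the positive class (+1): TP = malignant predicted malignant,
#' TN = benign predicted benign, FP = benign predicted malignant, FN =
#' malignant predicted benign.
#'
#' @param pred Predicted +1/-1 labels.
#' @param obs Observed +1/-1 labels, same length.
#' @return List of class `gf_confusion` with integer `TP`, `TN`, `FP`, `FN`.
#' @export
#' @examples
#' gf_confusion(c(1, 1, -1), c(1, -1, 1))  # TP 1, FP 1, FN 1, TN 0
gf_confusion <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 1L)
    gf_stop("gf_input_error", "pred (%d) and obs (%d) must match, length >= 1",
            length(pred), length(obs))
  structure(list(
    TP = sum(pred > 0 & obs > 0),
    TN = sum(pred < 0 & obs < 0),
    FP = sum(pred > 0 & obs < 0),
    FN = sum(pred < 0 & obs > 0)
  ), class = "gf_confusion")
}

#' @export
print.gf_confusion <- function(x, ...) {
  cat(sprintf("          obs +1  obs -1\npred +1   %6d  %6d\npred -1   %6d  %6d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Classification accuracy as a percentage
#'
#' `(TP + TN) / (TP + TN + FP + FN) * 100`.
#'
#' @param x A `gf_confusion`, or predicted labels (with `obs`).
#' @param obs Observed labels when `x` is a prediction vector.
#' @return Accuracy in percent.
#' @export
gf_accuracy <- function(x, obs = NULL) {
  if (!inherits(x, "gf_confusion")) x <- gf_confusion(x, obs)
  total <- x$TP + x$TN + x$FP + x$FN
  if (total == 0) gf_stop("gf_input_error", "no evaluated samples")
  (x$TP + x$TN) / total * 100
}

#' Mean squared error between predicted and observed classes
#'
#' `sum((pred - obs)^2) / n`, applied to the +1/-1 class codes (not to
#' probabilities): each misclassification contributes `(2)^2 = 4`, so in
#' this coding MSE equals four times the error rate.
#'
#' @param pred Predicted +1/-1 classes.
#' @param obs Observed +1/-1 classes.
#' @return Non-negative real.
#' @export
gf_mse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 1L)
    gf_stop("gf_input_error", "pred and obs must have equal length >= 1")
  mean((pred - obs)^2)
}

#' Area under the ROC curve (rank formulation)
#'
#' The Mann-Whitney form: the probability that a uniformly chosen positive
#' sample outranks a uniformly chosen negative one, ties counting one half.
#' Exact under ties and invariant to strictly monotone score transforms.
#'
#' @param scores Real decision values (larger = more positive).
#' @param obs Observed +1/-1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
gf_auc <- function(scores, obs) {
  if (length(scores) != length(obs))
    gf_stop("gf_input_error", "scores and obs must have equal length")
  np <- sum(obs > 0); nn <- sum(obs < 0)
  if (np == 0 || nn == 0)
    gf_stop("gf_input_error", "both classes must be present for AUC")
  r <- rank(scores)
  (sum(r[obs > 0]) - np * (np + 1) / 2) / (np * nn)
}

#' Full metrics report
#'
#' @param pred Predicted +1/-1 labels.
#' @param obs Observed +1/-1 labels.
#' @param scores Optional decision scores for AUC.
#' @return List of class `gf_metrics`: `accuracy` (percent), `mse`, `auc`
#'   (or `NA` without scores) and the `confusion` counts.
#' @export
gf_metrics <- function(pred, obs, scores = NULL) {
  conf <- gf_confusion(pred, obs)
  structure(list(
    accuracy = gf_accuracy(conf),
    mse = gf_mse(pred, obs),
    auc = if (is.null(scores)) NA_real_ else gf_auc(scores, obs),
    confusion = conf
  ), class = "gf_metrics")
}

#' @export
print.gf_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %6.2f %%\nMSE:      %6.4f\nAUC:      %s\n",
              x$accuracy, x$mse,
              if (is.na(x$auc)) "NA" else sprintf("%6.4f", x$auc)))
  print(x$confusion)
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param m A `gf_metrics`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
gf_write_metrics <- function(m, path) {
  jsonlite::write_json(list(
    accuracy_percent = m$accuracy, mse = m$mse, auc = m$auc,
    confusion = list(TP = m$confusion$TP, TN = m$confusion$TN,
                     FP = m$confusion$FP, FN = m$confusion$FN)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
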