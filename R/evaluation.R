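# Metric suite: ordinal 7-grade metrics, the healthy/lame binary protocol,
# and inter-rater agreement.

check_lengths <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty input")
}

#' Relaxed (plus-or-minus one grade) accuracy
#'
#' Fraction of predictions within one grade of the truth on the ordinal
#' scale: `|y_pred - y_true| <= 1`. Ordinal predictions such as the merged
#' 4.5 leaf are handled naturally (`|4.5 - 4| = 0.5` counts as correct,
#' `|4.5 - 3| = 1.5` as wrong). Always at least the exact-match accuracy.
#'
#' @param y_true,y_pred numeric grade vectors of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
relaxed_accuracy <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred)
  mean(abs(y_pred - y_true) <= 1)
}

#' Balanced accuracy
#'
#' Unweighted mean of per-true-class recall; robust to class imbalance.
#'
#' @param y_true,y_pred label vectors of equal length; every true class must
#'   have at least one row.
#' @return Fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred)
  cls <- unique(y_true)
  mean(vapply(cls, function(c) mean(y_pred[y_true == c] == c), 0))
}

#' Mean squared error on the ordinal grade scale
#'
#' @param y_true,y_pred numeric grade vectors of equal length.
#' @return Mean of squared ordinal differences (>= 0).
#' @export
grade_mse <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred)
  mean((y_pred - y_true)^2)
}

#' Map 7-grade scores to the binary healthy/lame protocol
#'
#' Grades 1-3 are healthy, 6-7 lame; the borderline grades 4-5 suffer the
#' lowest inter-observer agreement and are excluded from binary evaluation.
#'
#' @param grades numeric vector of grades in 1..7 (the merged 4.5 ordinal is
#'   accepted and excluded).
#' @return List with `label` (factor `healthy`/`lame`, `NA` for excluded)
#'   and `excluded` (logical mask).
#' @export
binary_map <- function(grades) {
  if (any(is.na(grades)) || any(grades < 1 | grades > 7))
    stop("grades must be in 1..7")
  label <- ifelse(grades <= 3, "healthy", ifelse(grades >= 6, "lame", NA))
  list(label = factor(label, levels = c("healthy", "lame")),
       excluded = is.na(label))
}

#' Cohen's kappa (unweighted)
#'
#' Chance-corrected agreement between two raters over the same items:
#' `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the product
#' of the raters' marginal distributions. When both raters are constant and
#' identical (`p_e = 1`) the conventional value 1 is returned.
#'
#' @param a,b rating vectors of equal length over a common category set.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  check_lengths(a, b)
  cats <- sort(unique(c(a, b)))
  fa <- factor(a, levels = cats); fb <- factor(b, levels = cats)
  po <- mean(a == b)
  pe <- sum(prop.table(table(fa)) * prop.table(table(fb)))
  if (pe >= 1) {
    message("cohens_kappa: both raters constant and equal; returning 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}

#' Assemble the evaluation report for a prediction set
#'
#' For the 7-grade task: balanced accuracy, plain (exact) accuracy, relaxed
#' accuracy, MSE, and class-frequency-weighted recall and precision (a
#' predicted class with no rows contributes precision 0). For the binary
#' task: grades 4-5 are excluded per protocol, then plain and balanced
#' accuracy and positive-class (lame) recall and precision are reported.
#'
#' @param y_true true grades in 1..7.
#' @param y_pred predicted grades (7-grade task: ordinals, merged 4.5
#'   allowed; binary task: grades or `"healthy"`/`"lame"` labels).
#' @param task `"grade7"` or `"binary"`.
#' @return A list of class `evaluation_report`.
#' @export
evaluate_predictions <- function(y_true, y_pred, task = c("grade7", "binary")) {
  task <- match.arg(task)
  check_lengths(y_true, y_pred)
  if (task == "grade7") {
    cls <- sort(unique(y_true))
    wts <- as.numeric(table(factor(y_true, levels = cls))) / length(y_true)
    recall_c <- vapply(cls, function(c) mean(y_pred[y_true == c] == c), 0)
    prec_c <- vapply(cls, function(c) {
      p <- y_true[y_pred == c]
      if (!length(p)) 0 else mean(p == c)  # zero-division -> 0
    }, 0)
    rep <- list(
      task = "grade7",
      accuracy = mean(y_pred == y_true),
      balanced_accuracy = balanced_accuracy(y_true, y_pred),
      relaxed_accuracy = relaxed_accuracy(y_true, y_pred),
      mse = grade_mse(y_true, y_pred),
      recall = sum(wts * recall_c),
      precision = sum(wts * prec_c),
      n_evaluated = length(y_true), n_excluded = 0L
    )
  } else {
    bt <- if (is.numeric(y_true)) binary_map(y_true)
          else list(label = factor(y_true, levels = c("healthy", "lame")),
                    excluded = rep(FALSE, length(y_true)))
    bp <- if (is.numeric(y_pred)) binary_map(y_pred)$label
          else factor(y_pred, levels = c("healthy", "lame"))
    keep <- !bt$excluded & !is.na(bp)
    yt <- bt$label[keep]; yp <- bp[keep]
    if (!length(yt)) stop("no rows left after binary exclusion")
    tp <- sum(yt == "lame" & yp == "lame")
    rep <- list(
      task = "binary",
      accuracy = mean(yp == yt),
      balanced_accuracy = balanced_accuracy(as.character(yt), as.character(yp)),
      recall = if (sum(yt == "lame")) tp / sum(yt == "lame") else 0,
      precision = if (sum(yp == "lame")) tp / sum(yp == "lame") else 0,
      n_evaluated = length(yt),
      n_excluded = sum(bt$excluded)
    )
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s task), n = %d evaluated, %d excluded\n",
              x$task, x$n_evaluated, x$n_excluded))
  for (k in setdiff(names(x), c("task", "n_evaluated", "n_excluded")))
    cat(sprintf("  %-18s %.4f\n", k, x[[k]]))
  invisible(x)
}
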