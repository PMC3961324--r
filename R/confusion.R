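#' Confusion matrix at a single classification threshold
#'
#' A data point is predicted foreground iff its score is greater than or
#' equal to the threshold `t`.  The entries of the confusion matrix are
#' accumulated weights: `tp` is the foreground weight of predicted-foreground
#' points, `fp` their background weight, `fn` and `tn` the complementary
#' sums.  For unweighted data these reduce to the usual counts.
#'
#' @param sample a `wpr_sample`, see [weighted_sample()].
#' @param t finite numeric classification threshold.
#' @return An object of class `wpr_confusion`: list with `tp`, `fp`, `fn`,
#'   `tn`, `threshold`, plus derived `precision`, `recall`, `tpr`, `fpr`
#'   (the undefined 0/0 cases are `NaN`).
#' @examples
#' x <- weighted_sample(c(2.54, 2.37, 1.56, 1.35, 0.06, -1.08),
#'                      c(0.90, 0.92, 0.22, 0.07, 0.67, 0.09),
#'                      c(0.10, 0.08, 0.78, 0.93, 0.33, 0.91))
#' confusion_at_threshold(x, 1.5)   # tp 2.04, fp 0.96, fn 0.83, tn 2.17
#' @export
confusion_at_threshold <- function(sample, t) {
  stopifnot(inherits(sample, "wpr_sample"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
    stop_input("threshold must be a single finite number")
  pred_fg <- sample$scores >= t
  tp <- sum(sample$w_fg[pred_fg])
  fp <- sum(sample$w_bg[pred_fg])
  fn <- sum(sample$w_fg[!pred_fg])
  tn <- sum(sample$w_bg[!pred_fg])
  new_confusion(tp, fp, fn, tn, t)
}

new_confusion <- function(tp, fp, fn, tn, threshold) {
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, threshold = threshold,
         precision = tp / (tp + fp), recall = tp / (tp + fn),
         tpr = tp / (tp + fn), fpr = fp / (fp + tn)),
    class = "wpr_confusion"
  )
}

#' @export
print.wpr_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix at threshold %g\n", x$threshold))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("fg", "bg"),
                              real = c("fg", "bg")))
  print(m)
  cat(sprintf("precision %.4g  recall %.4g  fpr %.4g\n",
              x$precision, x$recall, x$fpr))
  invisible(x)
}

#' Supporting points: the threshold sweep of confusion matrices
#'
#' Sweeping the classification threshold over all distinct score values
#' produces a series of confusion matrices -- the supporting points of the
#' PR and ROC curves.  Tied scores collapse into a single threshold step;
#' an additional sentinel threshold above the maximum score contributes the
#' `tp = fp = 0` anchor.  The rows are ordered by strictly decreasing
#' threshold, so `tp` and `fp` are non-decreasing down the table.
#'
#' All entries are computed in one pass from cumulative weight sums over
#' the score-sorted points, so the result is invariant under permutation of
#' the input rows.
#'
#' @param sample a `wpr_sample` with positive total foreground weight.
#' @return A `data.frame` of class `wpr_supporting_points` with columns
#'   `threshold`, `tp`, `fp`, `fn`, `tn` and attributes `r_fg`,
#'   `w_bg_total`, `unweighted`.
#' @seealso [curve_points()], [auc_pr_continuous()]
#' @export
supporting_points <- function(sample) {
  stopifnot(inherits(sample, "wpr_sample"))
  R <- r_fg(sample)
  if (R <= 0)
    stop_input("no foreground mass; recall undefined")
  o <- order(sample$scores, decreasing = TRUE, method = "radix")
  s <- sample$scores[o]
  tp <- cumsum(sample$w_fg[o])
  fp <- cumsum(sample$w_bg[o])
  n <- length(s)
  # last index of each tie group of equal scores (s is sorted)
  last <- which(c(s[-n] != s[-1L], TRUE))
  df <- data.frame(
    threshold = c(Inf, s[last]),
    tp = c(0, tp[last]),
    fp = c(0, fp[last])
  )
  df$fn <- R - df$tp
  df$tn <- sum(sample$w_bg) - df$fp
  structure(df,
            class = c("wpr_supporting_points", "data.frame"),
            r_fg = R,
            w_bg_total = w_bg_total(sample),
            unweighted = is_unweighted(sample))
}

as_supporting_points <- function(x) {
  if (inherits(x, "wpr_supporting_points")) return(x)
  if (inherits(x, "wpr_sample")) return(supporting_points(x))
  stop_input("expected a wpr_sample or wpr_supporting_points object")
}

#' Curve coordinates from supporting points
#'
#' Converts the supporting confusion matrices into PR coordinates
#' (`recall = tp / r_fg`, `precision = tp / (tp + fp)`) or ROC coordinates
#' (`fpr = fp / w_bg_total`, `tpr = tp / r_fg`).  The `tp = fp = 0` anchor
#' is emitted as (0, 0) for ROC but omitted for PR, where its precision is
#' the undefined ratio 0/0.
#'
#' @param points a `wpr_supporting_points` table (or a `wpr_sample`, which
#'   is swept first).
#' @param kind `"pr"` or `"roc"`.
#' @return A `data.frame` with columns `threshold` and either
#'   `recall`/`precision` or `fpr`/`tpr`.
#' @export
curve_points <- function(points, kind = c("pr", "roc")) {
  kind <- match.arg(kind)
  points <- as_supporting_points(points)
  R <- attr(points, "r_fg")
  B <- attr(points, "w_bg_total")
  if (kind == "roc") {
    if (B <= 0)
      stop_input("no background mass; false positive rate undefined")
    data.frame(threshold = points$threshold,
               fpr = points$fp / B,
               tpr = points$tp / R)
  } else {
    keep <- points$tp + points$fp > 0
    data.frame(threshold = points$threshold[keep],
               recall = points$tp[keep] / R,
               precision = points$tp[keep] / (points$tp[keep] + points$fp[keep]))
  }
}
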