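#' Construct a weighted test sample
#'
#' A weighted sample holds one classification score per data point together
#' with a non-negative foreground weight `w_fg` and background weight `w_bg`.
#' The weights may encode soft class labels (probabilities summing to one),
#' measured signal strengths, or multiplicities; hard-labeled (unweighted)
#' data are the special case where every point has `(w_fg, w_bg)` equal to
#' `(1, 0)` or `(0, 1)`.
#'
#' Points whose two weights are both zero carry no information for any
#' confusion matrix; they are dropped with a warning and counted in the
#' `n_dropped` field.
#'
#' @param scores numeric vector of finite classification scores, one per
#'   data point.  Higher scores mean stronger foreground prediction.
#' @param w_fg,w_bg non-negative numeric vectors of foreground and
#'   background weights, same length as `scores`.
#' @return An object of class `wpr_sample`: a list with fields `scores`,
#'   `w_fg`, `w_bg`, `n`, `n_dropped`.
#' @seealso [unweighted_sample()], [read_sample()], [supporting_points()]
#' @examples
#' x <- weighted_sample(scores = c(2.54, 2.37, 1.56, 1.35, 0.06, -1.08),
#'                      w_fg   = c(0.90, 0.92, 0.22, 0.07, 0.67, 0.09),
#'                      w_bg   = c(0.10, 0.08, 0.78, 0.93, 0.33, 0.91))
#' r_fg(x)       # total foreground weight, 2.87
#' @export
weighted_sample <- function(scores, w_fg, w_bg) {
  scores <- as.numeric(scores)
  w_fg <- as.numeric(w_fg)
  w_bg <- as.numeric(w_bg)
  if (length(scores) < 1L)
    stop_input("a sample needs at least one data point")
  if (length(w_fg) != length(scores) || length(w_bg) != length(scores))
    stop_input("scores, w_fg and w_bg must have equal length")
  bad_score <- which(!is.finite(scores))
  if (length(bad_score))
    stop_input("non-finite score at row ", bad_score[1L])
  bad_w <- which(!is.finite(w_fg) | !is.finite(w_bg) | w_fg < 0 | w_bg < 0)
  if (length(bad_w))
    stop_input("negative or non-finite weight at row ", bad_w[1L])
  zero <- w_fg == 0 & w_bg == 0
  n_dropped <- sum(zero)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d data point(s) with zero total weight",
                    n_dropped), call. = FALSE)
    scores <- scores[!zero]; w_fg <- w_fg[!zero]; w_bg <- w_bg[!zero]
  }
  if (length(scores) == 0L)
    stop_input("empty sample after removing zero-weight points")
  structure(
    list(scores = scores, w_fg = w_fg, w_bg = w_bg,
         n = length(scores), n_dropped = n_dropped),
    class = "wpr_sample"
  )
}

#' Construct an unweighted (hard-labeled) sample
#'
#' Maps binary class labels onto 0/1 weights: foreground points get
#' `(w_fg, w_bg) = (1, 0)`, background points `(0, 1)`.
#'
#' @param scores numeric vector of finite classification scores.
#' @param labels class labels; one of `"fg"`/`"bg"`, `1`/`0`, or a logical
#'   vector (`TRUE` = foreground).
#' @return A `wpr_sample` (see [weighted_sample()]) with unit weights.
#' @examples
#' unweighted_sample(c(3.1, 0.2, -1), labels = c("fg", "bg", "bg"))
#' @export
unweighted_sample <- function(scores, labels) {
  structure_labels <- parse_labels(labels)
  weighted_sample(scores,
                  w_fg = as.numeric(structure_labels),
                  w_bg = as.numeric(!structure_labels))
}

parse_labels <- function(labels) {
  if (is.logical(labels)) {
    if (anyNA(labels)) stop_input("missing class label")
    return(labels)
  }
  lab <- as.character(labels)
  ok_fg <- lab %in% c("fg", "1", "TRUE")
  ok_bg <- lab %in% c("bg", "0", "FALSE")
  if (any(!(ok_fg | ok_bg)))
    stop_input("labels must be in {fg, bg, 1, 0}; offending value: ",
               lab[which(!(ok_fg | ok_bg))[1L]])
  ok_fg
}

#' @export
print.wpr_sample <- function(x, ...) {
  cat(sprintf("Weighted sample: %d data points%s\n", x$n,
              if (is_unweighted(x)) " (unweighted 0/1 special case)" else ""))
  cat(sprintf("  total foreground weight R_fg = %g\n", r_fg(x)))
  cat(sprintf("  total background weight     = %g\n", w_bg_total(x)))
  if (x$n_dropped > 0L)
    cat(sprintf("  (%d zero-weight point(s) dropped on input)\n", x$n_dropped))
  invisible(x)
}

#' Class totals of a weighted sample
#'
#' `r_fg()` is the total foreground weight (the real-valued number of
#' positives), `w_bg_total()` the total background weight, and
#' `class_ratio()` their normalized ratio `r_fg / (r_fg + w_bg_total)` --
#' the precision of the all-foreground prediction and the approximate
#' AUC-PR of a random classifier.
#'
#' @param x a `wpr_sample`.
#' @return A single numeric value.
#' @export
r_fg <- function(x) {
  stopifnot(inherits(x, "wpr_sample"))
  sum(x$w_fg)
}

#' @rdname r_fg
#' @export
w_bg_total <- function(x) {
  stopifnot(inherits(x, "wpr_sample"))
  sum(x$w_bg)
}

#' @rdname r_fg
#' @export
class_ratio <- function(x) {
  r <- r_fg(x)
  r / (r + w_bg_total(x))
}

#' Test whether a sample is unweighted
#'
#' A sample is unweighted when every point has weights in \{0, 1\} and
#' `w_fg + w_bg = 1`, i.e. it is hard-labeled.
#'
#' @param x a `wpr_sample`.
#' @return `TRUE` or `FALSE`.
#' @export
is_unweighted <- function(x) {
  stopifnot(inherits(x, "wpr_sample"))
  all(x$w_fg %in% c(0, 1)) && all(x$w_fg + x$w_bg == 1)
}

#' Hard labels of an unweighted sample
#'
#' @param x an unweighted `wpr_sample`.
#' @return Logical vector, `TRUE` for foreground points.
#' @keywords internal
hard_labels <- function(x) {
  if (!is_unweighted(x))
    stop_input("sample is weighted; hard labels are undefined")
  x$w_fg == 1
}

## input-error condition used throughout; the CLI maps it to exit status 2
stop_input <- function(...) {
  stop(structure(
    class = c("wpr_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
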