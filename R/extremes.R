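#' Attainable extremes of AUC-PR for given weights
#'
#' For a fixed set of per-point weights, the AUC-PR of a classifier depends
#' only on how its scores order the data points.  The maximal AUC-PR is
#' attained exactly when the points are ranked by non-increasing
#' foreground confidence, and the minimal AUC-PR when they are ranked in
#' the reverse order.  The implemented sort key is the foreground
#' confidence ratio `w_fg / (w_fg + w_bg)`, which is monotone-equivalent to
#' `w_fg / w_bg` and remains well-defined for pure-foreground points
#' (`w_bg = 0`).  Points with equal ratio lie on a common
#' constant-precision hyperbola, so their relative order does not affect
#' the area; ties are kept in input order.
#'
#' For unweighted data the maximal ordering separates the classes
#' perfectly, so `max_auc = 1`.  The minimum is always strictly positive:
#' even the worst ordering ends at the common curve point with recall 1 and
#' precision equal to the class ratio.  No closed form exists for the
#' extreme values; they are computed by scoring the extreme orderings and
#' integrating the continuous PR curve.
#'
#' @param sample a `wpr_sample` with positive foreground mass.
#' @return An object of class `wpr_extremes`: list with `max_auc`,
#'   `min_auc`, `max_order`, `min_order` (permutations of point indices,
#'   best-ranked first), and `class_ratio`.
#' @seealso [normalized_auc_pr()], [random_baseline()]
#' @examples
#' x <- weighted_sample(1:4, c(.9, .2, .8, .1), c(.1, .8, .2, .9))
#' auc_pr_extremes(x)
#' @export
auc_pr_extremes <- function(sample) {
  stopifnot(inherits(sample, "wpr_sample"))
  ratio <- sample$w_fg / (sample$w_fg + sample$w_bg)
  max_order <- order(ratio, decreasing = TRUE, method = "radix")
  min_order <- order(ratio, decreasing = FALSE, method = "radix")
  structure(
    list(max_auc = auc_of_order(sample, max_order),
         min_auc = auc_of_order(sample, min_order),
         max_order = max_order,
         min_order = min_order,
         class_ratio = class_ratio(sample)),
    class = "wpr_extremes"
  )
}

## continuous AUC-PR of the classifier ranking the points in `ord`
## (first element of `ord` gets the highest score)
auc_of_order <- function(sample, ord) {
  scores <- numeric(sample$n)
  scores[ord] <- seq(sample$n, 1)
  auc_pr_continuous(weighted_sample(scores, sample$w_fg, sample$w_bg))$auc
}

#' @rdname auc_pr_extremes
#' @export
max_auc_pr <- function(sample) auc_pr_extremes(sample)$max_auc

#' @rdname auc_pr_extremes
#' @export
min_auc_pr <- function(sample) auc_pr_extremes(sample)$min_auc

#' @export
print.wpr_extremes <- function(x, ...) {
  cat(sprintf("AUC-PR extremes: min %.6f, max %.6f (class ratio %.4f)\n",
              x$min_auc, x$max_auc, x$class_ratio))
  invisible(x)
}

#' Normalized AUC-PR
#'
#' Rescales an AUC-PR value by the attainable extremes for the sample's
#' weights: `(auc - min_auc) / (max_auc - min_auc)`, so 0 is the worst and
#' 1 the best possible classifier for those weights.  Values outside
#' `[min_auc, max_auc]` beyond numerical round-off (1e-9) are rejected as
#' inconsistent; round-off overflow is clamped.
#'
#' @param auc an AUC-PR value computed on the same sample.
#' @param extremes a `wpr_extremes` object (or a `wpr_sample`, whose
#'   extremes are then computed).
#' @return A number in \[0, 1\].
#' @export
normalized_auc_pr <- function(auc, extremes) {
  if (inherits(extremes, "wpr_sample")) extremes <- auc_pr_extremes(extremes)
  stopifnot(inherits(extremes, "wpr_extremes"))
  lo <- extremes$min_auc; hi <- extremes$max_auc
  if (hi <= lo)
    stop_input("degenerate sample, normalization undefined")
  if (auc < lo - 1e-9 || auc > hi + 1e-9)
    stop("auc outside [min_auc, max_auc]; extremes from a different sample?")
  min(1, max(0, (auc - lo) / (hi - lo)))
}

#' Monte-Carlo random-classifier baseline
#'
#' Draws `m` independent random score vectors (i.i.d. uniform on (0, 1),
#' so ties occur with probability zero), computes the continuous AUC-PR of
#' each, and summarizes the ensemble.  The median of such an ensemble is
#' approximately the class ratio `r_fg / (r_fg + w_bg_total)`, for weighted
#' as well as unweighted data, which makes the class ratio the natural
#' chance level of AUC-PR.
#'
#' Quartiles use the default convention of linear interpolation between
#' order statistics ([stats::quantile()] type 7), fixed for
#' reproducibility.
#'
#' @param sample a `wpr_sample`.
#' @param m ensemble size (>= 1).
#' @param seed integer seed making the ensemble reproducible.
#' @return An object of class `wpr_baseline`: list with `m`, `aucs`
#'   (length `m`), `median`, `q25`, `q75`, `seed`.
#' @examples
#' x <- unweighted_sample(seq_len(20), rep(c("fg", "bg"), c(4, 16)))
#' random_baseline(x, m = 200, seed = 7)$median   # near 0.2
#' @export
random_baseline <- function(sample, m = 1000L, seed = 1L) {
  stopifnot(inherits(sample, "wpr_sample"))
  if (m < 1L) stop_input("m must be >= 1")
  set.seed(seed)
  aucs <- vapply(seq_len(m), function(i) {
    auc_pr_continuous(weighted_sample(stats::runif(sample$n),
                                      sample$w_fg, sample$w_bg))$auc
  }, numeric(1))
  q <- stats::quantile(aucs, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(m = m, aucs = aucs, median = q[2L],
                 q25 = q[1L], q75 = q[3L], seed = seed),
            class = "wpr_baseline")
}

#' @export
print.wpr_baseline <- function(x, ...) {
  cat(sprintf(
    "Random-classifier baseline (m = %d, seed = %d):\n  median AUC-PR %.4f [q25 %.4f, q75 %.4f]\n",
    x$m, x$seed, x$median, x$q25, x$q75))
  invisible(x)
}
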