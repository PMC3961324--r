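#' Exact area under one PR-curve segment
#'
#' Between two adjacent supporting points `A` and `B` (with
#' `tp_A < tp_B`), linear interpolation of the underlying confusion matrix
#' makes the false positives a linear function of the true positives,
#' `fp(tp) = fp_A + s (tp - tp_A)` with slope `s = (fp_B - fp_A)/(tp_B -
#' tp_A)`.  Written in terms of recall `p = tp / R_fg`, precision along the
#' segment is the hyperbola
#' \deqn{\mathrm{prec}(p) = \frac{p}{a\,p + b}, \quad
#'       a = 1 + s, \quad b = \frac{fp_A - s\,tp_A}{R_{fg}},}
#' and its integral over recall has the closed form (natural logarithm)
#' \deqn{\frac{1}{a}\Big(p_B - p_A -
#'       \frac{b}{a}\big(\ln(a p_B + b) - \ln(a p_A + b)\big)\Big),}
#' reducing to \eqn{(p_B - p_A)/a} in the constant-precision limit
#' \eqn{b = 0}.  Because it only uses ratios of accumulated weights, the
#' formula applies to real-valued (weighted) confusion matrices unchanged.
#'
#' @param B,A confusion matrices (objects with `tp` and `fp` entries, e.g.
#'   from [confusion_at_threshold()]), with `A$tp < B$tp` and
#'   `A$fp <= B$fp`, derived from the same sample.
#' @param r_fg positive total foreground weight of that sample.
#' @return The area contribution, a single non-negative number.
#' @examples
#' # constant precision 1/2 between recall 0.5 and 1:
#' segment_auc(B = list(tp = 2, fp = 2), A = list(tp = 1, fp = 1), r_fg = 2)
#' @export
segment_auc <- function(B, A, r_fg) {
  if (!(A$tp < B$tp))
    stop("segment_auc requires tp_A < tp_B; skip zero-recall-width pairs")
  segment_auc_vec(A$tp, A$fp, B$tp, B$fp, r_fg)
}

## vectorized work-horse over parallel segment vectors
segment_params_vec <- function(tpA, fpA, tpB, fpB, R) {
  s <- (fpB - fpA) / (tpB - tpA)
  a <- 1 + s
  b <- (fpA - s * tpA) / R
  list(a = a, b = b, pA = tpA / R, pB = tpB / R)
}

segment_auc_vec <- function(tpA, fpA, tpB, fpB, R) {
  par <- segment_params_vec(tpA, fpA, tpB, fpB, R)
  a <- par$a; b <- par$b; pA <- par$pA; pB <- par$pB
  if (any(a * pA + b < -1e-9 * R))
    stop("internal consistency error: negative denominator a*p + b")
  # the logarithmic form degenerates as b -> 0; switch to the exact limit
  const <- abs(b) <= 1e-12 * pmax(1, abs(a * pB))
  out <- numeric(length(a))
  if (any(const))
    out[const] <- (pB[const] - pA[const]) / a[const]
  if (any(!const)) {
    i <- !const
    out[i] <- (pB[i] - pA[i] -
                 b[i] / a[i] * (log(a[i] * pB[i] + b[i]) -
                                log(a[i] * pA[i] + b[i]))) / a[i]
  }
  out
}

new_curve_result <- function(kind, method, auc, points, n_segments) {
  structure(list(kind = kind, method = method, auc = auc,
                 points = points, n_segments = n_segments),
            class = "wpr_curve_result")
}

#' @export
print.wpr_curve_result <- function(x, ...) {
  cat(sprintf("%s curve (%s interpolation)\n", toupper(x$kind), x$method))
  cat(sprintf("  AUC = %.6f over %d segment(s), %d curve point(s)\n",
              x$auc, x$n_segments, nrow(x$points)))
  invisible(x)
}

#' AUC-PR by continuous (closed-form) interpolation
#'
#' Sweeps the supporting points from full recall down to zero recall and
#' accumulates the exact segment areas of [segment_auc()].  Adjacent
#' supporting points with equal `tp` span no recall and contribute zero
#' area (the later, larger-`fp` point simply becomes the next segment
#' anchor).  The first recall-increasing segment starts at the
#' `tp = fp = 0` anchor, so the integral covers the whole recall interval
#' \[0, 1\] with the zero-recall precision taken as its one-sided limit.
#'
#' This is the only interpolation that applies to weighted data, where the
#' confusion-matrix entries are real-valued accumulated weights.
#'
#' @param points a `wpr_supporting_points` table or a `wpr_sample`.
#' @return A `wpr_curve_result` with the AUC-PR, the PR supporting
#'   coordinates, and the number of positive-width segments.
#' @examples
#' x <- unweighted_sample(c(4, 3, 2, 1), c("fg", "fg", "bg", "bg"))
#' auc_pr_continuous(x)$auc   # separable data: 1
#' @export
auc_pr_continuous <- function(points) {
  points <- as_supporting_points(points)
  R <- attr(points, "r_fg")
  i <- seq_len(nrow(points) - 1L)
  keep <- points$tp[i + 1L] > points$tp[i]
  areas <- segment_auc_vec(points$tp[i][keep], points$fp[i][keep],
                           points$tp[i + 1L][keep], points$fp[i + 1L][keep],
                           R)
  new_curve_result("pr", "continuous",
                   auc = sum(areas),
                   points = curve_points(points, "pr"),
                   n_segments = sum(keep))
}

## shared scaffolding of the two discrete interpolations: walks adjacent
## supporting pairs, inserts intermediate confusion matrices at unit steps
## of `along` (tp or fp) with the other count interpolated linearly, and
## applies the trapezoidal rule over (recall, precision).
auc_pr_discrete <- function(points, along = c("tp", "fp"), force = FALSE) {
  along <- match.arg(along)
  points <- as_supporting_points(points)
  R <- attr(points, "r_fg")
  int_tol <- 1e-9
  integral <- all(abs(points$tp - round(points$tp)) <= int_tol) &&
    all(abs(points$fp - round(points$fp)) <= int_tol)
  if (!isTRUE(attr(points, "unweighted")) && (!force || !integral))
    stop_input("discrete interpolation undefined for weighted data; ",
               "use the continuous interpolation (force = TRUE admits ",
               "integer multiplicity weights only)")
  n <- nrow(points)
  tp <- points$tp; fp <- points$fp
  seg_tp <- list(); seg_fp <- list()
  n_segments <- 0L
  for (k in seq_len(n - 1L)) {
    dtp <- tp[k + 1L] - tp[k]
    dfp <- fp[k + 1L] - fp[k]
    if (dtp > 0) n_segments <- n_segments + 1L
    d <- if (along == "tp") dtp else dfp
    if (d > 1 + int_tol) {
      x <- seq_len(round(d) - 1L)
      if (along == "tp") {
        seg_tp[[length(seg_tp) + 1L]] <- tp[k] + x
        seg_fp[[length(seg_fp) + 1L]] <- fp[k] + x * dfp / dtp
      } else {
        seg_tp[[length(seg_tp) + 1L]] <- tp[k] + x * dtp / dfp
        seg_fp[[length(seg_fp) + 1L]] <- fp[k] + x
      }
    }
    seg_tp[[length(seg_tp) + 1L]] <- tp[k + 1L]
    seg_fp[[length(seg_fp) + 1L]] <- fp[k + 1L]
  }
  all_tp <- c(0, unlist(seg_tp))
  all_fp <- c(0, unlist(seg_fp))
  recall <- all_tp / R
  precision <- all_tp / (all_tp + all_fp)
  # zero-recall anchor: precision is the one-sided limit along the first
  # recall-increasing segment, lim_{p->0+} p/(a p + b) = 1/a if b = 0
  # (no false positives above the first foreground score) and 0 otherwise.
  # This makes the trapezoid integrate the same recall range [0, 1] as the
  # continuous interpolation.
  zero <- all_tp == 0
  j <- which(!zero)[1L]
  if (!is.na(j)) {
    fp_at_zero <- if (j > 1L) all_fp[j - 1L] else 0
    anchor_prec <- if (fp_at_zero > 0) 0 else all_tp[j] / (all_tp[j] + all_fp[j])
    precision[zero] <- anchor_prec
  }
  auc <- trapezoid(recall, precision)
  new_curve_result("pr", if (along == "tp") "discrete_tp" else "discrete_fp",
                   auc = auc,
                   points = data.frame(recall = recall, precision = precision),
                   n_segments = n_segments)
}

trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2)
}

#' AUC-PR by discrete interpolation along the true positives
#'
#' The classical interpolation for unweighted data: between adjacent
#' supporting points differing by more than one true positive, intermediate
#' points are inserted at every integer `tp` step with `fp` interpolated
#' linearly, and the area is the trapezoidal rule over (recall, precision).
#'
#' The unit step size is only meaningful when the confusion-matrix entries
#' are counts, so weighted data are refused unless all entries are integers
#' and `force = TRUE` (multiplicity-type weights).
#'
#' @param points a `wpr_supporting_points` table or a `wpr_sample`.
#' @param force allow integer-valued weighted matrices.
#' @return A `wpr_curve_result` (`method = "discrete_tp"`) whose `points`
#'   include the inserted intermediates.
#' @seealso [auc_pr_discrete_fp()], [auc_pr_continuous()]
#' @export
auc_pr_discrete_tp <- function(points, force = FALSE) {
  auc_pr_discrete(points, "tp", force)
}

#' AUC-PR by discrete interpolation along the false positives
#'
#' Same construction as [auc_pr_discrete_tp()] but with intermediate points
#' at every integer `fp` step and `tp` interpolated linearly.  Segments
#' with no false-positive change yield no intermediates and are handled as
#' plain trapezoids.
#'
#' @inheritParams auc_pr_discrete_tp
#' @return A `wpr_curve_result` (`method = "discrete_fp"`).
#' @export
auc_pr_discrete_fp <- function(points, force = FALSE) {
  auc_pr_discrete(points, "fp", force)
}

#' AUC-ROC by the trapezoidal rule
#'
#' Linear interpolation between supporting points is exact for ROC curves,
#' for weighted as well as unweighted data, so the area is simply the
#' trapezoidal rule over (fpr, tpr) including the (0, 0) and (1, 1)
#' anchors.  For unweighted data this equals the Mann-Whitney rank
#' statistic.
#'
#' @param points a `wpr_supporting_points` table or a `wpr_sample`; both
#'   total class weights must be positive.
#' @return A `wpr_curve_result` (`kind = "roc"`, `method = "trapezoid"`).
#' @export
auc_roc <- function(points) {
  points <- as_supporting_points(points)
  xy <- curve_points(points, "roc")
  new_curve_result("roc", "trapezoid",
                   auc = trapezoid(xy$fpr, xy$tpr),
                   points = xy,
                   n_segments = nrow(xy) - 1L)
}

#' Densely evaluated continuous PR curve
#'
#' Evaluates the hyperbolic precision function `p / (a p + b)` of each
#' recall-increasing segment at `per_segment` evenly spaced recall values
#' up to and including the segment's upper end, in addition to all
#' supporting points.  With `per_segment = 1` only the supporting points
#' are returned.  Useful for plotting and for checking that the discrete
#' interpolations' intermediate points lie on the continuous curve.
#'
#' @param points a `wpr_supporting_points` table or a `wpr_sample`.
#' @param per_segment number of evaluation steps per segment (>= 1).
#' @return A `data.frame` with columns `recall`, `precision`,
#'   non-decreasing in `recall`.
#' @export
dense_pr_curve <- function(points, per_segment = 20L) {
  points <- as_supporting_points(points)
  if (per_segment < 1L) stop_input("per_segment must be >= 1")
  R <- attr(points, "r_fg")
  recs <- list(); precs <- list()
  for (k in seq_len(nrow(points) - 1L)) {
    tpA <- points$tp[k]; fpA <- points$fp[k]
    tpB <- points$tp[k + 1L]; fpB <- points$fp[k + 1L]
    if (tpB > tpA) {
      par <- segment_params_vec(tpA, fpA, tpB, fpB, R)
      p <- par$pA + (par$pB - par$pA) * seq_len(per_segment) / per_segment
      recs[[length(recs) + 1L]] <- p
      precs[[length(precs) + 1L]] <- p / (par$a * p + par$b)
    } else if (tpA + fpA > 0) {
      # vertical segment: keep both endpoint precisions at fixed recall
      recs[[length(recs) + 1L]] <- c(tpA, tpB) / R
      precs[[length(precs) + 1L]] <-
        c(tpA / (tpA + fpA), tpB / (tpB + fpB))
    }
  }
  data.frame(recall = unlist(recs), precision = unlist(precs))
}
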