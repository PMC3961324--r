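# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: quadrature instead of the closed form, direct
# per-threshold sums instead of cumulative sums, pairwise rank comparisons
# instead of the trapezoidal ROC area.

# Composite Simpson quadrature of the segment precision p / (a p + b)
# over [pA, pB]; n subintervals (forced even).  The 0/0 point at p = 0,
# b = 0 is replaced by its limit 1/a.
simpson_segment_auc <- function(tpA, fpA, tpB, fpB, R, n = 1e5) {
  s <- (fpB - fpA) / (tpB - tpA)
  a <- 1 + s
  b <- (fpA - s * tpA) / R
  pA <- tpA / R
  pB <- tpB / R
  n <- 2L * ceiling(n / 2)
  p <- seq(pA, pB, length.out = n + 1L)
  f <- ifelse(a * p + b == 0, 1 / a, p / (a * p + b))
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f) * (pB - pA) / (3 * n)
}

# Sum of per-segment Simpson areas over all recall-increasing pairs of a
# supporting-point table.
simpson_auc_pr <- function(sp) {
  R <- attr(sp, "r_fg")
  total <- 0
  for (k in seq_len(nrow(sp) - 1L)) {
    if (sp$tp[k + 1L] > sp$tp[k])
      total <- total + simpson_segment_auc(sp$tp[k], sp$fp[k],
                                           sp$tp[k + 1L], sp$fp[k + 1L], R)
  }
  total
}

# Pairwise-comparison (Mann-Whitney) AUC-ROC oracle; the weighted form
# weighs each (i, j) pair by w_fg[i] * w_bg[j].
pairwise_auc_roc <- function(sample) {
  s <- sample$scores
  cmp <- outer(s, s, function(x, y) (x > y) + 0.5 * (x == y))
  wij <- outer(sample$w_fg, sample$w_bg)
  sum(wij * cmp) / (sum(sample$w_fg) * sum(sample$w_bg))
}

# Direct (non-cumulative) supporting points: one confusion_at_threshold
# call per distinct score, plus the above-maximum sentinel.
direct_supporting_points <- function(sample) {
  thr <- c(Inf, sort(unique(sample$scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    cm <- if (is.finite(t)) confusion_at_threshold(sample, t) else
      list(tp = 0, fp = 0, fn = sum(sample$w_fg), tn = sum(sample$w_bg))
    data.frame(threshold = t, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
  }))
}

# Random weighted sample with general non-negative weights (soft labels,
# signal strengths, multiplicities all look like this to the curve code).
random_weighted_sample <- function(n, allow_zero = TRUE) {
  w_fg <- round(runif(n, 0, 2), 3)
  w_bg <- round(runif(n, 0, 2), 3)
  if (allow_zero) {
    w_fg[runif(n) < 0.15] <- 0
    w_bg[runif(n) < 0.15] <- 0
  }
  keep <- w_fg + w_bg > 0
  w_fg <- w_fg[keep]; w_bg <- w_bg[keep]
  if (sum(w_fg) == 0) w_fg[1L] <- 1
  weighted_sample(rnorm(length(w_fg)), w_fg, w_bg)
}

# Random valid PR segment (tp_A < tp_B, fp_A <= fp_B) including the edge
# cases b = 0 (proportional counts) and fp_A = fp_B (pure-tp step).
random_segment <- function() {
  R <- runif(1, 0.5, 10)
  tpA <- runif(1, 0, 0.8 * R)
  tpB <- runif(1, tpA + 0.05 * R, R)
  u <- runif(1)
  if (u < 0.15) {          # horizontal: fp proportional to tp (b = 0)
    k <- runif(1, 0.1, 3)
    fpA <- k * tpA; fpB <- k * tpB
  } else if (u < 0.3) {    # no fp change across the segment
    fpA <- fpB <- runif(1, 0, 5)
  } else {
    fpA <- runif(1, 0, 5)
    fpB <- fpA + runif(1, 0, 5)
  }
  list(tpA = tpA, fpA = fpA, tpB = tpB, fpB = fpB, R = R)
}

# All precision values the continuous curve attains at recall p: one per
# recall-increasing segment containing p (hyperbola evaluation, from
# segment parameters recomputed on the spot); at recalls shared with a
# vertical segment the curve attains several values.
continuous_precisions_at <- function(sp, p) {
  R <- attr(sp, "r_fg")
  tp <- p * R
  vals <- numeric(0)
  for (k in seq_len(nrow(sp) - 1L)) {
    if (sp$tp[k] <= tp + 1e-9 && tp <= sp$tp[k + 1L] + 1e-9 &&
        sp$tp[k + 1L] > sp$tp[k]) {
      s <- (sp$fp[k + 1L] - sp$fp[k]) / (sp$tp[k + 1L] - sp$tp[k])
      a <- 1 + s
      b <- (sp$fp[k] - s * sp$tp[k]) / R
      vals <- c(vals, p / (a * p + b))
    }
  }
  if (!length(vals)) stop("recall value outside any recall-increasing segment")
  vals
}

# TRUE iff (recall p, precision q) lies on the continuous PR curve: either
# on the hyperbola of a recall-increasing segment, or on the vertical
# connector between two equal-recall supporting points.
on_continuous_curve <- function(sp, p, q, tol = 1e-12) {
  if (any(abs(continuous_precisions_at(sp, p) - q) <= tol)) return(TRUE)
  tp <- p * attr(sp, "r_fg")
  for (k in seq_len(nrow(sp) - 1L)) {
    if (sp$tp[k + 1L] == sp$tp[k] && abs(sp$tp[k] - tp) <= 1e-9 &&
        sp$tp[k] > 0) {
      prec <- sp$tp[c(k, k + 1L)] / (sp$tp[c(k, k + 1L)] +
                                       sp$fp[c(k, k + 1L)])
      if (q >= min(prec) - tol && q <= max(prec) + tol) return(TRUE)
    }
  }
  FALSE
}

table2_weighted <- function() {
  read_sample(system.file("extdata", "table2_weighted.tsv", package = "wpr"),
              "weighted")
}

table2_unweighted <- function() {
  read_sample(system.file("extdata", "table2_unweighted.tsv", package = "wpr"),
              "unweighted")
}
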