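test_that("segment areas match hand-computable special cases", {
  # perfect single segment: precision identically 1
  expect_equal(segment_auc(B = list(tp = 1, fp = 0),
                           A = list(tp = 0, fp = 0), r_fg = 1), 1)
  # proportional counts: constant precision 1/2 over recall [0.5, 1]
  expect_equal(segment_auc(B = list(tp = 2, fp = 2),
                           A = list(tp = 1, fp = 1), r_fg = 2), 0.25)
  # one foreground vs one background point, background ranked on top:
  # a = 1, b = 1 over [0, 1] integrates to 1 - ln 2
  expect_equal(segment_auc(B = list(tp = 1, fp = 1),
                           A = list(tp = 0, fp = 1), r_fg = 1),
               1 - log(2), tolerance = 1e-12)
  # zero-recall-width pairs are the caller's job to skip
  expect_error(segment_auc(B = list(tp = 1, fp = 2),
                           A = list(tp = 1, fp = 1), r_fg = 1),
               "tp_A < tp_B")
})

test_that("the closed form agrees with Simpson quadrature on random segments", {
  set.seed(21)
  for (i in 1:200) {
    g <- random_segment()
    closed <- segment_auc(B = list(tp = g$tpB, fp = g$fpB),
                          A = list(tp = g$tpA, fp = g$fpA), r_fg = g$R)
    quad <- simpson_segment_auc(g$tpA, g$fpA, g$tpB, g$fpB, g$R)
    expect_equal(closed, quad, tolerance = 1e-9)
  }
})

test_that("continuous AUC-PR integrates the fixture to the quadrature sum", {
  sp <- supporting_points(table2_weighted())
  res <- auc_pr_continuous(sp)
  expect_equal(res$auc, simpson_auc_pr(sp), tolerance = 1e-9)
  expect_equal(res$n_segments, 6L)
})

test_that("continuous AUC-PR is 1 exactly for separable unweighted data", {
  x <- unweighted_sample(1:10, rep(c("bg", "fg"), c(7, 3)))
  expect_equal(auc_pr_continuous(x)$auc, 1)
})

test_that("mixed-weight points make an AUC-PR of 1 unattainable", {
  # one point carries both foreground and background mass
  x <- weighted_sample(1:4, c(1, 1, 0.5, 0), c(0, 0, 0.5, 1))
  best <- max_auc_pr(x)
  expect_lt(best, 1)
  expect_lt(auc_pr_continuous(x)$auc, 1)
})

test_that("AUC values stay in [0, 1] on random weighted samples", {
  set.seed(22)
  for (i in 1:25) {
    x <- random_weighted_sample(sample(3:60, 1))
    a <- auc_pr_continuous(x)$auc
    expect_gte(a, 0)
    expect_lte(a, 1)
    if (w_bg_total(x) > 0) {
      r <- auc_roc(x)$auc
      expect_gte(r, 0)
      expect_lte(r, 1)
    }
  }
})

test_that("discrete interpolations refuse real-valued confusion matrices", {
  x <- table2_weighted()
  expect_error(auc_pr_discrete_tp(x), "discrete interpolation undefined",
               class = "wpr_input_error")
  expect_error(auc_pr_discrete_fp(x), class = "wpr_input_error")
  # integer multiplicity weights pass with the explicit override
  m <- weighted_sample(1:4, c(3, 1, 0, 2), c(0, 2, 4, 1))
  expect_error(auc_pr_discrete_tp(m), class = "wpr_input_error")
  expect_s3_class(auc_pr_discrete_tp(m, force = TRUE), "wpr_curve_result")
})

test_that("two-point toys give the expected discrete areas", {
  # separable: both discrete methods and the continuous one give 1
  x <- unweighted_sample(c(2, 1), c("fg", "fg"))
  expect_equal(auc_pr_discrete_tp(x)$auc, 1)
  # alternating labels: every segment is a single unit step, so the
  # discrete-TP trapezoid and the continuous integral stay close
  u <- unweighted_sample(c(4, 3, 2, 1), c("fg", "bg", "fg", "bg"))
  expect_equal(auc_pr_discrete_tp(u)$auc, auc_pr_continuous(u)$auc,
               tolerance = 0.02)
})

test_that("equal tp:fp ratio segments are horizontal in all three methods", {
  # supporting points (0,0) -> (2,2) -> (4,4): precision 1/2 throughout
  x <- weighted_sample(c(2, 1), c(2, 2), c(2, 2))
  sp <- supporting_points(x)
  expect_equal(auc_pr_continuous(sp)$auc, 0.5)
  expect_equal(auc_pr_discrete_tp(sp, force = TRUE)$auc, 0.5)
  expect_equal(auc_pr_discrete_fp(sp, force = TRUE)$auc, 0.5)
})

test_that("discrete intermediate points lie on the continuous curve", {
  set.seed(23)
  n_fg <- 12; n_bg <- 40
  x <- unweighted_sample(c(rnorm(n_fg, 1), rnorm(n_bg)),
                         rep(c(TRUE, FALSE), c(n_fg, n_bg)))
  sp <- supporting_points(x)
  for (res in list(auc_pr_discrete_tp(sp), auc_pr_discrete_fp(sp))) {
    pts <- res$points
    pts <- pts[pts$recall > 0, ]
    ok <- vapply(seq_len(nrow(pts)), function(i) {
      on_continuous_curve(sp, pts$recall[i], pts$precision[i])
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("a coarse-tp / fine-fp segment is dominated by discrete-FP", {
  # one segment spanning 5 true positives and 295 false positives: the
  # fp-wise interpolation is fine-grained and hugs the continuous curve
  x <- weighted_sample(c(2, 1), c(5, 5), c(5, 295))
  sp <- supporting_points(x)
  cont <- auc_pr_continuous(sp)$auc
  dfp <- auc_pr_discrete_fp(sp, force = TRUE)$auc
  dtp <- auc_pr_discrete_tp(sp, force = TRUE)$auc
  expect_equal(dfp, cont, tolerance = 1e-3)
  expect_gt(abs(dtp - cont), abs(dfp - cont))
})

test_that("vertical segments (no recall change) are handled without area", {
  # fp-only step between two equal-tp points
  x <- unweighted_sample(c(3, 2, 1), c("fg", "bg", "fg"))
  sp <- supporting_points(x)
  expect_s3_class(auc_pr_discrete_fp(sp), "wpr_curve_result")
  expect_s3_class(auc_pr_discrete_tp(sp), "wpr_curve_result")
  expect_equal(auc_pr_continuous(sp)$auc,
               simpson_auc_pr(sp), tolerance = 1e-9)
})

test_that("discrete-TP converges to continuous for large distinct samples", {
  set.seed(24)
  x <- unweighted_sample(c(rnorm(500, 1.5), rnorm(5000)),
                         rep(c(TRUE, FALSE), c(500, 5000)))
  sp <- supporting_points(x)
  expect_lt(abs(auc_pr_discrete_tp(sp)$auc - auc_pr_continuous(sp)$auc),
            0.005)
})

test_that("trapezoidal AUC-ROC equals the pairwise rank statistic", {
  set.seed(25)
  # unweighted, with ties
  x <- unweighted_sample(sample(1:30, 50, replace = TRUE), runif(50) < 0.4)
  expect_equal(auc_roc(x)$auc, pairwise_auc_roc(x), tolerance = 1e-12)
  # weighted analogue
  for (i in 1:10) {
    y <- random_weighted_sample(sample(5:40, 1))
    if (w_bg_total(y) == 0) next
    expect_equal(auc_roc(y)$auc, pairwise_auc_roc(y), tolerance = 1e-12)
  }
  # degenerate cases
  sep <- unweighted_sample(1:6, rep(c("bg", "fg"), c(3, 3)))
  expect_equal(auc_roc(sep)$auc, 1)
  tied <- unweighted_sample(rep(1, 10), rep(c("fg", "bg"), 5))
  expect_equal(auc_roc(tied)$auc, 0.5)
})

test_that("weighted and count-based code paths coincide on unweighted data", {
  set.seed(26)
  scores <- sample(1:40, 60, replace = TRUE)
  labels <- runif(60) < 0.3
  x <- unweighted_sample(scores, labels)
  # independent integer-count path
  thr <- sort(unique(scores), decreasing = TRUE)
  counts <- data.frame(
    threshold = c(Inf, thr),
    tp = c(0, vapply(thr, function(t) sum(labels & scores >= t), numeric(1))),
    fp = c(0, vapply(thr, function(t) sum(!labels & scores >= t), numeric(1)))
  )
  sp <- supporting_points(x)
  expect_identical(sp$tp, counts$tp)
  expect_identical(sp$fp, counts$fp)
  # weighted route vs 0/1-weight route: same object
  y <- weighted_sample(scores, as.numeric(labels), as.numeric(!labels))
  expect_identical(supporting_points(y)$tp, sp$tp)
  expect_lt(abs(auc_pr_continuous(y)$auc - auc_pr_continuous(x)$auc), 1e-12)
})

test_that("the dense curve passes through supporting points exactly", {
  x <- table2_weighted()
  sp <- supporting_points(x)
  dense <- dense_pr_curve(sp, per_segment = 7)
  expect_true(all(diff(dense$recall) >= 0))
  pr <- curve_points(sp, "pr")
  for (i in seq_len(nrow(pr))) {
    hit <- which(abs(dense$recall - pr$recall[i]) < 1e-12)
    expect_true(any(abs(dense$precision[hit] - pr$precision[i]) < 1e-12))
  }
  # per_segment = 1 reduces to the supporting points
  d1 <- dense_pr_curve(sp, per_segment = 1)
  expect_equal(sort(unique(round(d1$recall, 12))),
               sort(unique(round(pr$recall, 12))))
  expect_error(dense_pr_curve(sp, per_segment = 0), class = "wpr_input_error")
})
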