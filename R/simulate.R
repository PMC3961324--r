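#' Configuration for class-conditional Gaussian score simulation
#'
#' Describes the score-sampling study used to compare the discrete and
#' continuous PR interpolations: per replicate, foreground scores are drawn
#' from a normal distribution whose mean is itself drawn around
#' `mu_center`, background scores from a standard-width normal at mean 0,
#' and all scores are then discretized to `n_bins` equal-width bins so that
#' at most `n_bins` distinct score values remain.  The default
#' `mu_center = 1.64` pairs with the default 1:10 foreground:background
#' ratio via the Gaussian quantile function; drawing the per-replicate mean
#' (default spread `mu_sd = 1`) spreads the resulting AUC values roughly
#' uniformly rather than concentrating them.
#'
#' @param n_fg,n_bg foreground and background sample sizes per replicate.
#' @param mu_center center of the per-replicate foreground mean.
#' @param mu_sd standard deviation of the per-replicate foreground mean.
#' @param score_sd within-class score standard deviation.
#' @param n_bins number of equal-width score bins (1 = all scores tied).
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @return A list of class `wpr_score_sim_config`.
#' @seealso [simulate_scores()], [interpolation_difference_experiment()]
#' @export
score_sim_config <- function(n_fg = 10L, n_bg = 100L, mu_center = 1.64,
                             mu_sd = 1, score_sd = 1, n_bins = 10L,
                             replicates = 1000L, seed = 1L) {
  stopifnot(n_fg >= 1L, n_bg >= 1L, n_bins >= 1L, score_sd > 0,
            replicates >= 1L)
  structure(list(n_fg = as.integer(n_fg), n_bg = as.integer(n_bg),
                 mu_center = mu_center, mu_sd = mu_sd, score_sd = score_sd,
                 n_bins = as.integer(n_bins),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "wpr_score_sim_config")
}

## equal-width binning over the pooled observed range; scores become the
## midpoints of their bins, so at most n_bins distinct values remain
bin_scores <- function(scores, n_bins) {
  if (n_bins == 1L || diff(range(scores)) == 0)
    return(rep(mean(range(scores)), length(scores)))
  breaks <- seq(min(scores), max(scores), length.out = n_bins + 1L)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  idx <- pmin(findInterval(scores, breaks, rightmost.closed = TRUE), n_bins)
  mids[idx]
}

#' Simulate binned class-conditional Gaussian scores
#'
#' Draws `replicates` independent unweighted samples under the model of
#' [score_sim_config()]: foreground scores `Normal(mu, score_sd)` with
#' `mu ~ Normal(mu_center, mu_sd)` redrawn per replicate, background scores
#' `Normal(0, score_sd)`, all scores discretized to `n_bins` equal-width
#' bins over the pooled per-replicate range.  Hard labels record the class
#' of origin.
#'
#' @param config a `wpr_score_sim_config`.
#' @return A list of `wpr_sample` objects of length `config$replicates`.
#' @export
simulate_scores <- function(config) {
  stopifnot(inherits(config, "wpr_score_sim_config"))
  set.seed(config$seed)
  lapply(seq_len(config$replicates), function(i) simulate_scores_once(config))
}

simulate_scores_once <- function(config) {
  mu <- stats::rnorm(1, config$mu_center, config$mu_sd)
  raw <- c(stats::rnorm(config$n_fg, mu, config$score_sd),
           stats::rnorm(config$n_bg, 0, config$score_sd))
  unweighted_sample(bin_scores(raw, config$n_bins),
                    rep(c(TRUE, FALSE), c(config$n_fg, config$n_bg)))
}

#' Per-replicate differences between discrete-TP and continuous AUC-PR
#'
#' Runs the simulation of [simulate_scores()] and records, per replicate,
#' the AUC-PR under the discrete-TP and the continuous interpolation and
#' their absolute difference.  Few data points combined with few distinct
#' score values produce coarse segments where the two interpolations
#' disagree most; the differences shrink towards zero as the sample size or
#' the number of bins grows.
#'
#' @param config a `wpr_score_sim_config`.
#' @return A `data.frame` with columns `replicate`, `auc_discrete_tp`,
#'   `auc_continuous`, `abs_diff`, carrying a `summary` attribute with
#'   `max`, `q50`, `q90`, `q99` of `abs_diff`.
#' @export
interpolation_difference_experiment <- function(config) {
  stopifnot(inherits(config, "wpr_score_sim_config"))
  set.seed(config$seed)
  res <- vapply(seq_len(config$replicates), function(i) {
    sp <- supporting_points(simulate_scores_once(config))
    c(auc_pr_discrete_tp(sp)$auc, auc_pr_continuous(sp)$auc)
  }, numeric(2))
  out <- data.frame(replicate = seq_len(config$replicates),
                    auc_discrete_tp = res[1L, ],
                    auc_continuous = res[2L, ],
                    abs_diff = abs(res[1L, ] - res[2L, ]))
  q <- stats::quantile(out$abs_diff, c(0.5, 0.9, 0.99), names = FALSE)
  attr(out, "summary") <- list(max = max(out$abs_diff),
                               q50 = q[1L], q90 = q[2L], q99 = q[3L])
  out
}

#' Configuration for beta-mixture foreground-weight simulation
#'
#' Describes the soft-label study: per-point foreground weights are drawn
#' from a mixture of beta distributions (bimodal by default, so most points
#' lean clearly towards one class), background weights are the complement
#' `1 - w_fg`, and hard labels are derived by thresholding `w_fg`.  The
#' default mixture `0.9 Beta(1.2, 8) + 0.1 Beta(8, 1.5)` with threshold 0.5
#' yields a hard-label class ratio of roughly 1:9.
#'
#' @param n number of data points.
#' @param mixture a list of components, each `list(weight, alpha, beta)`;
#'   component weights must be positive and sum to 1.
#' @param hard_threshold hard-label cut on `w_fg`, in (0, 1).
#' @param seed integer seed.
#' @return A list of class `wpr_weight_sim_config`.
#' @export
weight_sim_config <- function(n = 10000L,
                              mixture = list(
                                list(weight = 0.9, alpha = 1.2, beta = 8),
                                list(weight = 0.1, alpha = 8, beta = 1.5)),
                              hard_threshold = 0.5, seed = 1L) {
  w <- vapply(mixture, `[[`, numeric(1), "weight")
  ab <- vapply(mixture, function(m) c(m$alpha, m$beta), numeric(2))
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-12)
    stop_input("mixture weights must be positive and sum to 1")
  if (any(ab <= 0)) stop_input("beta shape parameters must be positive")
  if (hard_threshold <= 0 || hard_threshold >= 1)
    stop_input("hard_threshold must lie in (0, 1)")
  structure(list(n = as.integer(n), mixture = mixture,
                 hard_threshold = hard_threshold, seed = as.integer(seed)),
            class = "wpr_weight_sim_config")
}

#' Simulate beta-mixture foreground weights with derived hard labels
#'
#' @param config a `wpr_weight_sim_config`.
#' @return A `data.frame` with columns `w_fg`, `w_bg` (= `1 - w_fg`) and
#'   logical `label` (`TRUE` iff `w_fg >= hard_threshold`).
#' @seealso [build_good_permuted_bad()]
#' @export
simulate_weights <- function(config) {
  stopifnot(inherits(config, "wpr_weight_sim_config"))
  set.seed(config$seed)
  probs <- vapply(config$mixture, `[[`, numeric(1), "weight")
  comp <- sample.int(length(config$mixture), config$n,
                     replace = TRUE, prob = probs)
  alpha <- vapply(config$mixture, `[[`, numeric(1), "alpha")[comp]
  beta <- vapply(config$mixture, `[[`, numeric(1), "beta")[comp]
  w_fg <- stats::rbeta(config$n, alpha, beta)
  data.frame(w_fg = w_fg, w_bg = 1 - w_fg,
             label = w_fg >= config$hard_threshold)
}

#' Construct the good / permuted / bad classifier triple
#'
#' Given soft-labeled data points with derived hard labels, draws one pool
#' of class-conditional Gaussian scores (foreground mean above the
#' background mean 0) and assigns them to the points *within each hard
#' class* in three ways: sorted so that larger foreground weight receives a
#' larger score (`good`), in random order (`permuted`), and reversed
#' (`bad`).  The multiset of (score, hard label) pairs is identical across
#' the three classifiers by construction, so any evaluation that ignores
#' the weights cannot distinguish them, while weight-aware PR and ROC
#' curves rank them good > permuted > bad.  Because the scores are sorted
#' separately per hard class, even the good classifier stays below the
#' attainable maximum of [auc_pr_extremes()].
#'
#' @param weights a `data.frame` as returned by [simulate_weights()]
#'   (columns `w_fg`, `w_bg`, logical `label`); both classes must be
#'   non-empty.
#' @param seed integer seed for the score pool and the permutation.
#' @param mu_fg foreground score mean; default `qnorm(1 - f)` where `f` is
#'   the hard-label foreground fraction, placing the class boundary at the
#'   matching Gaussian quantile.
#' @return A named list `good`, `permuted`, `bad` of `data.frame`s with
#'   columns `score`, `w_fg`, `w_bg`, `label`.
#' @export
build_good_permuted_bad <- function(weights, seed = 1L, mu_fg = NULL) {
  stopifnot(is.data.frame(weights),
            all(c("w_fg", "w_bg", "label") %in% names(weights)))
  fg <- which(weights$label)
  bg <- which(!weights$label)
  if (length(fg) == 0L || length(bg) == 0L)
    stop_input("both hard classes must be non-empty")
  set.seed(seed)
  if (is.null(mu_fg))
    mu_fg <- stats::qnorm(1 - length(fg) / nrow(weights))
  pool_fg <- sort(stats::rnorm(length(fg), mu_fg, 1))
  pool_bg <- sort(stats::rnorm(length(bg), 0, 1))

  assign_scores <- function(ord_fg, ord_bg) {
    score <- numeric(nrow(weights))
    score[fg[ord_fg]] <- pool_fg   # k-th of ord gets k-th smallest score
    score[bg[ord_bg]] <- pool_bg
    cbind(score = score, weights)
  }
  up_fg <- order(weights$w_fg[fg], method = "radix")
  up_bg <- order(weights$w_fg[bg], method = "radix")
  list(
    good = assign_scores(up_fg, up_bg),
    permuted = assign_scores(sample(seq_along(fg)), sample(seq_along(bg))),
    bad = assign_scores(rev(up_fg), rev(up_bg))
  )
}

#' Logistic soft-labeling of a continuous signal
#'
#' Converts a measured signal (e.g. log-intensities) into soft labels with
#' a logistic function centered at the hard-labeling threshold: the
#' foreground weight is `1 / (1 + exp(-slope (signal - threshold)))`, so it
#' equals 0.5 exactly at the threshold and saturates to 0/1 away from it;
#' the background weight is the complement.
#'
#' @param signal numeric vector of signal values.
#' @param threshold signal value at which `w_fg = 0.5`.
#' @param slope positive logistic slope (default 1).
#' @return A `data.frame` with columns `w_fg`, `w_bg`.
#' @export
logistic_weighting <- function(signal, threshold, slope = 1) {
  if (slope <= 0) stop_input("slope must be positive")
  w_fg <- stats::plogis(slope * (signal - threshold))
  data.frame(w_fg = w_fg, w_bg = 1 - w_fg)
}

#' Stability of AUC-PR under a shifted labeling threshold
#'
#' Labeling rules that dichotomize a continuous signal are somewhat
#' arbitrary; a useful performance measure should be stable under mild
#' changes of the class border.  This experiment simulates datasets of
#' signal values (a Gaussian bulk plus a small high-signal component,
#' mimicking intensity measurements), a panel of classifiers of graded
#' quality (signal plus noise of increasing standard deviation), and two
#' labeling thresholds at `mean + 1 sd` and `mean + 2 sd` of the signal.
#' For each (dataset, classifier) pair it computes AUC-PR with hard labels
#' at either threshold, and with logistic soft labels ([logistic_weighting()])
#' centered at either threshold, and returns the Pearson correlations of
#' the two threshold's AUC-PR values across all pairs.  Weight-aware
#' evaluation retains information about points near the border and is
#' therefore expected to correlate more strongly across thresholds.
#'
#' @param n_datasets number of simulated datasets.
#' @param n_points signal values per dataset.
#' @param noise_sds classifier noise levels (one classifier per value).
#' @param slope logistic slope for the soft labels.
#' @param seed integer seed.
#' @return A list with `cor_weighted`, `cor_unweighted`, and the
#'   per-(dataset, classifier) `table` of the four AUC-PR values.
#' @export
stability_experiment <- function(n_datasets = 25L, n_points = 400L,
                                 noise_sds = c(0.25, 0.5, 1, 1.5, 2, 3),
                                 slope = 2, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (d in seq_len(n_datasets)) {
    comp <- stats::runif(n_points) < 0.08
    signal <- ifelse(comp, stats::rnorm(n_points, 2.5, 0.8),
                     stats::rnorm(n_points, 0, 1))
    thr <- mean(signal) + c(1, 2) * stats::sd(signal)
    w1 <- logistic_weighting(signal, thr[1L], slope)
    w2 <- logistic_weighting(signal, thr[2L], slope)
    lab1 <- signal >= thr[1L]
    lab2 <- signal >= thr[2L]
    if (!any(lab2) || all(lab1)) next  # degenerate draw: no foreground
    for (k in seq_along(noise_sds)) {
      score <- signal + stats::rnorm(n_points, 0, noise_sds[k])
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = d, classifier = k,
        auc_w_t1 = auc_pr_continuous(
          weighted_sample(score, w1$w_fg, w1$w_bg))$auc,
        auc_w_t2 = auc_pr_continuous(
          weighted_sample(score, w2$w_fg, w2$w_bg))$auc,
        auc_u_t1 = auc_pr_continuous(unweighted_sample(score, lab1))$auc,
        auc_u_t2 = auc_pr_continuous(unweighted_sample(score, lab2))$auc)
    }
  }
  tab <- do.call(rbind, rows)
  list(cor_weighted = stats::cor(tab$auc_w_t1, tab$auc_w_t2),
       cor_unweighted = stats::cor(tab$auc_u_t1, tab$auc_u_t2),
       table = tab)
}
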