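#' Bhattacharyya distance between two Gaussian distributions
#'
#' Closed form for univariate Gaussians:
#' \deqn{D_B = \frac{1}{4}\frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2}
#'   + \frac{1}{2}\ln\frac{\sigma_1^2+\sigma_2^2}{2\sigma_1\sigma_2}}
#' Vectorized over all arguments. Variances are floored at `var_floor` to
#' guard against degenerate (zero-spread) samples.
#'
#' @param mean1,var1 Mean and variance of the first distribution.
#' @param mean2,var2 Mean and variance of the second distribution.
#' @param var_floor Lower bound applied to both variances (default 1e-9).
#' @return Non-negative distance(s); 0 iff means and variances agree.
#' @export
bhattacharyya_gaussian <- function(mean1, var1, mean2, var2,
                                   var_floor = 1e-9) {
  v1 <- pmax(var1, var_floor)
  v2 <- pmax(var2, var_floor)
  if (any(v1 <= 0) || any(v2 <= 0))
    stop("non-positive variance after regularization")
  0.25 * (mean1 - mean2)^2 / (v1 + v2) +
    0.5 * log((v1 + v2) / (2 * sqrt(v1 * v2)))
}

# histogram (empirical) Bhattacharyya distance on shared breaks:
# D = -log sum_b sqrt(p_b q_b), with the coefficient floored to avoid -Inf
# for non-overlapping samples.
bhattacharyya_hist <- function(x, y, breaks, bc_floor = 1e-12) {
  px <- tabulate(findInterval(x, breaks, all.inside = TRUE),
                 nbins = length(breaks) - 1) / length(x)
  py <- tabulate(findInterval(y, breaks, all.inside = TRUE),
                 nbins = length(breaks) - 1) / length(y)
  -log(max(sum(sqrt(px * py)), bc_floor))
}

#' Distance between two individuals' rating distributions
#'
#' The unsigned rating dissimilarity of a (training, test) pair: the
#' Bhattacharyya distance between the two individuals' trial-wise rating
#' distributions. The default estimator plugs the sample means and unbiased
#' sample variances into the Gaussian closed form
#' ([bhattacharyya_gaussian()]); a histogram estimator over the 0-10 rating
#' scale is available for sensitivity analysis.
#'
#' @param ratings_t,ratings_s Rating vectors of the test and training
#'   individuals (at least 2 trials each). The distance is symmetric.
#' @param estimator `"gaussian"` (default) or `"histogram"`.
#' @param breaks Histogram breaks (default 21 bins over 0-10).
#' @param var_floor Variance floor for the Gaussian estimator.
#' @return A non-negative scalar.
#' @export
dist_pain <- function(ratings_t, ratings_s,
                      estimator = c("gaussian", "histogram"),
                      breaks = seq(0, 10, length.out = 22),
                      var_floor = 1e-9) {
  estimator <- match.arg(estimator)
  if (length(ratings_t) < 2 || length(ratings_s) < 2)
    stop("need at least 2 trials per individual")
  if (estimator == "gaussian")
    bhattacharyya_gaussian(mean(ratings_t), var(ratings_t),
                           mean(ratings_s), var(ratings_s), var_floor)
  else
    bhattacharyya_hist(ratings_t, ratings_s, breaks)
}

#' Signed difference of two individuals' mean ratings
#'
#' The signed rating dissimilarity of a (training, test) pair:
#' `mean(test ratings) - mean(training ratings)`. The test-minus-training
#' orientation is part of the definition.
#'
#' @param ratings_t,ratings_s Rating vectors of the test and training
#'   individuals (at least 1 trial each).
#' @return A scalar; antisymmetric under role swap.
#' @export
diff_pain <- function(ratings_t, ratings_s) {
  if (length(ratings_t) < 1 || length(ratings_s) < 1)
    stop("need at least 1 trial per individual")
  mean(ratings_t) - mean(ratings_s)
}

#' Voxel-wise Bhattacharyya distance of two individuals' features
#'
#' At each voxel, the Bhattacharyya distance between the two individuals'
#' trial-wise feature distributions (Gaussian closed-form estimator).
#'
#' @param features_t,features_s Trial-by-voxel matrices of the test and
#'   training individuals (same voxel count, at least 2 trials each).
#' @param var_floor Variance floor.
#' @return Numeric voxel vector, non-negative.
#' @export
dist_bold_map <- function(features_t, features_s, var_floor = 1e-9) {
  if (ncol(features_t) != ncol(features_s))
    stop("feature matrices have mismatched voxel counts (masks differ)")
  if (nrow(features_t) < 2 || nrow(features_s) < 2)
    stop("need at least 2 trials per individual")
  bhattacharyya_gaussian(colMeans(features_t), col_vars(features_t),
                         colMeans(features_s), col_vars(features_s),
                         var_floor)
}

#' Voxel-wise signed difference of two individuals' mean features
#'
#' At each voxel, `mean(test features) - mean(training features)` across
#' trials.
#'
#' @inheritParams dist_bold_map
#' @return Numeric voxel vector; antisymmetric under role swap.
#' @export
diff_bold_map <- function(features_t, features_s) {
  if (ncol(features_t) != ncol(features_s))
    stop("feature matrices have mismatched voxel counts (masks differ)")
  colMeans(features_t) - colMeans(features_s)
}

#' All-pairs individual-difference metrics for a cohort
#'
#' Computes, for every ordered (training s, test t) pair of individuals,
#' the four individual-difference metrics: `dist_pain` and `diff_pain`
#' (square matrices, rows = training, columns = test) and `dist_bold` /
#' `diff_bold` (pairs-by-voxel matrices over all ordered pairs, enumerated
#' training-major with an explicit `pair_index` table so rows are joinable
#' across modules).
#'
#' @param datasets List of `individual_dataset` objects.
#' @param estimator `"gaussian"` (default) or `"histogram"` Bhattacharyya
#'   estimator. The histogram estimator bins ratings on the 0-10 scale and
#'   features on 16 equal bins over their cohort-wide range.
#' @param var_floor Variance floor for the Gaussian estimator.
#' @return An object of class `difference_metrics`: list with `dist_pain`,
#'   `diff_pain` (n x n), `dist_bold`, `diff_bold` (n^2 x voxels),
#'   `pair_index` (data.frame with `row`, `training`, `test`,
#'   `training_id`, `test_id`), `ids`, `estimator`.
#' @export
difference_metrics <- function(datasets,
                               estimator = c("gaussian", "histogram"),
                               var_floor = 1e-9) {
  estimator <- match.arg(estimator)
  n <- length(datasets)
  if (n < 2) stop("need at least 2 individuals")
  ids <- vapply(datasets, `[[`, "", "individual_id")
  V <- ncol(datasets[[1]]$features)

  r_mean <- vapply(datasets, function(d) mean(d$ratings), 0)
  r_var <- vapply(datasets, function(d) var(d$ratings), 0)
  f_mean <- do.call(rbind, lapply(datasets, function(d) colMeans(d$features)))
  f_var <- do.call(rbind, lapply(datasets, function(d) col_vars(d$features)))

  dp <- matrix(0, n, n, dimnames = list(training = ids, test = ids))
  fp <- dp
  if (estimator == "gaussian") {
    for (s in seq_len(n)) {
      dp[s, ] <- bhattacharyya_gaussian(r_mean, r_var, r_mean[s], r_var[s],
                                        var_floor)
    }
  } else {
    breaks <- seq(0, 10, length.out = 22)
    for (s in seq_len(n))
      for (t_idx in seq_len(n))
        dp[s, t_idx] <- bhattacharyya_hist(datasets[[t_idx]]$ratings,
                                           datasets[[s]]$ratings, breaks)
  }
  for (s in seq_len(n)) fp[s, ] <- r_mean - r_mean[s]
  diag(dp) <- 0
  diag(fp) <- 0

  pair_index <- data.frame(
    row = seq_len(n * n),
    training = rep(seq_len(n), each = n),
    test = rep(seq_len(n), times = n))
  pair_index$training_id <- ids[pair_index$training]
  pair_index$test_id <- ids[pair_index$test]

  db <- matrix(0, n * n, V)
  fb <- matrix(0, n * n, V)
  if (estimator == "histogram") {
    rng <- range(vapply(datasets, function(d) range(d$features), numeric(2)))
    breaks_f <- seq(rng[1], rng[2], length.out = 17)
    nb <- length(breaks_f) - 1
    counts <- lapply(datasets, function(d) {
      cnt <- matrix(0, V, nb)
      for (v in seq_len(V))
        cnt[v, ] <- tabulate(findInterval(d$features[, v], breaks_f,
                                          all.inside = TRUE), nbins = nb)
      sqrt(cnt / nrow(d$features))
    })
  }
  for (r in seq_len(nrow(pair_index))) {
    s <- pair_index$training[r]
    t_idx <- pair_index$test[r]
    if (s == t_idx) next
    if (estimator == "gaussian") {
      db[r, ] <- bhattacharyya_gaussian(f_mean[t_idx, ], f_var[t_idx, ],
                                        f_mean[s, ], f_var[s, ], var_floor)
    } else {
      bc <- rowSums(counts[[t_idx]] * counts[[s]])
      db[r, ] <- -log(pmax(bc, 1e-12))
    }
    fb[r, ] <- f_mean[t_idx, ] - f_mean[s, ]
  }

  structure(list(dist_pain = dp, diff_pain = fp,
                 dist_bold = db, diff_bold = fb,
                 pair_index = pair_index, ids = ids, estimator = estimator),
            class = "difference_metrics")
}

#' @export
print.difference_metrics <- function(x, ...) {
  off <- row(x$dist_pain) != col(x$dist_pain)
  cat(sprintf(
    "difference_metrics (%s): %d individuals, %d voxels; DIST_PAIN %.3f +/- %.3f, |DIFF_PAIN| %.3f +/- %.3f\n",
    x$estimator, length(x$ids), ncol(x$dist_bold),
    mean(x$dist_pain[off]), sd(x$dist_pain[off]),
    mean(abs(x$diff_pain[off])), sd(abs(x$diff_pain[off]))))
  invisible(x)
}
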