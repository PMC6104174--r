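#' Mean absolute error between predicted and actual ratings
#'
#' The unsigned per-pair error metric: the mean over trials of
#' `|predicted - actual|`.
#'
#' @param predicted Numeric vector of predicted ratings.
#' @param actual Numeric vector of actual ratings, same length.
#' @return A non-negative scalar.
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) == 0 || length(predicted) != length(actual))
    stop("predicted and actual must be non-empty vectors of equal length")
  mean(abs(predicted - actual))
}

#' Mean prediction bias between predicted and actual ratings
#'
#' The signed per-pair error metric: the mean over trials of
#' `predicted - actual`. Positive values mean systematic over-prediction of
#' the test individual's ratings, negative values under-prediction. Always
#' `|mpb| <= mae`.
#'
#' @inheritParams mae
#' @return A scalar.
#' @export
mpb <- function(predicted, actual) {
  if (length(predicted) == 0 || length(predicted) != length(actual))
    stop("predicted and actual must be non-empty vectors of equal length")
  mean(predicted - actual)
}

#' Run the full individual-by-individual prediction scheme
#'
#' Applies every individual's decoding model to every individual's trials,
#' filling all `n^2` ordered (training, test) pairs: the diagonal is
#' within-individual prediction, the off-diagonal cells are
#' between-individual prediction. With 30 individuals this yields 900
#' prediction results, 870 between- and 30 within-individual.
#'
#' Within-individual prediction defaults to resubstitution (the model is
#' trained and applied on the same trials); combined with the centering
#' identity of [fit_simpls()] this forces diagonal MPB to zero. An optional
#' k-fold mode refits the diagonal models on k-1 folds and predicts the
#' held-out trials, which yields honest (nonzero) within-individual error.
#'
#' @param models List of `plsr_model`, one per individual.
#' @param datasets List of `individual_dataset`, aligned with `models` by
#'   `individual_id`.
#' @param within_mode `"resubstitution"` (default) or `"kfold"`.
#' @param k Number of folds for `within_mode = "kfold"`.
#' @return An object of class `pairwise_errors`: list with `mae` and `mpb`
#'   (n x n matrices, rows = training individual, columns = test
#'   individual), `ids`, `n_individuals`, `within_mode`.
#' @export
pairwise_predict <- function(models, datasets,
                             within_mode = c("resubstitution", "kfold"),
                             k = 5) {
  within_mode <- match.arg(within_mode)
  n <- length(models)
  if (n != length(datasets)) stop("models and datasets differ in length")
  ids_m <- vapply(models, function(m) m$individual_id %||% NA_character_, "")
  ids_d <- vapply(datasets, `[[`, "", "individual_id")
  if (anyNA(ids_m) || !identical(ids_m, ids_d))
    stop("models and datasets are not aligned by individual_id")
  mae_mat <- matrix(NA_real_, n, n, dimnames = list(training = ids_d, test = ids_d))
  mpb_mat <- mae_mat
  coef_mat <- do.call(cbind, lapply(models, `[[`, "coefficients"))
  intercepts <- vapply(models, `[[`, 0, "intercept")
  for (t_idx in seq_len(n)) {
    F_t <- datasets[[t_idx]]$features
    R_t <- datasets[[t_idx]]$ratings
    pred <- sweep(F_t %*% coef_mat, 2, intercepts, `+`)  # trials x training models
    err <- pred - R_t
    mae_mat[, t_idx] <- colMeans(abs(err))
    mpb_mat[, t_idx] <- colMeans(err)
  }
  if (within_mode == "kfold") {
    for (j in seq_len(n)) {
      d <- datasets[[j]]
      nt <- length(d$ratings)
      if (k < 2 || k > nt) stop("k must lie in [2, trials]")
      fold <- rep(seq_len(k), length.out = nt)
      pred <- numeric(nt)
      for (f in seq_len(k)) {
        hold <- fold == f
        A <- min(models[[j]]$n_components, sum(!hold) - 1,
                 ncol(d$features))
        m <- fit_simpls(d$features[!hold, , drop = FALSE],
                        d$ratings[!hold], A)
        pred[hold] <- predict(m, d$features[hold, , drop = FALSE])
      }
      mae_mat[j, j] <- mae(pred, d$ratings)
      mpb_mat[j, j] <- mpb(pred, d$ratings)
    }
  }
  structure(list(mae = mae_mat, mpb = mpb_mat, ids = ids_d,
                 n_individuals = n, within_mode = within_mode),
            class = "pairwise_errors")
}

#' @export
print.pairwise_errors <- function(x, ...) {
  off <- row(x$mae) != col(x$mae)
  cat(sprintf(
    "pairwise_errors: %d ordered pairs (%d between, %d within; within = %s)\n",
    length(x$mae), sum(off), x$n_individuals, x$within_mode))
  cat(sprintf("  between MAE %.3f +/- %.3f, between MPB %.3f +/- %.3f\n",
              mean(x$mae[off]), sd(x$mae[off]),
              mean(x$mpb[off]), sd(x$mpb[off])))
  invisible(x)
}

#' Compare within- and between-individual prediction error
#'
#' Splits each error matrix into its within-individual (diagonal) and
#' between-individual (off-diagonal) groups, compares the groups with a
#' two-sample t-test (Welch by default, as the groups have unequal sizes
#' and variances), and returns kernel density estimates (Gaussian kernel,
#' Silverman's rule-of-thumb bandwidth) of each group's distribution.
#'
#' @param errors A `pairwise_errors` object.
#' @param var_equal Passed to [stats::t.test()]; default `FALSE` (Welch).
#' @return An object of class `within_between_comparison`: per metric
#'   (`mae`, `mpb`) a list with group values, group means, `t`, `p`, and
#'   `density` (a list of two [stats::density()] objects).
#' @export
compare_within_between <- function(errors, var_equal = FALSE) {
  n <- errors$n_individuals
  if (n < 3) stop("need at least 3 individuals")
  out <- lapply(c(mae = "mae", mpb = "mpb"), function(metric) {
    m <- errors[[metric]]
    within <- diag(m)
    between <- m[row(m) != col(m)]
    if (sd(between) == 0 && sd(within) == 0) {
      # degenerate homogeneous case: identical groups, no evidence of difference
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(between, within, var.equal = var_equal)
    }
    kde <- function(v) if (sd(v) > 0) density(v, bw = "nrd0") else NULL
    list(between = between, within = within,
         mean_between = mean(between), mean_within = mean(within),
         t = unname(tt$statistic), p = tt$p.value,
         density = list(between = kde(between), within = kde(within)))
  })
  structure(c(out, list(n_individuals = n)),
            class = "within_between_comparison")
}

#' @export
print.within_between_comparison <- function(x, ...) {
  for (metric in c("mae", "mpb")) {
    m <- x[[metric]]
    cat(sprintf(
      "%s: between %.3f vs within %.3f (t = %.2f, p = %.3g)\n",
      toupper(metric), m$mean_between, m$mean_within, m$t, m$p))
  }
  invisible(x)
}
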