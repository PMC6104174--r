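## SIMPLS core (de Jong 1993), univariate response.
## Extracts orthonormal score vectors maximizing covariance with the centered
## response, deflating the cross-product vector against the orthonormalized
## loading basis. Returns as many components as requested, or fewer when the
## residual cross-covariance collapses (rank exhaustion) and strict = FALSE.
simpls_core <- function(Xc, yc, n_components, strict = TRUE) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc, yc)                       # p x 1 cross-covariance
  Rmat <- matrix(0, p, n_components)
  qvec <- numeric(n_components)
  Vmat <- matrix(0, p, n_components)
  a_done <- 0L
  normt1 <- NA_real_
  for (a in seq_len(n_components)) {
    r <- S
    tt <- Xc %*% r
    normt <- sqrt(sum(tt * tt))
    if (a == 1) normt1 <- normt
    tol <- if (is.finite(normt1) && normt1 > 0) 1e-10 * normt1 else 0
    if (!is.finite(normt) || normt <= tol) {
      if (strict)
        stop("n_components exceeds the rank of the centered feature matrix")
      break
    }
    tt <- tt / normt
    r <- r / normt
    pl <- crossprod(Xc, tt)                    # loading
    qa <- sum(yc * tt)
    v <- pl
    if (a > 1) {
      Vp <- Vmat[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    nv <- sqrt(sum(v * v))
    if (!is.finite(nv) || nv == 0) {
      if (strict)
        stop("n_components exceeds the rank of the centered feature matrix")
      break
    }
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    Rmat[, a] <- r; qvec[a] <- qa; Vmat[, a] <- v
    a_done <- a
  }
  list(weights = Rmat[, seq_len(a_done), drop = FALSE],
       q = qvec[seq_len(a_done)],
       n_components = a_done)
}

#' Fit a per-individual PLSR pain-decoding model (SIMPLS)
#'
#' Fits the linear decoding model `rating = features %*% coefficients +
#' intercept` by partial least squares regression with the SIMPLS algorithm:
#' latent score vectors are extracted iteratively from the centered data to
#' maximize covariance with the centered response, and the response is
#' regressed on these scores. Both blocks are mean-centered, so the mean of
#' the fitted values on the training trials equals the mean training rating
#' (this centering identity forces resubstitution mean prediction bias to
#' zero).
#'
#' At full rank (`n_components = min(trials - 1, voxels)` on a full-column-
#' rank problem) the solution coincides with ordinary least squares.
#'
#' @param features Trial-by-voxel numeric matrix.
#' @param ratings Numeric response vector, one rating per trial.
#' @param n_components Number of latent components (>= 1, at most
#'   `min(trials - 1, voxels)` and at most the rank of the centered data).
#' @param individual_id Optional label stored in the model.
#' @return An object of class `plsr_model`: list with `coefficients` (voxel
#'   vector, original scale), `intercept`, `n_components`, `r2` (cumulative
#'   fraction of response variance fitted by the first k components) and
#'   `individual_id`.
#' @export
fit_simpls <- function(features, ratings, n_components,
                       individual_id = NULL) {
  X <- as.matrix(features)
  y <- as.numeric(ratings)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("ratings length must equal feature-matrix row count")
  if (n < 2) stop("need at least 2 trials")
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) stop("degenerate response: ratings are constant")
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components must lie in [1, min(trials - 1, voxels)]")
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx)
  yc <- y - my
  core <- simpls_core(Xc, yc, n_components, strict = TRUE)
  coefs <- drop(core$weights %*% core$q)
  structure(
    list(coefficients = coefs,
         intercept = my - sum(mx * coefs),
         n_components = core$n_components,
         r2 = cumsum(core$q^2) / ssy,
         individual_id = individual_id),
    class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("plsr_model%s: %d voxels, %d components, training R2 = %.3f\n",
              if (!is.null(x$individual_id)) paste0(" [", x$individual_id, "]") else "",
              length(x$coefficients), x$n_components, max(x$r2)))
  invisible(x)
}

#' @export
coef.plsr_model <- function(object, ...) object$coefficients

#' Predict pain ratings from a fitted PLSR model
#'
#' Applies `features %*% coefficients + intercept`. Predictions are not
#' clipped to the rating scale: clipping would bias the signed error metric.
#'
#' @param object A `plsr_model`.
#' @param features Trial-by-voxel matrix (or a single feature vector).
#' @param ... Unused.
#' @return Numeric vector of predicted ratings.
#' @export
predict.plsr_model <- function(object, features, ...) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  if (ncol(X) != length(object$coefficients))
    stop("feature column count does not match coefficient length")
  drop(X %*% object$coefficients) + object$intercept
}

#' Choose the number of latent components by fitted-variance ratio
#'
#' Returns the smallest component count whose cumulative coefficient of
#' determination -- the fraction of the response variance carried by the
#' fitted values of the first k latent components -- reaches `r2_threshold`,
#' capped at `max_components`. If the threshold is unreachable at the cap
#' (or at the data rank), the cap is returned with a warning.
#'
#' @param features Trial-by-voxel matrix.
#' @param ratings Response vector.
#' @param r2_threshold Target fitted-variance ratio in (0, 1), default 0.95.
#' @param max_components Component cap, default 10.
#' @return Integer component count.
#' @export
select_n_components <- function(features, ratings, r2_threshold = 0.95,
                                max_components = 10) {
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("r2_threshold must lie in (0, 1)")
  X <- as.matrix(features)
  y <- as.numeric(ratings)
  n <- nrow(X)
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) stop("degenerate response: ratings are constant")
  cap <- min(max_components, n - 1, ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  core <- simpls_core(Xc, y - mean(y), cap, strict = FALSE)
  r2 <- cumsum(core$q^2) / ssy
  hit <- which(r2 >= r2_threshold)
  if (length(hit)) return(hit[1])
  warning(sprintf(
    "fitted-variance ratio %.3f below threshold %.3f at cap %d; returning cap",
    if (length(r2)) r2[length(r2)] else 0, r2_threshold, max(cap, 1)))
  max(core$n_components, 1L)
}

#' Group-level predictive-region map from per-individual models
#'
#' Tests, at each voxel, whether the decoding coefficients differ from zero
#' across individuals (one-sample t-test, two-sided), and applies
#' family-wise error correction (Bonferroni over in-mask voxels). Voxels
#' with zero across-individual coefficient variance are excluded from the
#' significance mask (their p is set to 0 or 1 by the sign of the mean) and
#' reported in `excluded`. Significant voxels carry a polarity label,
#' `"positive"` or `"negative"`, from the sign of the mean coefficient.
#'
#' @param models List of `plsr_model` objects over a common mask.
#' @param alpha Family-wise significance level (default 0.05).
#' @return An object of class `voxel_stat_map` with fields `statistic` (t),
#'   `p_value`, `p_fwe`, `significant`, `polarity`, `excluded`,
#'   `correction`, `alpha`, `df`.
#' @export
group_predictive_map <- function(models, alpha = 0.05) {
  if (length(models) < 3) stop("need at least 3 models")
  p_len <- vapply(models, function(m) length(m$coefficients), 0L)
  if (length(unique(p_len)) != 1) stop("models do not share a common mask")
  C <- do.call(rbind, lapply(models, `[[`, "coefficients"))
  n <- nrow(C); V <- ncol(C)
  mu <- colMeans(C)
  s <- sqrt(col_vars(C))
  degen <- s == 0
  tstat <- rep(NA_real_, V)
  pval <- rep(NA_real_, V)
  ok <- !degen
  tstat[ok] <- mu[ok] / (s[ok] / sqrt(n))
  pval[ok] <- 2 * pt(-abs(tstat[ok]), df = n - 1)
  if (any(degen)) {
    pval[degen] <- ifelse(mu[degen] == 0, 1, 0)
    tstat[degen] <- ifelse(mu[degen] == 0, 0, sign(mu[degen]) * Inf)
    message(sum(degen), " voxel(s) with zero across-individual variance ",
            "excluded from significance")
  }
  p_fwe <- pmin(pval * V, 1)
  significant <- !degen & p_fwe <= alpha
  polarity <- rep(NA_character_, V)
  polarity[significant] <- ifelse(mu[significant] > 0, "positive", "negative")
  structure(
    list(statistic = tstat, p_value = pval, p_fwe = p_fwe,
         significant = significant, polarity = polarity, excluded = degen,
         correction = "bonferroni", alpha = alpha, df = n - 1,
         mean_coefficient = mu),
    class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  sig <- x$significant
  n_sig <- if (is.matrix(sig)) colSums(sig) else sum(sig)
  cat(sprintf("voxel_stat_map: %d voxels, correction = %s, alpha = %s, significant = %s\n",
              length(x$p_value), x$correction,
              paste(format(x$alpha), collapse = "/"),
              paste(n_sig, collapse = "/")))
  invisible(x)
}
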