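#' Pearson correlation between a difference metric and an error metric
#'
#' Correlates two aligned per-pair vectors (e.g. DIST_PAIN with MAE, or
#' DIFF_PAIN with MPB) across between-individual pairs and returns the
#' Pearson coefficient with its two-sided p-value.
#'
#' @param metric Numeric per-pair vector of an individual-difference metric.
#' @param error Numeric per-pair vector of an error metric, same length.
#' @return List with `r`, `p`, `n`.
#' @export
correlate_scalar <- function(metric, error) {
  if (length(metric) != length(error) || length(metric) < 3)
    stop("metric and error must be equal-length vectors with n >= 3")
  if (sd(metric) == 0) stop("constant input: metric")
  if (sd(error) == 0) stop("constant input: error")
  ct <- cor.test(metric, error, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(metric))
}

#' Voxel-wise correlation map with family-wise error control
#'
#' Correlates each voxel's column of a pairs-by-voxel difference-metric
#' matrix with a per-pair error vector (Pearson, signed r retained so
#' positive and negative coupling are distinguishable), and flags voxels
#' that survive family-wise error correction at each requested alpha.
#'
#' Two inference modes are available:
#' \describe{
#'   \item{`"parametric"`}{per-voxel t-distributed p-values with Bonferroni
#'     correction over in-mask voxels, treating the pairs as independent
#'     observations. This mirrors common practice but is anti-conservative
#'     here, because each individual participates in many ordered pairs.}
#'   \item{`"permutation"`}{max-statistic permutation of individual labels:
#'     each permutation relabels the individuals underlying the metric's
#'     pair structure (requires `pair_index` and `n_individuals`) and the
#'     null distribution of the maximum |r| over voxels gives exact
#'     family-wise-corrected p-values under exchangeability of individuals.}
#' }
#'
#' @param metric_matrix Pairs-by-voxel numeric matrix (between-individual
#'   pairs only, in `pair_index` row order).
#' @param error Numeric per-pair error vector, same row order.
#' @param alpha Numeric vector of family-wise significance levels
#'   (default 0.05).
#' @param method `"parametric"` (default) or `"permutation"`.
#' @param pair_index Data frame with integer columns `training` and `test`
#'   (1-based individual indices) for each row of `metric_matrix`; required
#'   for permutation inference.
#' @param n_perm Number of permutations (default 499).
#' @param perm_seed Seed for the permutation draws.
#' @return A `voxel_stat_map` with `statistic` (r), `p_value`, `p_fwe`,
#'   `significant` (voxels x length(alpha) logical matrix), `excluded`
#'   (constant columns), `correction`, `alpha`, `n_pairs`.
#' @export
correlate_voxelwise <- function(metric_matrix, error, alpha = 0.05,
                                method = c("parametric", "permutation"),
                                pair_index = NULL, n_perm = 499,
                                perm_seed = 1L) {
  method <- match.arg(method)
  M <- as.matrix(metric_matrix)
  m <- nrow(M)
  if (length(error) != m) stop("error length does not match metric row count")
  if (m < 4) stop("need at least 4 pairs")
  if (sd(error) == 0) stop("constant input: error")
  V <- ncol(M)
  ec <- error - mean(error)
  sse <- sum(ec^2)
  Mc <- sweep(M, 2, colMeans(M))
  ssm <- colSums(Mc^2)
  excluded <- ssm == 0
  if (any(excluded))
    message(sum(excluded), " constant voxel column(s) excluded")
  denom <- sqrt(ssm * sse)
  r <- rep(NA_real_, V)
  r[!excluded] <- (crossprod(Mc, ec) / denom)[!excluded]

  if (method == "parametric") {
    tstat <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
    pval <- 2 * pt(-abs(tstat), df = m - 2)
    p_fwe <- pmin(pval * sum(!excluded), 1)
    correction <- "bonferroni"
  } else {
    if (is.null(pair_index))
      stop("permutation inference requires pair_index")
    n_ind <- max(pair_index$training, pair_index$test)
    lookup <- matrix(NA_integer_, n_ind, n_ind)
    lookup[cbind(pair_index$training, pair_index$test)] <- seq_len(m)
    rabs <- abs(r[!excluded])
    Mcv <- Mc[, !excluded, drop = FALSE]
    denv <- denom[!excluded]
    exceed <- numeric(sum(!excluded))
    with_seed(perm_seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample(n_ind)
        rows <- lookup[cbind(perm[pair_index$training],
                             perm[pair_index$test])]
        rp <- abs(crossprod(Mcv[rows, , drop = FALSE], ec) / denv)
        exceed <- exceed + (max(rp) >= rabs)
      }
    })
    pval <- rep(NA_real_, V)
    pval[!excluded] <- (1 + exceed) / (n_perm + 1)
    p_fwe <- pval  # max-statistic p-values are already family-wise
    correction <- "permutation-maxT"
  }

  significant <- matrix(FALSE, V, length(alpha),
                        dimnames = list(NULL, paste0("alpha_", alpha)))
  for (a in seq_along(alpha))
    significant[, a] <- !excluded & !is.na(p_fwe) & p_fwe <= alpha[a]
  structure(
    list(statistic = r, p_value = pval, p_fwe = p_fwe,
         significant = significant, excluded = excluded,
         correction = correction, alpha = alpha, n_pairs = m),
    class = "voxel_stat_map")
}

#' Flatten error and difference metrics into aligned per-pair vectors
#'
#' Extracts the off-diagonal (between-individual) cells of the error and
#' difference matrices in the shared training-major pair order, asserting
#' alignment by individual id. With n individuals each vector has
#' `n * (n - 1)` entries (870 for the 30-individual design).
#'
#' @param errors A `pairwise_errors` object.
#' @param diffs A `difference_metrics` object on the same individuals.
#' @return List with `pair_index` (between pairs only), `mae`, `mpb`,
#'   `dist_pain`, `diff_pain` (vectors) and `dist_bold`, `diff_bold`
#'   (pairs-by-voxel matrices).
#' @export
build_pair_vectors <- function(errors, diffs) {
  if (!identical(sort(errors$ids), sort(diffs$ids)))
    stop("errors and diffs cover different individuals")
  pi_all <- diffs$pair_index
  between <- pi_all$training != pi_all$test
  pi_b <- pi_all[between, , drop = FALSE]
  # index error matrices by id, not position, to stay order-safe
  e_tr <- match(pi_b$training_id, errors$ids)
  e_te <- match(pi_b$test_id, errors$ids)
  if (anyNA(e_tr) || anyNA(e_te)) stop("pair_index ids not found in errors")
  idx_e <- cbind(e_tr, e_te)
  idx_d <- cbind(pi_b$training, pi_b$test)
  list(pair_index = pi_b,
       mae = errors$mae[idx_e],
       mpb = errors$mpb[idx_e],
       dist_pain = diffs$dist_pain[idx_d],
       diff_pain = diffs$diff_pain[idx_d],
       dist_bold = diffs$dist_bold[between, , drop = FALSE],
       diff_bold = diffs$diff_bold[between, , drop = FALSE])
}
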