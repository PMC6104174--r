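# shared fixtures and independent oracles, all built in code

# scaled-down cohort used throughout the suite: study-sized individual count,
# reduced grid (8^3 keeps the default region layout valid)
small_config <- function(seed = 1, n = 30, g = 8, ...) {
  cohort_config(n_individuals = n, grid_shape = c(g, g, g), seed = seed, ...)
}

fit_cohort_models <- function(cohort, r2 = 0.95, cap = 10) {
  lapply(cohort$datasets, function(d) {
    A <- suppressWarnings(
      select_n_components(d$features, d$ratings, r2_threshold = r2,
                          max_components = cap))
    fit_simpls(d$features, d$ratings, A, individual_id = d$individual_id)
  })
}

# generate + fit + predict + difference metrics in one go
run_cohort_analysis <- function(config) {
  cohort <- generate_cohort(config)
  models <- fit_cohort_models(cohort)
  errors <- pairwise_predict(models, cohort$datasets)
  diffs <- difference_metrics(cohort$datasets)
  pv <- build_pair_vectors(errors, diffs)
  list(cohort = cohort, models = models, errors = errors, diffs = diffs,
       pv = pv, polarity = cohort$ground_truth$polarity)
}

# quadrature oracle for the Bhattacharyya distance of two Gaussians:
# D = -log integral sqrt(p q)
bhattacharyya_quadrature <- function(mean1, var1, mean2, var2) {
  f <- function(x) sqrt(dnorm(x, mean1, sqrt(var1)) * dnorm(x, mean2, sqrt(var2)))
  -log(integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
}

# normal-equations least-squares oracle (coefficients + intercept)
ols_oracle <- function(X, y) {
  Xc <- sweep(X, 2, colMeans(X))
  b <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  list(coefficients = drop(b), intercept = mean(y) - sum(colMeans(X) * b))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
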