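test_that("Gaussian Bhattacharyya distance matches closed forms and quadrature", {
  expect_equal(bhattacharyya_gaussian(3, 2, 3, 2), 0)
  expect_equal(bhattacharyya_gaussian(0, 1, 2, 1), 0.5)  # 0.25*4/2 + 0.5*ln 1
  expect_error(bhattacharyya_gaussian(0, -1, 0, 1, var_floor = -2),
               "non-positive variance")
  set.seed(14)
  for (i in 1:20) {
    m1 <- rnorm(1, 0, 3); m2 <- rnorm(1, 0, 3)
    v1 <- runif(1, 0.2, 4); v2 <- runif(1, 0.2, 4)
    expect_equal(bhattacharyya_gaussian(m1, v1, m2, v2),
                 bhattacharyya_quadrature(m1, v1, m2, v2), tolerance = 1e-6)
  }
})

test_that("dist_pain is a symmetric non-negative distance of rating samples", {
  set.seed(3)
  a <- runif(20, 0, 10); b <- runif(20, 2, 9)
  expect_equal(dist_pain(a, a), 0)
  expect_equal(dist_pain(a, b), dist_pain(b, a))
  expect_gt(dist_pain(a, b + 3), dist_pain(a, b) * 0)
  expect_error(dist_pain(a, b[1]), "at least 2")
  expect_equal(dist_pain(a, b),
               bhattacharyya_gaussian(mean(a), var(a), mean(b), var(b)))
  # histogram estimator: zero for identical samples, positive for separated
  expect_equal(dist_pain(a, a, estimator = "histogram"), 0)
  expect_gt(dist_pain(runif(50, 0, 3), runif(50, 6, 10),
                      estimator = "histogram"), 1)
})

test_that("diff_pain is the signed test-minus-training mean difference", {
  expect_equal(diff_pain(rep(7, 5), rep(3, 4)), 4)
  expect_equal(diff_pain(rep(3, 4), rep(7, 5)), -4)
  expect_equal(diff_pain(1:9, 1:9), 0)
  expect_error(diff_pain(numeric(0), 1), "at least 1")
})

test_that("voxel-wise distance and difference maps match direct computation", {
  set.seed(6)
  Ft <- matrix(rnorm(6 * 4), 6, 4)
  Fs <- matrix(rnorm(6 * 4), 6, 4)
  expect_equal(dist_bold_map(Ft, Ft), rep(0, 4))
  expect_equal(diff_bold_map(Ft, Fs), colMeans(Ft) - colMeans(Fs),
               tolerance = 1e-12)
  expect_equal(diff_bold_map(Ft, Fs), -diff_bold_map(Fs, Ft))
  # constant shift of one voxel with equal variances: closed form 0.25 c^2 / (2 v)
  Fs2 <- Ft
  Fs2[, 2] <- Ft[, 2] + 1.5
  d <- dist_bold_map(Ft, Fs2)
  expect_equal(d[2], 0.25 * 1.5^2 / (2 * var(Ft[, 2])))
  expect_equal(d[-2], rep(0, 3))
  # per-voxel agreement with the quadrature oracle on a 5-voxel toy
  Ga <- matrix(rnorm(30 * 5, 1, 1), 30, 5)
  Gb <- matrix(rnorm(30 * 5, 0, 2), 30, 5)
  d2 <- dist_bold_map(Ga, Gb)
  for (v in 1:5)
    expect_equal(d2[v],
                 bhattacharyya_quadrature(mean(Ga[, v]), var(Ga[, v]),
                                          mean(Gb[, v]), var(Gb[, v])),
                 tolerance = 1e-6)
  expect_error(dist_bold_map(Ft, Fs[, 1:3]), "mismatched voxel")
})

test_that("difference_metrics has the symmetry structure and pair order", {
  an <- run_cohort_analysis(small_config(seed = 19, n = 5))
  dm <- an$diffs
  expect_equal(dm$dist_pain, t(dm$dist_pain), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(dm$diff_pain, -t(dm$diff_pain), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diag(dm$dist_pain) == 0) && all(diag(dm$diff_pain) == 0))
  expect_true(all(dm$dist_pain >= 0) && all(dm$dist_bold >= 0))
  # training-major pair enumeration, antisymmetric voxel differences
  pi_ <- dm$pair_index
  expect_equal(pi_$training, rep(1:5, each = 5))
  expect_equal(pi_$test, rep(1:5, times = 5))
  r12 <- which(pi_$training == 1 & pi_$test == 2)
  r21 <- which(pi_$training == 2 & pi_$test == 1)
  expect_equal(dm$diff_bold[r12, ], -dm$diff_bold[r21, ], tolerance = 1e-12)
  expect_equal(dm$dist_bold[r12, ], dm$dist_bold[r21, ], tolerance = 1e-12)
  # spot-check one pair against the pairwise functions
  d1 <- an$cohort$datasets[[1]]; d2 <- an$cohort$datasets[[2]]
  expect_equal(dm$dist_pain[1, 2], dist_pain(d2$ratings, d1$ratings))
  expect_equal(dm$diff_pain[1, 2], diff_pain(d2$ratings, d1$ratings))
  expect_equal(dm$dist_bold[r12, ], dist_bold_map(d2$features, d1$features))
})

test_that("DIFF_PAIN recovers the planted sensitivity offsets", {
  cfg <- small_config(seed = 25, n = 12, rating_noise_sd = 0.2)
  an <- run_cohort_analysis(cfg)
  gt <- an$cohort$ground_truth
  mu <- gt$alpha + gt$beta * 0.5  # balanced levels: mean drive is 1/2
  pi_ <- an$pv$pair_index
  planted <- mu[pi_$test] - mu[pi_$training]
  expect_gt(cor(an$pv$diff_pain, planted), 0.9)
})
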