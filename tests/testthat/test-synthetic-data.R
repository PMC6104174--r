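test_that("stimulus sequences are balanced, reproducible and seed-sensitive", {
  cfg <- small_config(seed = 11, n = 4)
  for (j in 1:4) {
    s <- generate_stimulus_sequence(cfg, j)
    expect_length(s, 40)
    expect_equal(unname(table(s)), rep(10L, 4), ignore_attr = TRUE)
  }
  expect_identical(generate_stimulus_sequence(cfg, 2),
                   generate_stimulus_sequence(cfg, 2))
  expect_false(identical(generate_stimulus_sequence(cfg, 1),
                         generate_stimulus_sequence(cfg, 2)))
  one <- cohort_config(n_individuals = 2, n_levels = 1, trials_per_level = 3,
                       grid_shape = c(8, 8, 8), min_rating_range = 0)
  expect_identical(generate_stimulus_sequence(one, 1), rep(1L, 3))
})

test_that("cohort datasets respect the design counts and rating bounds", {
  co <- generate_cohort(small_config(seed = 5, n = 6))
  expect_length(co$datasets, 6)
  for (d in co$datasets) {
    expect_length(d$ratings, 40)
    expect_equal(nrow(d$features), 40)
    expect_equal(ncol(d$features), 512)
    expect_true(all(d$ratings >= 0 & d$ratings <= 10))
    expect_equal(unname(table(d$energy_levels)), rep(10L, 4),
                 ignore_attr = TRUE)
    expect_true(diff(range(d$ratings)) >= 4)  # exclusion rule enforced
  }
})

test_that("ground-truth weights follow region polarity", {
  co <- generate_cohort(small_config(seed = 9, n = 20))
  gt <- co$ground_truth
  pol <- gt$polarity
  W <- gt$true_weight_map
  expect_true(all(W[, pol == "null"] == 0))
  expect_true(all(W[, pol == "positive"] > 0))
  expect_true(all(W[, pol == "negative"] < 0))
  het <- W[, pol == "sign_heterogeneous", drop = FALSE]
  sgn <- sign(het[, 1])
  expect_true(all(sgn %in% c(-1, 1)))
  # coherent sign across the region within an individual
  expect_true(all(sign(het) == matrix(sgn, nrow(het), ncol(het))))
})

test_that("sign-heterogeneous weights have near-zero mean across individuals", {
  # across many individuals the random per-individual sign cancels
  co <- generate_cohort(small_config(seed = 21, n = 60))
  het <- co$ground_truth$true_weight_map[,
    co$ground_truth$polarity == "sign_heterogeneous", drop = FALSE]
  m <- colMeans(het)
  se <- sqrt(col_vars(het) / nrow(het))
  expect_true(all(abs(m) < 3 * se))
})

test_that("homogeneous noise-free cohorts are identical up to trial order", {
  spec <- default_region_spec(c(8, 8, 8))
  spec <- spec[vapply(spec, `[[`, "", "polarity") != "sign_heterogeneous"]
  cfg <- cohort_config(n_individuals = 4, grid_shape = c(8, 8, 8),
                       region_spec = spec,
                       sensitivity_mean_sd = c(1, 0),
                       rating_gain_mean_sd = c(8, 0),
                       amplitude_cv = 0, amplitude_voxel_sd = 0,
                       gain_sd = 0, rating_noise_sd = 0, bold_noise_sd = 0,
                       seed = 3)
  co <- generate_cohort(cfg)
  ref <- co$datasets[[1]]
  ord0 <- order(ref$energy_levels)
  for (d in co$datasets[-1]) {
    ord <- order(d$energy_levels)
    expect_equal(d$ratings[ord], ref$ratings[ord0])
    expect_equal(d$features[ord, ], ref$features[ord0, ])
  }
  diffs <- difference_metrics(co$datasets)
  expect_true(all(abs(diffs$dist_pain) < 1e-12))
  expect_true(all(abs(diffs$diff_pain) < 1e-12))
  expect_true(all(abs(diffs$diff_bold) < 1e-12))
})

test_that("different seeds give different cohorts", {
  a <- generate_cohort(small_config(seed = 1, n = 2))
  b <- generate_cohort(small_config(seed = 2, n = 2))
  expect_false(identical(a$datasets[[1]]$features, b$datasets[[1]]$features))
  a2 <- generate_cohort(small_config(seed = 1, n = 2))
  expect_identical(a$datasets[[1]]$features, a2$datasets[[1]]$features)
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(n_individuals = 0), "positive count")
  expect_error(cohort_config(grid_shape = c(8, 8), region_spec = list()),
               "three positive")
  expect_error(cohort_config(rating_scale = c(10, 0)), "increasing")
  bad <- default_region_spec(c(8, 8, 8))
  bad[[2]]$voxels[1] <- bad[[1]]$voxels[1]
  expect_error(cohort_config(grid_shape = c(8, 8, 8), region_spec = bad),
               "disjoint")
  out <- default_region_spec(c(8, 8, 8))
  out[[1]]$voxels[1] <- 513L
  expect_error(cohort_config(grid_shape = c(8, 8, 8), region_spec = out),
               "outside the grid")
})

test_that("trial timecourses peak at the 4th post-onset scan and round-trip", {
  cfg <- small_config(seed = 13, n = 2)
  tc <- generate_trial_timecourses(cfg, scans_per_trial = 8)
  expect_error(generate_trial_timecourses(cfg, scans_per_trial = 4), ">= 5")
  arr <- tc$timecourses[[1]]
  feats <- tc$cohort$datasets[[1]]$features
  # onset scan equals the baseline everywhere
  expect_true(all(arr[, , tc$onset_index] == tc$baseline))
  # zero-weight voxels with zero offset would be flat; in general the
  # normalized extremum sits at the 4th post-onset scan
  norm <- sweep(sweep(arr, c(1, 2), arr[, , 1], `-`), c(1, 2), arr[, , 1], `/`)
  nz <- which(abs(feats) > 1e-8, arr.ind = TRUE)
  peak_idx <- apply(abs(norm), c(1, 2), which.max)
  expect_true(all(peak_idx[nz] == tc$onset_index + 4L))
  # feature extraction recovers the generated feature matrix
  rec <- extract_features(arr, onset_index = tc$onset_index)
  expect_lt(max(abs(rec - feats)), 1e-12)
})
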