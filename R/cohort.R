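#' Default planted-region layout for a voxel grid
#'
#' Places four disjoint cubic regions of `region_size^3` voxels near the
#' corners of the grid: two positively predictive regions (S1-like and
#' insula-like), one negatively predictive region (mPFC-like), and one
#' sign-heterogeneous modulator region (precuneus-like) whose generative
#' weights have a random sign per individual and hence a zero
#' across-individual mean. All remaining voxels are null background.
#'
#' @param grid_shape Integer vector of length 3, the voxel grid dimensions.
#' @param region_size Edge length of each cubic region (default 3, i.e. 27
#'   voxels per region).
#' @return A list of regions, each a list with elements `label`, `polarity`
#'   (one of `"positive"`, `"negative"`, `"sign_heterogeneous"`), `voxels`
#'   (1-based indices into the column-major flattened grid) and `amplitude`
#'   (relative evoked-amplitude scale; the negatively predictive mPFC-like
#'   region deactivates strongly, the modulator region responds more
#'   weakly).
#' @export
default_region_spec <- function(grid_shape, region_size = 3) {
  d <- as.integer(grid_shape)
  if (length(d) != 3 || any(d < 2 * region_size + 2))
    stop("grid_shape must be 3 dimensions, each >= ", 2 * region_size + 2,
         " for the default region layout")
  lo <- lapply(d, function(dd) 2:(1 + region_size))
  hi <- lapply(d, function(dd) (dd - region_size):(dd - 1))
  block <- function(xs, ys, zs) {
    g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    as.integer((g[, 3] - 1) * d[1] * d[2] + (g[, 2] - 1) * d[1] + g[, 1])
  }
  list(
    list(label = "S1-like",        polarity = "positive", amplitude = 1,
         voxels = block(lo[[1]], lo[[2]], lo[[3]])),
    list(label = "insula-like",    polarity = "positive", amplitude = 1,
         voxels = block(hi[[1]], hi[[2]], lo[[3]])),
    list(label = "mPFC-like",      polarity = "negative", amplitude = 1.4,
         voxels = block(lo[[1]], hi[[2]], hi[[3]])),
    list(label = "precuneus-like", polarity = "sign_heterogeneous", amplitude = 0.9,
         voxels = block(hi[[1]], lo[[2]], hi[[3]]))
  )
}

#' Configuration of a synthetic laser-evoked pain cohort
#'
#' Bundles and validates every knob of the cohort generator. The defaults
#' emulate the study design the analysis is built for: 30 individuals, 10
#' trials at each of 4 laser energies (40 trials each), ratings on a 0-10
#' visual analog scale with heterogeneous per-individual sensitivity, and a
#' 12 x 12 x 12 voxel grid carrying four planted 27-voxel regions.
#'
#' Generative model, individual `j`, trial `i` at energy level `e`:
#' \deqn{R_i = clip(\alpha_j + \beta_j d_e + s\,(i-1) + \epsilon_i,\ 0,\ 10)}
#' with drive `d_e` linear in level index (equally spaced on `[0, 1]`),
#' `s` the optional adaptation slope, and
#' \deqn{B_{i,v} = w_{j,v} R_i + \delta_{j,v} + \eta_{i,v}}
#' where `w_{j,v}` is positive in positive regions, negative in the negative
#' region, random-signed per individual in the sign-heterogeneous region and
#' exactly zero at null voxels.
#'
#' The weights and offsets realize a stimulus-driven evoked response:
#' region voxels carry a per-individual evoked amplitude
#' `A_{j,v} = amplitude_mean * gain_{j,region} * (1 + voxel jitter)`
#' (fractional signal change per unit drive), and the feature model is
#' `B = polarity * A * drive + noise`, expressed in the rating-coupled form
#' above through `w_{j,v} = polarity * A_{j,v} / beta_j` and
#' `delta_{j,v} = -w_{j,v} * alpha_j + delta0_{j,v}`. Consequently the
#' individual rating offset `alpha_j` -- interpreted as report bias -- does
#' not propagate into the features, while evoked-amplitude heterogeneity
#' (`amplitude_cv`) and additive offsets (`gain_sd`) do; this is what makes
#' between-individual transfer fail in the characteristic, empirically
#' observed ways.
#'
#' @param n_individuals Number of individuals (default 30).
#' @param n_levels Number of stimulus energy levels (default 4).
#' @param trials_per_level Trials per level (default 10).
#' @param grid_shape Voxel grid dimensions (default `c(12, 12, 12)`).
#' @param region_spec Planted regions as produced by [default_region_spec()];
#'   regions must be disjoint in-grid voxel sets.
#' @param sensitivity_mean_sd Length-2 numeric: mean and across-individual SD
#'   of the rating offset `alpha_j` (rating units).
#' @param rating_gain_mean_sd Length-2 numeric: mean and SD of the rating
#'   range `beta_j`, the rating span between weakest and strongest energy.
#' @param amplitude_mean Nominal evoked amplitude per unit drive (fractional
#'   BOLD signal change at the strongest energy; default 0.015, i.e. 1.5%).
#' @param amplitude_cv Across-individual coefficient of variation of the
#'   regional amplitude gain.
#' @param amplitude_voxel_sd Within-region per-voxel relative jitter of the
#'   amplitude.
#' @param gain_sd Across-individual SD of the independent additive voxel
#'   offsets `delta0_{j,v}` (fractional signal change).
#' @param rating_noise_sd Trial-to-trial rating noise SD (rating units).
#' @param bold_noise_sd Trial-to-trial feature noise SD (fractional signal
#'   change).
#' @param rating_scale Rating bounds, fixed at `c(0, 10)` by the visual
#'   analog scale.
#' @param adaptation_slope Optional per-trial drift of ratings (rating units
#'   per trial; default 0). Affects ratings only.
#' @param min_rating_range Minimum realized rating range per individual
#'   (default 4): individuals whose trial ratings span less than this are
#'   redrawn (new offset and trial noise), mirroring the design's exclusion
#'   of participants without usable rating variation. Set to 0 to disable.
#' @param seed Integer seed from which all generator randomness derives.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 30,
                          n_levels = 4,
                          trials_per_level = 10,
                          grid_shape = c(12, 12, 12),
                          region_spec = default_region_spec(grid_shape),
                          sensitivity_mean_sd = c(1.0, 1.2),
                          rating_gain_mean_sd = c(8.0, 1.5),
                          amplitude_mean = 0.015,
                          amplitude_cv = 1.0,
                          amplitude_voxel_sd = 0.1,
                          gain_sd = 0.003,
                          rating_noise_sd = 1.0,
                          bold_noise_sd = 0.015,
                          rating_scale = c(0, 10),
                          adaptation_slope = 0,
                          min_rating_range = 4,
                          seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_levels = as.integer(n_levels),
    trials_per_level = as.integer(trials_per_level),
    grid_shape = as.integer(grid_shape),
    region_spec = region_spec,
    sensitivity_mean_sd = as.numeric(sensitivity_mean_sd),
    rating_gain_mean_sd = as.numeric(rating_gain_mean_sd),
    amplitude_mean = as.numeric(amplitude_mean),
    amplitude_cv = as.numeric(amplitude_cv),
    amplitude_voxel_sd = as.numeric(amplitude_voxel_sd),
    gain_sd = as.numeric(gain_sd),
    rating_noise_sd = as.numeric(rating_noise_sd),
    bold_noise_sd = as.numeric(bold_noise_sd),
    rating_scale = as.numeric(rating_scale),
    adaptation_slope = as.numeric(adaptation_slope),
    min_rating_range = as.numeric(min_rating_range),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (is.na(n_individuals) || n_individuals < 1)
      stop("n_individuals must be a positive count")
    if (is.na(n_levels) || n_levels < 1 || is.na(trials_per_level) ||
        trials_per_level < 1)
      stop("n_levels and trials_per_level must be positive counts")
    if (length(grid_shape) != 3 || any(grid_shape < 1) || any(is.na(grid_shape)))
      stop("grid_shape must be three positive integers")
    if (prod(grid_shape) < 1) stop("voxel grid is empty")
    if (length(rating_scale) != 2 || rating_scale[1] >= rating_scale[2])
      stop("rating_scale must be increasing bounds")
    if (min_rating_range < 0 || min_rating_range >= diff(rating_scale))
      stop("min_rating_range must lie in [0, rating scale span)")
    if (any(c(rating_noise_sd, bold_noise_sd, gain_sd, amplitude_voxel_sd,
              amplitude_cv) < 0))
      stop("noise and heterogeneity SDs must be non-negative")
    v_all <- unlist(lapply(region_spec, `[[`, "voxels"))
    if (length(v_all)) {
      if (any(v_all < 1 | v_all > prod(grid_shape)))
        stop("region voxels fall outside the grid")
      if (anyDuplicated(v_all)) stop("region voxel sets must be disjoint")
    }
    pol <- vapply(region_spec, `[[`, "", "polarity")
    bad <- setdiff(pol, c("positive", "negative", "sign_heterogeneous", "null"))
    if (length(bad)) stop("unknown region polarity: ", paste(bad, collapse = ", "))
  })
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort_config: %d individuals, %d x %d trials, grid %s (%d voxels), %d planted regions, seed %d\n",
    x$n_individuals, x$n_levels, x$trials_per_level,
    paste(x$grid_shape, collapse = "x"), prod(x$grid_shape),
    length(x$region_spec), x$seed))
  invisible(x)
}

#' Random balanced stimulus sequence for one individual
#'
#' Returns the energy-level index of each trial: a random permutation
#' containing exactly `trials_per_level` occurrences of each of the
#' `n_levels` levels, reproducible from the config seed and the individual
#' index.
#'
#' @param config A [cohort_config()].
#' @param individual_index 1-based individual index.
#' @return Integer vector of length `n_levels * trials_per_level`.
#' @export
generate_stimulus_sequence <- function(config, individual_index) {
  validate_cohort_config(config)
  if (individual_index < 1) stop("individual_index must be >= 1")
  lev <- rep(seq_len(config$n_levels), each = config$trials_per_level)
  with_seed(derive_seed(config$seed, 101L, individual_index), sample(lev))
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Draws per-individual rating offsets, rating gains, regional weight gains,
#' sign-heterogeneous region signs and voxel amplitude offsets, then
#' simulates every individual's trial ratings and trial-by-voxel feature
#' matrix under the generative model documented in [cohort_config()].
#'
#' @param config A [cohort_config()].
#' @return An object of class `pain_cohort`: a list with
#'   \describe{
#'     \item{datasets}{list of `individual_dataset` objects (fields
#'       `individual_id`, `ratings`, `features`, `energy_levels`)}
#'     \item{ground_truth}{list with `true_weight_map` (individuals x voxels),
#'       `alpha`, `beta`, `gain` (individuals x regions), `het_sign`,
#'       `delta` (individuals x voxels), `region_labels` and `polarity`
#'       (per voxel)}
#'     \item{mask}{logical array of `grid_shape`, all `TRUE`}
#'     \item{config}{the input config}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_individuals
  V <- prod(config$grid_shape)
  n_trials <- config$n_levels * config$trials_per_level

  region_labels <- rep("null", V)
  polarity <- rep("null", V)
  for (rg in config$region_spec) {
    region_labels[rg$voxels] <- rg$label
    polarity[rg$voxels] <- rg$polarity
  }

  # individual-level draws, one derived stream per purpose
  alpha <- with_seed(derive_seed(config$seed, 202L),
                     rnorm(n, config$sensitivity_mean_sd[1],
                           config$sensitivity_mean_sd[2]))
  beta <- with_seed(derive_seed(config$seed, 203L), {
    b <- rnorm(n, config$rating_gain_mean_sd[1], config$rating_gain_mean_sd[2])
    pmax(b, 2)  # rating range stays usable (individuals with range < 2 excluded by design)
  })
  n_regions <- length(config$region_spec)
  gain <- with_seed(derive_seed(config$seed, 204L), {
    g <- matrix(rnorm(n * max(n_regions, 1), 1, config$amplitude_cv),
                n, max(n_regions, 1))
    pmax(g, 0.05)  # amplitude gains stay positive; polarity is carried separately
  })
  het_sign <- with_seed(derive_seed(config$seed, 205L),
                        matrix(sample(c(-1, 1), n * max(n_regions, 1),
                                      replace = TRUE),
                               n, max(n_regions, 1)))
  delta0 <- if (config$gain_sd > 0)
    with_seed(derive_seed(config$seed, 206L),
              matrix(rnorm(n * V, 0, config$gain_sd), n, V))
  else matrix(0, n, V)

  drive <- if (config$n_levels > 1)
    (seq_len(config$n_levels) - 1) / (config$n_levels - 1)
  else rep(0, 1)

  # realized ratings first: individuals without usable rating variation are
  # redrawn (offset + trial noise), mirroring the design's exclusion rule
  ratings_list <- vector("list", n)
  levels_list <- vector("list", n)
  for (j in seq_len(n)) {
    lev <- generate_stimulus_sequence(config, j)
    for (attempt in 0:24) {
      a_j <- if (attempt == 0) alpha[j]
             else with_seed(derive_seed(config$seed, 208L, j, attempt),
                            rnorm(1, config$sensitivity_mean_sd[1],
                                  config$sensitivity_mean_sd[2]))
      eps <- if (config$rating_noise_sd > 0)
        with_seed(derive_seed(config$seed, 301L, j, attempt),
                  rnorm(n_trials, 0, config$rating_noise_sd))
      else numeric(n_trials)
      ratings <- a_j + beta[j] * drive[lev] +
        config$adaptation_slope * (seq_len(n_trials) - 1) + eps
      ratings <- pmin(pmax(ratings, config$rating_scale[1]),
                      config$rating_scale[2])
      if (diff(range(ratings)) >= config$min_rating_range) break
    }
    alpha[j] <- a_j
    ratings_list[[j]] <- ratings
    levels_list[[j]] <- lev
  }

  # per-individual voxel weights w = polarity * A / beta and offsets
  # delta = -w * alpha + delta0, so that B = w R + delta + eta realizes a
  # stimulus-driven evoked response B ~ polarity * A * drive + noise in
  # which the report offset alpha does not propagate into the features
  W <- matrix(0, n, V)
  if (n_regions) {
    jitter_rel <- if (config$amplitude_voxel_sd > 0)
      with_seed(derive_seed(config$seed, 207L),
                matrix(pmax(1 + rnorm(n * V, 0, config$amplitude_voxel_sd), 0.1),
                       n, V))
    else matrix(1, n, V)
    for (k in seq_len(n_regions)) {
      rg <- config$region_spec[[k]]
      sgn <- switch(rg$polarity,
                    positive = rep(1, n),
                    negative = rep(-1, n),
                    sign_heterogeneous = het_sign[, k],
                    null = rep(0, n))
      amp_scale <- rg$amplitude %||% 1
      for (v in rg$voxels) {
        A_v <- config$amplitude_mean * amp_scale * gain[, k] * jitter_rel[, v]
        W[, v] <- sgn * A_v / beta
      }
    }
  }
  delta <- -W * alpha + delta0

  datasets <- vector("list", n)
  for (j in seq_len(n)) {
    ratings <- ratings_list[[j]]
    eta <- if (config$bold_noise_sd > 0)
      with_seed(derive_seed(config$seed, 302L, j),
                matrix(rnorm(n_trials * V, 0, config$bold_noise_sd), n_trials, V))
    else matrix(0, n_trials, V)
    features <- tcrossprod(ratings, W[j, ]) +
      matrix(delta[j, ], n_trials, V, byrow = TRUE) + eta
    datasets[[j]] <- structure(
      list(individual_id = sprintf("sub-%02d", j),
           ratings = ratings,
           features = features,
           energy_levels = levels_list[[j]]),
      class = "individual_dataset")
  }

  structure(
    list(datasets = datasets,
         ground_truth = list(true_weight_map = W, alpha = alpha, beta = beta,
                             gain = gain, het_sign = het_sign, delta = delta,
                             region_labels = region_labels, polarity = polarity),
         mask = array(TRUE, config$grid_shape),
         config = config),
    class = "pain_cohort")
}

#' @export
print.pain_cohort <- function(x, ...) {
  cat(sprintf("pain_cohort: %d individuals, %d trials each, %d voxels\n",
              length(x$datasets), length(x$datasets[[1]]$ratings),
              prod(x$config$grid_shape)))
  invisible(x)
}

#' @export
print.individual_dataset <- function(x, ...) {
  cat(sprintf("individual_dataset %s: %d trials x %d voxels, ratings in [%.2f, %.2f]\n",
              x$individual_id, nrow(x$features), ncol(x$features),
              min(x$ratings), max(x$ratings)))
  invisible(x)
}

#' Generate per-trial scan series around each evoked feature
#'
#' Embeds every generated trial feature in a short scan series: the series
#' starts at a nonzero baseline at stimulus onset and follows a smooth
#' response shape whose extremum (in normalized units) falls exactly at the
#' 4th scan after onset, where it equals the trial's feature value. Running
#' the feature-extraction stage on these series therefore recovers the
#' cohort's feature matrices exactly (up to floating point).
#'
#' @param config A [cohort_config()]. The cohort is regenerated internally
#'   from this config, so the series correspond to [generate_cohort()] run
#'   on the same config.
#' @param scans_per_trial Number of scans per trial series (>= 5 so the 4th
#'   post-onset scan exists; onset is the first scan).
#' @param baseline Raw signal baseline value at onset (arbitrary scanner
#'   units, default 100).
#' @return A list with `cohort` (the generated [generate_cohort()] object),
#'   `timecourses` (per individual, an array trials x voxels x scans of raw
#'   signal), `onset_index` (1, the onset scan) and `baseline`.
#' @export
generate_trial_timecourses <- function(config, scans_per_trial = 8,
                                       baseline = 100) {
  if (scans_per_trial < 5)
    stop("scans_per_trial must be >= 5 so the 4th post-onset scan exists")
  cohort <- generate_cohort(config)
  k <- 0:(scans_per_trial - 1)
  # gamma-like shape: 0 at onset, unique extremum (=1) at the 4th post-onset scan
  shape <- (k / 4)^2 * exp(2 * (1 - k / 4))
  tc <- lapply(cohort$datasets, function(d) {
    arr <- array(0, c(nrow(d$features), ncol(d$features), scans_per_trial))
    for (s in seq_len(scans_per_trial))
      arr[, , s] <- baseline * (1 + d$features * shape[s])
    arr
  })
  list(cohort = cohort, timecourses = tc, onset_index = 1L,
       baseline = baseline)
}
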