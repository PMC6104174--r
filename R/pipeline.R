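#' Run the full analysis pipeline on a synthetic cohort
#'
#' Composes every stage end to end: simulate the cohort, select components
#' and fit one SIMPLS decoding model per individual, run the full ordered
#' train-by-test prediction scheme, compare within- and between-individual
#' error, compute the four individual-difference metrics, build the group
#' predictive-region map, and correlate difference metrics with error
#' metrics (scalar for ratings, voxel-wise with FWE correction for BOLD).
#' All randomness derives from `config$seed`, so identical configs produce
#' identical numeric outputs.
#'
#' When `config$out` is set, tabular artifacts (ratings, error matrices,
#' pair table, scalar report) and NIfTI volumes (mask, group map, r-maps)
#' are written there together with `manifest.csv` listing each file's MD5
#' checksum.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress messages (default `TRUE`).
#' @return An object of class `painxfer_report`: list with `cohort`,
#'   `models`, `n_components`, `errors`, `comparison`, `diffs`,
#'   `pair_vectors`, `group_map`, `scalar_cor` (DIST_PAIN~MAE,
#'   DIFF_PAIN~MPB), `voxel_cor` (DIST_BOLD~MAE, DIFF_BOLD~MPB maps) and
#'   `config`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  say <- function(...) if (verbose) message(sprintf(...))
  say("[simulate] seed %d: %d individuals, %d trials, %d voxels",
      config$seed, config$cohort$n_individuals,
      config$cohort$n_levels * config$cohort$trials_per_level,
      prod(config$cohort$grid_shape))
  cohort <- generate_cohort(config$cohort)

  say("[fit] SIMPLS per individual (R2 threshold %.2f, cap %d)",
      config$r2_threshold, config$max_components)
  models <- lapply(cohort$datasets, function(d) {
    A <- suppressWarnings(
      select_n_components(d$features, d$ratings,
                          r2_threshold = config$r2_threshold,
                          max_components = config$max_components))
    fit_simpls(d$features, d$ratings, A, individual_id = d$individual_id)
  })
  n_comp <- vapply(models, `[[`, 0L, "n_components")

  say("[predict] %d ordered pairs (within mode: %s)",
      length(models)^2, config$within_mode)
  errors <- pairwise_predict(models, cohort$datasets,
                             within_mode = config$within_mode)
  comparison <- if (length(models) >= 3) compare_within_between(errors)

  say("[diff] individual-difference metrics (%s estimator)", config$estimator)
  diffs <- difference_metrics(cohort$datasets, estimator = config$estimator)
  pv <- build_pair_vectors(errors, diffs)

  say("[map] group predictive map and correlation maps (%s inference)",
      config$inference)
  group_map <- if (length(models) >= 3)
    group_predictive_map(models, alpha = config$alpha[1])
  enough_pairs <- length(pv$mae) >= 4
  if (!enough_pairs)
    say("[map] fewer than 4 between-individual pairs: correlation stages skipped")
  scalar_cor <- if (enough_pairs) list(
    dist_pain_mae = correlate_scalar(pv$dist_pain, pv$mae),
    diff_pain_mpb = correlate_scalar(pv$diff_pain, pv$mpb))
  voxel_cor <- if (enough_pairs) list(
    dist_bold_mae = correlate_voxelwise(
      pv$dist_bold, pv$mae, alpha = config$alpha,
      method = config$inference, pair_index = pv$pair_index,
      n_perm = config$n_perm,
      perm_seed = derive_seed(config$seed, 401L)),
    diff_bold_mpb = correlate_voxelwise(
      pv$diff_bold, pv$mpb, alpha = config$alpha,
      method = config$inference, pair_index = pv$pair_index,
      n_perm = config$n_perm,
      perm_seed = derive_seed(config$seed, 402L)))

  report <- structure(
    list(cohort = cohort, models = models, n_components = n_comp,
         errors = errors, comparison = comparison, diffs = diffs,
         pair_vectors = pv, group_map = group_map,
         scalar_cor = scalar_cor, voxel_cor = voxel_cor, config = config),
    class = "painxfer_report")
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' @export
print.painxfer_report <- function(x, ...) {
  off <- row(x$errors$mae) != col(x$errors$mae)
  cat("painxfer pipeline report\n")
  print(x$cohort)
  cat(sprintf("  components per model: median %g (range %d-%d)\n",
              stats::median(x$n_components), min(x$n_components),
              max(x$n_components)))
  print(x$errors)
  if (!is.null(x$scalar_cor)) {
    cat(sprintf("  DIST_PAIN ~ MAE: r = %.3f (p = %.3g)\n",
                x$scalar_cor$dist_pain_mae$r, x$scalar_cor$dist_pain_mae$p))
    cat(sprintf("  DIFF_PAIN ~ MPB: r = %.3f (p = %.3g)\n",
                x$scalar_cor$diff_pain_mpb$r, x$scalar_cor$diff_pain_mpb$p))
  }
  if (!is.null(x$group_map)) {
    cat("  group predictive map: ")
    print(x$group_map)
  }
  invisible(x)
}

#' Write pipeline artifacts and a checksum manifest
#'
#' @param report A `painxfer_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask <- report$cohort$mask
  for (d in report$cohort$datasets)
    write_ratings_table(d, file.path(dir, paste0(d$individual_id, "_ratings.csv")))
  write_mask(mask, file.path(dir, "mask.nii.gz"))
  write.csv(report$errors$mae, file.path(dir, "mae_matrix.csv"))
  write.csv(report$errors$mpb, file.path(dir, "mpb_matrix.csv"))
  write.csv(report$diffs$dist_pain, file.path(dir, "dist_pain_matrix.csv"))
  write.csv(report$diffs$diff_pain, file.path(dir, "diff_pain_matrix.csv"))
  write.csv(report$pair_vectors$pair_index, file.path(dir, "pair_index.csv"),
            row.names = FALSE)
  if (!is.null(report$group_map)) {
    write_voxel_map(report$group_map$statistic, mask,
                    file.path(dir, "group_tmap.nii.gz"))
    write_voxel_map(as.numeric(report$group_map$significant), mask,
                    file.path(dir, "group_sig.nii.gz"))
  }
  if (!is.null(report$voxel_cor)) {
    write_voxel_map(report$voxel_cor$dist_bold_mae$statistic, mask,
                    file.path(dir, "r_dist_bold_mae.nii.gz"))
    write_voxel_map(report$voxel_cor$diff_bold_mpb$statistic, mask,
                    file.path(dir, "r_diff_bold_mpb.nii.gz"))
  }
  summary <- list(
    n_individuals = report$errors$n_individuals,
    n_pairs_total = length(report$errors$mae),
    n_pairs_between = sum(row(report$errors$mae) != col(report$errors$mae)),
    scalar_cor = report$scalar_cor,
    comparison = if (!is.null(report$comparison)) list(
      mae = report$comparison$mae[c("mean_between", "mean_within", "t", "p")],
      mpb = report$comparison$mpb[c("mean_between", "mean_within", "t", "p")]))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
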