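#' Write an individual's ratings table
#'
#' Comma-delimited with header columns `trial`, `level`, `rating`.
#'
#' @param dataset An `individual_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ratings_table <- function(dataset, path) {
  df <- data.frame(trial = seq_along(dataset$ratings),
                   level = dataset$energy_levels,
                   rating = dataset$ratings)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate an individual's ratings table
#'
#' Expects columns `trial`, `level`, `rating`; ratings must lie on the 0-10
#' scale and levels must be positive integers. Violations are reported with
#' their row number.
#'
#' @param path CSV file path.
#' @param rating_scale Allowed rating bounds (default `c(0, 10)`).
#' @return Data frame with columns `trial`, `level`, `rating`.
#' @export
read_ratings_table <- function(path, rating_scale = c(0, 10)) {
  df <- read.csv(path)
  need <- c("trial", "level", "rating")
  if (!all(need %in% names(df)))
    stop("malformed ratings table ", path, ": needs columns ",
         paste(need, collapse = ", "))
  bad <- which(!is.finite(df$rating) | df$rating < rating_scale[1] |
                 df$rating > rating_scale[2])
  if (length(bad))
    stop(sprintf("rating out of [%g, %g] at row %d of %s",
                 rating_scale[1], rating_scale[2], bad[1], path))
  badl <- which(!is.finite(df$level) | df$level < 1 |
                  df$level != round(df$level))
  if (length(badl))
    stop(sprintf("invalid level at row %d of %s", badl[1], path))
  df
}

#' Write voxel data as a NIfTI volume
#'
#' Maps a voxel vector (or trials-by-voxel matrix) onto the mask grid and
#' writes a 3D (or 4D, one volume per trial) NIfTI-1 file. Out-of-mask
#' voxels are written as 0. Voxel order is the column-major flattening of
#' the grid.
#'
#' @param values Numeric voxel vector, or a matrix with one row per volume.
#' @param mask Logical 3D array defining the grid and in-mask voxels.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_voxel_map <- function(values, mask, path) {
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be a 3D logical array")
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) != sum(mask))
    stop("values length does not match in-mask voxel count")
  n_vol <- nrow(values)
  arr <- array(0, c(d, n_vol))
  flat <- which(mask)
  for (i in seq_len(n_vol)) {
    vol <- array(0, d)
    vol[flat] <- values[i, ]
    arr[, , , i] <- vol
  }
  if (n_vol == 1) arr <- array(arr, d)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read voxel data from a NIfTI volume under a mask
#'
#' @param path NIfTI file path.
#' @param mask Logical 3D array; grid must match the volume.
#' @return Numeric vector (3D input) or volumes-by-voxel matrix (4D input)
#'   of in-mask values.
#' @export
read_voxel_map <- function(path, mask) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(mask)
  if (!identical(dim(arr)[1:3], as.integer(d)))
    stop("volume grid ", paste(dim(arr)[1:3], collapse = "x"),
         " does not match mask grid ", paste(d, collapse = "x"))
  flat <- which(mask)
  if (length(dim(arr)) == 3) return(as.numeric(arr[flat]))
  n_vol <- dim(arr)[4]
  out <- matrix(0, n_vol, length(flat))
  for (i in seq_len(n_vol)) out[i, ] <- array(arr[, , , i], d)[flat]
  out
}

#' Write a binary brain mask as NIfTI
#' @param mask Logical 3D array with at least one `TRUE` voxel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D logical array")
  if (sum(mask) == 0) stop("mask has 0 in-mask voxels")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask))), path)
  invisible(path)
}

#' Read a binary brain mask from NIfTI
#' @param path NIfTI file path.
#' @return Logical 3D array.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3) stop("mask volume must be 3D")
  m <- arr != 0
  if (sum(m) == 0) stop("mask has 0 in-mask voxels")
  m
}

#' Write a cohort to disk
#'
#' Per individual: a ratings CSV and a 4D NIfTI feature stack (one volume
#' per trial); plus the binary mask and the ground-truth weight maps (one
#' volume per individual).
#'
#' @param cohort A `pain_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(cohort$mask, file.path(dir, "mask.nii.gz"))
  for (d in cohort$datasets) {
    write_ratings_table(d, file.path(dir, paste0(d$individual_id, "_ratings.csv")))
    write_voxel_map(d$features, cohort$mask,
                    file.path(dir, paste0(d$individual_id, "_features.nii.gz")))
  }
  write_voxel_map(cohort$ground_truth$true_weight_map, cohort$mask,
                  file.path(dir, "true_weights.nii.gz"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Bundles the cohort generator configuration with the fitting and analysis
#' settings of [run_pipeline()]. Serializable to YAML with
#' [write_pipeline_config()] / [read_pipeline_config()] (round-trip
#' stable).
#'
#' @param cohort A [cohort_config()].
#' @param r2_threshold Fitted-variance threshold for component selection.
#' @param max_components Component cap.
#' @param alpha Numeric vector of family-wise significance levels.
#' @param estimator Bhattacharyya estimator, `"gaussian"` or `"histogram"`.
#' @param within_mode Within-individual prediction mode.
#' @param inference Voxel-wise correlation inference, `"parametric"` or
#'   `"permutation"`.
#' @param n_perm Permutations for `inference = "permutation"`.
#' @param seed Top-level pipeline seed; overrides `cohort$seed`.
#' @param out Optional output directory for artifacts and manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            r2_threshold = 0.95,
                            max_components = 10,
                            alpha = 0.05,
                            estimator = "gaussian",
                            within_mode = "resubstitution",
                            inference = "parametric",
                            n_perm = 499,
                            seed = 1L,
                            out = NULL) {
  cfg <- list(cohort = cohort, r2_threshold = r2_threshold,
              max_components = as.integer(max_components),
              alpha = as.numeric(alpha), estimator = estimator,
              within_mode = within_mode, inference = inference,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              out = out)
  cfg$cohort$seed <- cfg$seed
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cc <- x$cohort
  cc$region_spec <- lapply(cc$region_spec, function(rg) {
    rg$voxels <- as.integer(rg$voxels)
    rg
  })
  cohort <- do.call(cohort_config, cc)
  pipeline_config(cohort = cohort, r2_threshold = x$r2_threshold,
                  max_components = x$max_components, alpha = x$alpha,
                  estimator = x$estimator, within_mode = x$within_mode,
                  inference = x$inference, n_perm = x$n_perm,
                  seed = x$seed, out = x$out)
}
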