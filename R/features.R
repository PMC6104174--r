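#' Baseline-normalize a trial scan series
#'
#' Normalizes a raw BOLD scan series by subtracting and then dividing by its
#' baseline value at stimulus onset, so the onset scan maps to 0 and every
#' other scan to a fractional signal change.
#'
#' Indexing convention (used throughout the package): `onset_index` is the
#' 1-based position of the onset scan within `values`; the "k-th scan after
#' onset" is position `onset_index + k`.
#'
#' @param values Numeric vector of raw scan values for one trial and voxel.
#' @param onset_index 1-based index of the stimulus-onset scan.
#' @param context Optional string naming the trial/voxel, used in error
#'   messages for degenerate baselines.
#' @return Numeric vector `(values - baseline) / baseline`.
#' @export
normalize_series <- function(values, onset_index = 1L, context = NULL) {
  if (onset_index < 1 || onset_index > length(values))
    stop("onset_index out of series bounds")
  b <- values[onset_index]
  if (!is.finite(b) || b == 0)
    stop("degenerate baseline (zero at onset)",
         if (!is.null(context)) paste0(" at ", context) else "")
  (values - b) / b
}

#' Extract the trial feature from a normalized series
#'
#' The decoding feature of a trial is the normalized BOLD value at exactly
#' the 4th scan after stimulus onset -- the scan at which the evoked
#' response peaks at a 1.5 s repetition time -- not a running maximum,
#' which would be noise-biased.
#'
#' @param normalized Numeric vector, a baseline-normalized scan series.
#' @param onset_index 1-based index of the onset scan.
#' @return The normalized value at `onset_index + 4`.
#' @export
extract_feature <- function(normalized, onset_index = 1L) {
  idx <- onset_index + 4L
  if (onset_index < 1 || idx > length(normalized))
    stop("series too short: no 4th scan after onset")
  normalized[idx]
}

#' Extract the trial-by-voxel feature matrix from trial scan series
#'
#' Applies [normalize_series()] and [extract_feature()] to every trial and
#' voxel of a trials x voxels x scans array.
#'
#' @param timecourses Numeric array, trials x voxels x scans, raw signal.
#' @param onset_index 1-based index of the onset scan.
#' @return Numeric matrix, trials x voxels, of normalized 4th-post-onset
#'   scan values.
#' @export
extract_features <- function(timecourses, onset_index = 1L) {
  d <- dim(timecourses)
  if (length(d) != 3) stop("timecourses must be a trials x voxels x scans array")
  if (onset_index < 1 || onset_index + 4L > d[3])
    stop("series too short: no 4th scan after onset")
  b <- matrix(timecourses[, , onset_index], d[1], d[2])
  if (any(!is.finite(b)) || any(b == 0)) {
    bad <- which(b == 0 | !is.finite(b), arr.ind = TRUE)
    stop(sprintf("degenerate baseline (zero at onset) at trial %d, voxel %d",
                 bad[1, 1], bad[1, 2]))
  }
  peak <- matrix(timecourses[, , onset_index + 4L], d[1], d[2])
  (peak - b) / b
}
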