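Package: painxfer
Title: Between-Individual Transfer Error Analysis for fMRI Pain Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how individual differences in pain ratings and
    in evoked BOLD features determine the error of cross-individual fMRI pain
    decoding. Provides a synthetic laser-evoked cohort simulator with recorded
    ground truth, trial-level BOLD feature extraction, per-individual partial
    least squares regression (SIMPLS) decoding models, the full
    individual-by-individual transfer prediction scheme with mean absolute
    error and mean prediction bias, Bhattacharyya-distance and mean-difference
    individual-difference metrics, and voxel-wise correlation mapping with
    family-wise error control (Bonferroni and max-statistic permutation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
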