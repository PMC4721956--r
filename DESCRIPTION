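Package: froimal
Title: Multi-Atlas Labeling of Subject-Specific Functional Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic identification of subject-specific functional regions
    of interest (fROIs) in thresholded fMRI activation maps by multi-atlas
    labeling. Each manually labeled reference atlas is encoded as a
    coordinate-to-label decision forest; reference atlases are ranked by
    activation-pattern similarity to the target (Pearson correlation or
    normalized mutual information) and the top-ranked subset is fused by
    averaging per-atlas probabilistic predictions and majority voting.
    Includes the image-based label-transfer baseline, the single-atlas
    group-constrained subject-specific (GSS) baseline built from maximum
    probability maps, a synthetic activation-map cohort generator for
    validation, leave-one-subject-out evaluation drivers, and a command-line
    interface. Volumes are read and written as NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ranger,
    knitr
Config/testthat/edition: 3
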