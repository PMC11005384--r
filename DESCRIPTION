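Package: potholeFA
Title: White-Matter FA Deviation Mapping ("Pothole" Analysis) for DTI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise normative deviation mapping of diffusion-tensor
    fractional anisotropy (FA). Builds a control-cohort normative template
    (per-voxel mean and SD over white matter common to controls), computes
    per-subject z-maps, detects contiguous clusters of abnormally low FA
    ("potholes") by 3D connected-component labeling with a cluster-extent
    filter, summarizes per-subject pothole counts and volumes, extracts
    atlas-ROI mean FA, and provides the group-comparison statistics used in
    such studies (one-way ANOVA with eta-squared and Bonferroni post hocs,
    from raw data or from published group summaries; pooled t-test with
    Cohen's d; Pearson chi-square; Mann-Whitney; Spearman). Includes a
    synthetic-cohort generator with planted hypo-FA lesions and recorded
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
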