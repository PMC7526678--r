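Package: meniscusstrain
Title: Regional Strain Analysis of Menisci from Volumetric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-to-strain pipeline for human menisci under
    compressive load. Reads volumetric MR images and segmentation masks
    (NIfTI), estimates dense displacement fields by rigid alignment
    followed by a demons-style diffeomorphic registration with a local
    cross-correlation metric, converts segmented voxels into hexahedral
    meshes, computes element strain tensors from nodal displacements,
    decomposes them into axial, circumferential and radial components in
    a per-meniscus cylindrical frame, partitions the meniscus into the
    five anatomical regions and inner/outer zones, and reduces strain
    fields to characteristic regional medians. Includes a synthetic
    phantom generator (C-shaped wedge geometry, analytic deformation
    fields, MRI-like noise, two-group cohorts) and the nonparametric
    statistics battery used for group comparison (Mann-Whitney,
    Friedman, paired Wilcoxon, Kruskal-Wallis, Shapiro-Wilk, Holm and
    Bonferroni corrections), plus Dice overlap reporting for
    segmentation agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
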