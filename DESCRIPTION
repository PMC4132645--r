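Package: lesionmapr
Title: Lesion-Deficit Mapping, Mislocalization Error Fields, and
    Multivariate Remapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying systematic mislocalization in voxel-based
    lesion-symptom mapping (VLSM). Simulates stroke-like binary lesion
    cohorts with controllable spatial stereotypy (vascular-tree-like
    territory architecture) alongside independent-damage null cohorts,
    derives ground-truth deficit labels from hypothetical critical loci
    (single voxels or parcellation areas), runs mass-univariate Fisher's
    exact inference with Bonferroni control, quantifies the displacement of
    the inferred locus from the true locus as an error vector field, and
    contrasts the result with high-dimensional multivariate inference based
    on linear support vector machines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
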