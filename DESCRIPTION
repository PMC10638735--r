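Package: pifmclass
Title: Architecture-Based Classification of Plantar Intrinsic Foot Muscles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-muscle fiber length and physiological
    cross-sectional area (PCSA) of the seven large plantar intrinsic foot
    muscles by combining in-vivo MRI morphometry (muscle volume and length
    from segmented label stacks) with cadaveric architecture parameters
    (fiber-length-to-muscle-length ratios and pennation angles), then groups
    the (PCSA, fiber length) feature space with seeded multi-restart k-means
    under elbow-method model selection and tests per-muscle cluster
    membership frequencies with a chi-square test and Bonferroni-corrected
    pairwise post-hoc comparisons. Includes a synthetic-cohort generator
    (Gaussian-copula truncated-normal marginals) and voxelized phantom
    builder so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
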