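Package: footmorph
Title: Subject-Specific Foot Geometry Morphing and Finite-Element Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building subject-specific foot models from 3D surface
    scans. Morphs a template foot surface and its merged internal bone onto a
    target scanned surface via landmark-driven affine registration followed by
    radial-basis-function transformations (point-based on landmarks, then
    surface-based on sampled correspondences) with multiquadric, thin-plate and
    triharmonic kernels. Quantifies morphing accuracy with signed surface
    distance maps and positive/negative error summaries, assembles a
    solver-ready finite-element input deck (linear-elastic bone, second-order
    polynomial hyperelastic bulk soft tissue, first-order Ogden skin membrane,
    contact, loads and boundary conditions), and provides region-wise plantar
    pressure comparison statistics (normality-gated paired tests, Pearson
    correlation, Bland-Altman agreement). Includes a fully synthetic fixture
    generator (foot-like surfaces with an embedded bone core, 16 named
    landmarks, smooth ground-truth deformation fields, two-lobed pressure maps)
    so the whole pipeline can be exercised without proprietary scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
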