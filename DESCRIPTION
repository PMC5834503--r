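Package: smlmq
Title: Quantitative Analysis of Labeling Quality in Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing and quantification toolkit for single-molecule
    localization microscopy (dSTORM/PALM) experiments that assess labeling
    quality. Covers fiducial-based drift correction, NeNA localization
    precision estimation, blink merging, image reconstruction and Fourier
    ring correlation (FIRE) resolution; filament width (FWHM) and lengthwise
    coverage morphometry with chi-square category statistics; DBSCAN-based
    cluster quantification; a binomial/log-normal stoichiometry model for
    completeness-of-labeling estimation on homo-oligomeric counting
    standards; and MSD-based single-particle mobility classification.
    Includes a ground-truth-annotated synthetic data generator emulating
    blinking emitters on filaments, clusters, fiducial beads under drift,
    oligomer intensity traces and Brownian membrane trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
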