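Package: cccfp
Title: Texture and Structure Analysis of Copper Chloride Crystallisation Fingerprints
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating copper chloride crystallisation (CCC)
    fingerprints of plant extracts: grey-level co-occurrence texture
    variables (kappa, diagonal_moment, entropy, cluster_shade and the
    standard second-order set), skeleton-based needle morphometry (endpoint
    counts and length/width histograms including lend, l220, l250),
    systematic-control-driven block randomisation with counterbalanced
    rotation, and a three-sensitivity-test statistical evaluation based on
    four-way fixed-effects ANOVA, protected Fisher's LSD and Cohen's d.
    Includes a synthetic dendritic-fingerprint simulator so the complete
    pipeline can be exercised and calibrated without laboratory scans.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
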