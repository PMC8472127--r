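Package: effiq
Title: Effective Image Quality Metrics for Radiographic Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measurement pipeline for effective (whole-system) image quality
    metrics of projection radiography: slanted-edge effective modulation
    transfer function (eMTF), effective normalised noise power spectrum
    (eNNPS) from flat-field images, beam-stop scatter fraction, phantom
    transmission factor and air-kerma geometry for slot-scan and cone-beam
    systems, photon fluence per air kerma (q) from an X-ray spectrum, and
    their composition into effective noise equivalent quanta (eNEQ) and
    effective detective quantum efficiency (eDQE). Includes a synthetic
    radiograph generator with closed-form ground truth for validation, and
    rank-based (Kruskal-Wallis / Mann-Whitney) comparison of metric curves
    across systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
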