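Package: relaxiq
Title: In Vivo Iron Relaxivity Mapping from Quantitative MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing molecular iron environments in tissue from
    quantitative MRI relaxation maps. Implements forward simulation of
    spoiled-gradient-echo and inversion-recovery signals for iron-containing
    phantoms and brain-like labelled volumes, estimation of R1, R2*, R2,
    macromolecular tissue volume (MTV) and magnetization-transfer saturation
    (MTsat) maps, iron-relaxivity linear models, a binned region-of-interest
    estimator of the R1-versus-R2* relaxivity, voxel-wise sliding-window
    relaxivity maps, conversion of iron-binding-protein concentrations to
    elemental iron, and the statistical battery (slope-homogeneity ANCOVA,
    regression F-tests with FDR correction, paired effect sizes,
    Kolmogorov-Smirnov contrasts) used to validate the relaxivity contrast
    against postmortem iron-homeostasis markers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
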