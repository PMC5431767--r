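Package: paleoenamel
Title: Discriminating Enamel Hypomineralisation from Post-Mortem Staining in Archaeological Teeth
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Micro-CT grey-level densitometry and X-ray-fluorescence screening
    pipeline for deciding whether a discoloured enamel area on an archaeological
    tooth is an ante-mortem hypomineralised lesion (MIH/HSPM) or post-mortem
    taphonomic staining. Provides a 16-bit volume data model with reslicing and
    transect extraction, five-cube paired densitometry with a Wilcoxon
    signed-rank test, 99-point dento-enamel-junction-to-surface density
    profiles with gradient-direction classification, paired elemental
    (Mn/Fe/Cu/Pb) enrichment screening, a rule-based differential diagnosis,
    and a synthetic enamel-phantom generator with known ground truth for
    end-to-end validation. Includes self-contained exact and
    normal-approximation Wilcoxon signed-rank tests and Fleiss' kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
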