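Package: ioertdose
Title: Intraoperative Electron Radiotherapy Dose-Scenario Comparison on CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify how the air gap between an IOERT applicator and
    the tumour-bed surface, and tissue heterogeneity, affect intraoperative
    electron radiotherapy dose distributions. Builds the five classic CT dose
    scenarios (intraoperative gold standard, water-equivalent assumption,
    registered preoperative CT, and both updated with the segmented air gap)
    from paired pre/intraoperative CT volumes via rigid bone-based NMI
    registration, Hounsfield-window region growing, and applicator pose
    recovery, computes 3D electron dose with a divergent pencil-beam engine,
    and compares scenarios with 3D gamma analysis (3%/3 mm, global
    normalisation). Includes a synthetic CT phantom generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
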