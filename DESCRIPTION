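Package: orthoTrack
Title: Marker-Less Target Tracking with Orthogonal kV Imaging and Linear Motion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for marker-less tracking of abdominal targets (pancreas) on the
    orthogonal kilovoltage imager pair of a robotic radiotherapy system. Implements
    ray-traced digitally reconstructed radiographs, bandpass sharpening, fiducial
    removal and intensity equalization, coupled and subregion grid-search image
    registration scored by a product of normalized mean-square and normalized
    mutual information objectives, inter- and intra-fraction linear motion models
    solved by truncated singular value decomposition with leave-one-out cross
    validation, a daily-volumetric-imaging scenario, and stochastic accumulation of
    residual tracking error onto a synthetic multi-beam dose distribution with
    dose-volume-histogram reporting. A digital abdomen phantom generator provides
    cohorts with known ground-truth motion for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml, tiff, png, RNifti
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
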