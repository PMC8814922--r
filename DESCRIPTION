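Package: brightpath
Title: Image-Based TMS Target Planning, Coil-Pose Geometry, and Trial Power Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans transcranial magnetic stimulation (TMS) treatment targets
    from resting-state fMRI: selects the left central-executive-network
    component, maps effective connectivity from the right anterior insula into
    the left middle frontal gyrus with a bivariate first-order Granger
    causality analysis, and takes the peak z-score voxel as the
    connectivity-guided target. Converts brain targets into neuronavigation
    coil poses through a fiducial-based nasion-left-right (NLR) head frame,
    scalp-mesh projection, and a 45-degree coil angulation rule, exporting
    rotation matrices as unit quaternions. Also provides BOLD motion quality
    control based on framewise displacement, MEGA-PRESS edited-spectroscopy
    preprocessing (eddy-current correction, spectral registration, outlier
    rejection, linewidth and SNR gates), repeated-follow-up and Fisher-z
    correlation power calculators, and synthetic-fixture generators with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
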