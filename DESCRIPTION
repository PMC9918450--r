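Package: gaitspm
Title: Statistical Parametric Mapping of Gait Trajectories with Clinical Severity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and grades deviations of a patient's lower-limb gait
    trajectories (joint moments and kinematics) from a normative reference
    using one-dimensional Statistical Parametric Mapping. Univariate t fields
    and multivariate Hotelling's T-squared fields are thresholded family-wise
    by Random Field Theory, with a nonparametric permutation alternative.
    Supra-threshold deviations are summarised as fold-of-threshold severity
    maps suitable for clinician-facing colormap displays. Includes readers and
    writers for a simple per-component CSV trajectory format (101 nodes per
    gait cycle), time normalisation, body-weight scaling and sign-convention
    flipping, a synthetic gait-trajectory generator for calibration and power
    studies, and a command-line interface for batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
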