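Package: nailsim
Title: Virtual Straight Antegrade Humeral Nailing Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates straight antegrade humeral nail insertion on triangle
    surface meshes of the humerus and scapula. Estimates the medullary canal
    axis, constructs the optimal entry point on the humeral head (with the
    5-mm supraspinatus-footprint safety rule), places a virtual 8-mm nail,
    poses the arm for transdeltoid (0 degrees extension) and anterolateral
    (30 degrees extension) approaches, and detects implant-acromion collision
    with an exact triangle-mesh contact test. Measures the Acromion Index
    (GA/GH) from the glenoid reference plane, and provides the cohort-level
    statistics used in approach-comparison studies: paired McNemar tests,
    absolute risk reduction and number-needed-to-treat, Fisher/Woolf odds
    ratios, logistic regression with interaction screening, ROC analysis with
    Youden threshold selection and percentile-bootstrap internal validation,
    Cohen's kappa and two-way mixed intraclass correlation coefficients.
    Includes a parametric synthetic shoulder and cohort generator with
    analytic ground truth, so every pipeline stage is testable without CT
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
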