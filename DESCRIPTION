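Package: anthrofit
Title: Anthropometric Body Measurements from Template Meshes and
    Height-Weight Linear Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts standard anthropometric body measurements (lengths
    and circumferences) from watertight triangle meshes in the SMPL
    template topology via a fixed landmark registry and plane slicing,
    estimates body weight from mesh volume under a Gaussian self-report
    noise model, fits per-sex closed-form linear regressions of every
    measurement on height and weight (optionally augmented with BMI and
    other interaction terms), and evaluates predictions with mean
    absolute error, mean relative error, and the fraction of subjects
    within expert allowable error. Includes a synthetic-fixture
    generator producing procedural humanoid meshes with closed-form
    ground truth and per-sex populations with known linear structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    lmtest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
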