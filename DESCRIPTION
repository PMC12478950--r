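Package: bimanum
Title: Bilateral Upper-Limb Model Construction and Bimanual Load Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bilateral upper-extremity musculoskeletal models from a
    unilateral OpenSim 3.3 model by mid-sagittal mirroring of bone meshes,
    body frames, joint definitions and muscle paths; parameterizes graded
    unilateral rotator-cuff-tear severities as peak-isometric-force scaling;
    attaches bimanual shared loads between the hands; generates a battery of
    static and dynamic bimanual tasks; resolves muscle redundancy per time
    step with a bounded static-optimization solver carrying explicit torque
    slack; and computes compensation outcomes (time-averaged normalized
    muscle force, severity and load contrasts) and load-position deviation
    summaries, together with kinematic symmetry verification by RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
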