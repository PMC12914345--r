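Package: letplan
Title: Proton Therapy Plan Optimization with LET and Robustness Objectives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intensity-modulated proton therapy (IMPT) planning
    research on synthetic voxel phantoms. Provides an analytical pencil-beam
    dose and linear-energy-transfer (LET) influence engine, three spot-weight
    optimization strategies (nominal, objective-wise worst-case robust, and
    dose-averaged-LET-aware), a nine-scenario setup/range uncertainty model,
    variable proton RBE and LET-weighted biological dose evaluation, and
    dose-volume/LET-volume histogram and robustness-bandwidth reporting.
    Phantom generators emulate pediatric brain anatomies in which the target
    volume wraps around, abuts, or extends inferiorly past the brainstem.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
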