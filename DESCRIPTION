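Package: pvsim
Title: Patient-Ventilator Interaction Simulation, Asynchrony Labeling, and
    Inspiratory Muscle Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-loop simulation of a single-compartment active respiratory
    system coupled to a ventilator with trigger, pressurization and cycling
    logic; a deterministic battery of labeled patient-ventilator asynchrony
    scenarios with gold-standard inspiratory muscle pressure (Pmus); a
    rule-based per-breath asynchrony classifier (ineffective effort,
    auto-triggering, double-triggering, reverse triggering with and without
    double cycling, premature and delayed cycling); noninvasive Pmus
    estimation from airway pressure, flow and volume by equation-of-motion
    inversion plus a small recurrent-network estimator trained on synthetic
    data; and rater-trial statistics (stratified randomization, answer-key
    scoring into sensitivity and specificity, normality-gated two-group
    comparison, and two-sample t-test power and sample-size computation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
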