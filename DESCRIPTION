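Package: neoloop
Title: In-Silico Closed-Loop Glucose Control Trials in Extremely Preterm Infants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Virtual randomised trials of closed-loop (model predictive
    control) insulin and 20% dextrose delivery guided by continuous glucose
    monitoring in extremely preterm infants. Provides a glucose-insulin
    compartment model of the preterm infant with stochastic insulin
    sensitivity, a CGM sensor error and calibration model, an adaptive
    model predictive controller with low-glucose dextrose rescue, a
    reconstructed nurse-executed guideline comparator, Pocock-Simon
    minimisation for arm assignment, trial orchestration, and the glycaemic
    outcome statistics (time in range, hypoglycaemia episodes, Mann-Whitney
    and t tests) used to summarise such trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
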