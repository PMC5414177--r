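Package: cdksizer
Title: Size-Dependent CDK Cell-Cycle Models and Lineage Statistics for
    Dividing Plant Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of cell-size homeostasis in dividing
    plant tissues such as the Arabidopsis shoot apical meristem. Cells grow
    exponentially and progress through the cell cycle by accumulating
    cyclin-dependent kinase (CDK) activity to threshold levels; making CDK
    production proportional to cell size (or thresholds inversely
    proportional to it) turns a timer cycle into a sizer/adder cycle.
    Provides one- and two-transition (G1/S and G2/M) model variants, a
    calibration procedure that solves production rates for target birth and
    division sizes and G1 fraction, scripted perturbation experiments
    (uneven divisions, growth-rate and CDK-production changes, fold scans
    with a loss-of-control classifier), lineage-table statistics used on
    tracked meristem cells (relative growth rate, inferred phase lengths,
    sister-pair asymmetry and the exact binomial convergence test), and a
    synthetic lineage-table generator so every analysis is testable without
    imaging data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
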