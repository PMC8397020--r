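Package: boldperf
Title: Reperfusion BOLD-MRI Skeletal Muscle Perfusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of cuff-occlusion reperfusion BOLD-MRI
    examinations of the lower limb. Generates synthetic multi-echo
    gradient-echo phantom series following a rest/occlusion/reperfusion
    cuffing paradigm, estimates dynamic T2* maps by weighted least-squares
    fitting of the exponential signal decay over echoes, corrects subject
    motion by translation registration and propagates regions of interest,
    extracts ROI-mean T2* time curves, computes reactive-hyperemia curve
    descriptors (baseline T2*, hyperemia peak value, time to peak,
    overshoot), and compares feature distributions between patient and
    control groups with Mann-Whitney U tests and Spearman rank correlations
    against the ankle-brachial index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
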