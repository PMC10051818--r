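Package: trajsafe
Title: Trajectory Safety Scoring and Cohort Simulation for Navigated Brain Biopsy Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric safety assessment of planned stereotactic biopsy
    trajectories against neuroanatomical structures (corticospinal-tract
    streamlines, vessels, sulci, eloquent cortex, ventricles, midline),
    a four-component Trajectory Safety Index, seeded generators for
    synthetic neuroanatomical scenes and a calibrated behavioural cohort
    of trainee planning sessions, and the cohort statistics that compare
    tractography-enhanced with anatomy-only planning: group comparisons,
    experience-adjusted regressions, learning-curve trends, and
    graph-based clustering of planning profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
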