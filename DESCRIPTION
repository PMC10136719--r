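Package: adaptgait
Title: Simulation and Analysis of Assist-as-Needed Robotic Gait Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying assist-as-needed robotic gait training at desk
    scale. Implements a windowed impedance controller that adapts normalized
    joint stiffness and damping to a patient's trajectory-tracking error over
    30 gait-cycle windows, a synthetic rehabilitation cohort simulator
    (heterogeneous impairment, multi-week training schedules, walking and
    isometric-force assessments), per-subphase feature extraction with
    exponential-decay plateau estimation, and the accompanying statistical
    pipeline: paired support comparison, forward and elastic-net variable
    selection, Bland-Altman and Spearman reliability, force-versus-control
    clustering, and cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
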