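Package: fearcond
Title: Simulation and Analysis of Differential Fear Conditioning with
    Imagined Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for differential fear-conditioning experiments in which
    conditioned stimuli are either viewed or imagined. Generates the
    constrained habituation and acquisition trial schedules of a two-phase
    (imagery/visual) 50%-reinforcement design, simulates skin-conductance
    traces, trial-wise ROI voxel patterns, BOLD run time series and Likert
    ratings with controllable effect sizes, scores skin-conductance
    responses by baseline-to-peak amplitude, estimates trial-wise GLM
    parameter patterns with a double-gamma haemodynamic response function,
    performs ROI multivoxel cross-classification with per-participant
    label-permutation nulls and a group-level bootstrap null, and computes
    the accompanying repeated-measures ANOVA, paired t with Cohen's d and
    Jeffreys-Zellner-Siow Bayes factor statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
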