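Package: somnoblast
Title: Sleep EEG/EMG Staging, Spindle Detection and Behavioral Scoring
    for Rodent Blast-Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Longitudinal sleep and behavior analysis pipeline for
    blast-injured mice. Extracts multitaper band powers (delta, theta,
    alpha, beta, gamma) from two-channel EEG/EMG telemetry sampled at
    500 Hz, classifies 5-second epochs into awake/NREM/REM with
    threshold rules calibrated on robust scale statistics, detects NREM
    sleep spindles on 10-20 Hz band-passed traces and computes their
    amplitude, cycle count, intra-spindle frequency, symmetry and
    density, stratifies injured subjects into high- and low-delta/alpha
    cohorts by K-means, scores novel-object-recognition, Y-maze,
    rotarod and balance-beam assays with the published exclusion rules,
    and runs the nonparametric statistics battery (Mann-Whitney,
    Kruskal-Wallis with Dunn-Bonferroni, Friedman with Wilcoxon).
    Includes a synthetic EEG/EMG/behavior generator with full ground
    truth for validating every stage, plus EDF and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
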