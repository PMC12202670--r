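Package: aafkit
Title: Auditory Cortex Receptive Fields, Temporal Coding, and Neural
    Speech Discrimination in Nested Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for multi-unit auditory cortex
    recordings from nested rodent cohorts (sites within animals within
    experimental groups), built around a valproic-acid exposure /
    vagus-nerve-stimulation pairing design. Constructs the acoustic and
    electrical stimulus set (tone-pip frequency-by-level grids, periodic
    noise-burst trains, consonant-vowel speech proxies, VNS pulse trains
    and pairing schedules), simulates trial-structured spike responses
    with configurable group effect structure (gain, latency shift,
    per-burst adaptation, phase jitter), and extracts the standard
    physiology metrics: frequency response areas with characteristic
    frequency, threshold and bandwidths, onset and peak latency,
    rate-level functions, vector strength and Rayleigh phase-locking
    statistics, paired-pulse ratios, speech-window driven activity, and a
    leave-one-out PSTH template classifier for consonant discrimination.
    Group comparisons use nested linear mixed models with Type II Wald
    chi-square tests and Tukey-adjusted estimated marginal means;
    behavioral go/no-go sessions are scored and compared with repeated
    measures ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    glmmTMB,
    car,
    emmeans,
    nortest
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
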