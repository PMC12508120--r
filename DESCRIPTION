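Package: prldecode
Title: Simulation and Neural Decoding Analysis for Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-aligned calcium-imaging data recorded
    during probabilistic reversal learning. Includes a task and agent
    simulator that generates committed-trial event tables and event-locked
    fluorescence traces with planted side-, outcome- and reward-retrieval-
    selective neurons; epoch extraction with overlapping-bin temporal
    downsampling; balanced leave-one-trial-out linear (SVM) decoding of
    chosen side and trial outcome with circular-shift label nulls and
    beta-ranked cell ablation; per-cell selectivity linear models and
    cross-validated peak-aligned difference heatmaps; behavioural strategy
    metrics (win-stay, lose-shift, perseveration and flexibility indices,
    latency medians); and design-matrix builders with mixed-effects model
    fitting linking behaviour to decoding accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
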