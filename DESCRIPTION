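Package: fuccitrack
Title: Cell-Cycle Phase Lengths and Lineage Statistics from FUCCI Time-Lapse Tracking
Version: 0.1.0
Authors@R:
    person("Lineage", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse single-cell cell-cycle dynamics from FUCCI
    (Fluorescent Ubiquitination-based Cell Cycle Indicator) time-lapse tracking
    data of clonal colonies, such as mouse embryonic stem cells in ground-state
    ('2i+LIF') versus differentiation medium. Reads per-frame tracking tables,
    extracts per-cell cycle length (CC-L), G1 length (G1-L, birth to the
    hCdt1-mCherry maximum) and S/G2/M length (SG2M-L) with right-censoring
    bookkeeping, reconstructs lineage forests, estimates Kaplan-Meier survival
    curves and per-generation medians with log-rank tests, computes
    colony/generation-stratified bootstrap Spearman correlations for sister,
    mother-daughter and cousin pairs together with the simple-inheritance
    inequality, runs Grassberger-Procaccia correlation-dimension analysis with
    shuffle surrogates, and quantifies trajectory and colony morphology
    (speed, convex-hull exploration, colony area/density, peripheral cells).
    A synthetic lineage generator with heritable phase durations emulates the
    data structure so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
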