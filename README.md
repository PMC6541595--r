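# fuccitrack

Cell-cycle phase lengths and lineage statistics from FUCCI time-lapse
tracking data.

## What this is for

Live imaging of cells carrying the FUCCI reporter pair (hCdt1-mCherry marking
G1, hGeminin-mVenus marking S/G2/M) plus a nuclear marker lets you follow
every cell in a colony from birth to division. Given per-frame tracking
tables (one row per cell per frame, as exported by nuclear-tracking tools),
`fuccitrack` quantifies how the cell cycle is structured and inherited in
clonal colonies — the motivating system is mouse embryonic stem cells in
ground-state self-renewal (`2i+LIF`) versus early differentiation — without
you writing any of the statistical plumbing:

* **Phase extraction.** Per cell: cycle length CC-L (birth to division, both
  placed at frame-midpoint division events), G1-L (birth to the mCherry
  maximum, called on a smoothed-then-refined trace), SG2M-L = CC-L − G1-L,
  generation number, fate, and right-censoring bookkeeping for cells that
  outlive the movie.
* **Censoring-aware survival statistics.** Kaplan–Meier curves
  S(t) = ∏ (1 − dᵢ/nᵢ) per condition × generation with Greenwood
  log(−log) confidence bands, medians inf{t : S(t) ≤ 0.5}, log-rank tests,
  Mann–Whitney comparisons — because complete-cell medians are biased short
  near the end of a finite movie.
* **Lineage correlations.** Sister / mother-daughter / cousin Spearman
  coefficients with a colony- and generation-stratified bootstrap (rank
  centering within strata, two-level colony→pair resampling), and the
  simple-inheritance test Δ = ρ_cc − ρ²_md·ρ_ss with joint replicates.
* **Determinism analysis.** Grassberger–Procaccia correlation dimension of
  phase variables embedded along (grandmother, mother, daughter) chains,
  against within-stratum shuffle surrogates.
* **Motility and morphology.** Per-cell speed (path/CC-L) and exploration
  (trajectory convex-hull area/CC-L), colony area and density over time,
  and center-versus-periphery classification.
* **A synthetic lineage generator** that emulates the whole data structure
  (heritable log-normal phase durations, FUCCI-shaped traces, colony-confined
  motion, rare apoptosis, window censoring) so the entire pipeline runs and
  is tested with no external data.

See `vignettes/fuccitrack-methods.Rmd` for the model, the estimators, every
tunable default and the generator's assumptions.

## Worked example

```r
library(fuccitrack)

p   <- sim_params(seed = 101, n_colonies = 12)   # the stated default world
tab <- simulate_experiment(p)                    # both conditions, per-frame table
rec <- extract_records(tab)                      # per-cell cycle database

table(rec$condition, rec$fate)
#>                APOPTOSIS CENSORED_END DIVIDED
#>   DIFF                 6          512     458
#>   GROUND_STATE        17          392     349

median(rec$CC_L_h[rec$complete & rec$condition == "GROUND_STATE"])  # 13
median(rec$CC_L_h[rec$complete & rec$condition == "DIFF"])          # 10.75
```

Ground-state cells cycle in ~13 h while differentiating cells accelerate to
~10.75 h (complete cells only; the generator's calibration targets are
13.25 h and ~10.5 h). Mann–Whitney confirms the shift
(`mann_whitney(...)$p` ≈ 3e-34). Per-generation Kaplan–Meier medians show
the progressive shortening that complete-cell medians alone understate:

```r
km_median_by_generation(rec, "CC_L", "DIFF", min_n = 20)
#>   generation   n n_events median ci_low ci_high
#> 1          2 115      115  12.25  11.25   12.50
#> 2          3 229      197  11.25  10.75   11.50
#> 3          4 393       84   9.75   9.50   10.25
#> 4          5 168        3     NA   9.00      NA
```

(The generation-5 median is "not reached" at this 12-colony scale — only 3
divisions were observed; larger runs pin it near 9.5 h.) Sister cells are
strongly correlated in G1 length, estimated with the stratified bootstrap on
the differentiating arm:

```r
recd <- rec[rec$condition == "DIFF", ]
pv <- pair_values(enumerate_pairs(build_forest(recd), recd, "SISTER"),
                  recd, "G1_L")
bootstrap_corr(pv, n_boot = 2000, seed = 7)
#> <bootstrap_corr> SISTER G1_L: rho = 0.578 [0.405, 0.71], p = 0.001 (188 pairs, 2000 reps)
```

The generator's latent sister correlation is 0.8; the estimate from extracted
traces is attenuated by peak-call noise (the same 188 pairs scored on the
generator's truth values give 0.68, and at ≥500 pairs the estimator recovers
the target within ±0.1 — the acceptance suite checks this). A full bundle — records, KM curves,
correlations, determinism verdicts, motility, manifest with seeds and hashes —
comes from one call:

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

or from the CLI: `Rscript inst/scripts/fuccitrack run-all --out out --seed 1`
(subcommands `simulate`, `extract`, `pairs`, `survival`, `correlate`,
`determinism`, `motility`, `colony` run stages individually).

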