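# predlook

Anticipatory-looking analysis for two-picture preferential-looking tasks
recorded with webcam eye-trackers.

## What it is for

In a preferential-looking task a listener sees a target and a distractor
picture while hearing a sentence such as "The woman read the book".  When
the verb constrains the upcoming noun, listeners who *predict* fixate the
target before the noun is spoken.  `predlook` implements the complete
analysis chain for studies of this effect across sentence conditions
(closely related verb CV, moderately related verb MV, unrelated verb UV)
and participant groups (e.g. typically developing children, young people
with Down syndrome, adults):

- **Design & geometry** — counterbalanced 28-trial sessions (7 CV / 7 MV /
  14 UV from a 56-sentence inventory, each image pair once per
  participant) and screen-proportional area-of-interest scaling for
  heterogeneous displays (`build_design`, `scale_aoi`).
- **Preprocessing** — gap-aware Gaussian smoothing (σ = 5 samples),
  linear interpolation onto a 20 ms grid with a strict >150 ms
  no-reconstruction rule, half-open AOI coding, 100 ms binning into
  target-fixation counts *F* of AOI samples *N*, and exclusion of trials
  with <25% looking (`preprocess_cohort`).
- **Growth-curve analysis** — weighted mixed models of the empirical
  log-odds log((F + ½)/(N − F + ½)) over 4,000–6,000 ms with third-order
  orthogonal polynomial time terms, condition × group dummy coding (UV/TD
  reference), and a deterministic maximal-random-structure back-off
  (`fit_gca`).
- **Cluster-mass permutation tests** — per-bin paired and chance-level
  (0.5) t series over 0–6,000 ms, clusters of adjacent |t| above the
  α = .05 critical value, max-cluster-mass sign-flip null with 100,000
  iterations (`permutation_test`, `cluster_report`).
- **Prediction-window models** — per-trial F/N aggregated over
  2,500–4,000 ms, binomial mixed models with min–max-normalized
  ([−0.5, 0.5]) covariates, χ²(3) model comparison and BIC-approximate
  Bayes factors with the 0.33 / 3 evidence bounds (`fit_window_model`,
  `compare_models`, `bic_bayes_factor`).
- **Stimulus norming** — restricted-association scoring, Kruskal–Wallis
  and Mann–Whitney statistics with tie/continuity corrections, and a
  packaged item-level association-strength table (`score_association`,
  `mann_whitney`, `association_table`).
- **Synthetic gaze** — a generative model of webcam recordings (logistic
  target-preference curves, ~60 Hz jittered sampling, 100 px noise,
  missing runs, per-subject random effects) for download-free testing and
  calibration (`generate_cohort`).

See `vignettes/anticipatory-looking.Rmd` for the underlying models and the
design decisions.

## Worked example

Simulate a Down-syndrome-like cohort (21 subjects, prediction only in the
CV condition, +200 ms onset shift), preprocess, and test:

```r
library(predlook)

coh  <- generate_cohort(21, "DS",
                        params_by_condition = default_sim_params("cv_only"),
                        seed = 42)
bins <- preprocess_cohort(coh$gaze, coh$design)

rep <- cluster_report(bins, n_perm = 5000, seed = 1)
subset(rep, significant)
#>  group  contrast start_ms end_ms  mass t_max     p
#>     DS     CV-UV     2500   6000 275.8 15.43 2e-04
#>     DS CV-chance     2500   6000 854.6 70.80 2e-04
#>     DS MV-chance     4700   6000 119.9 17.20 2e-04
#>     DS UV-chance     4500   6000 166.0 20.80 2e-04

fit <- fit_window_model(aggregate_window(bins))
fit$coefficients
#>         term estimate     SE statistic        p
#>  (Intercept)   0.0692 0.0581      1.19 2.34e-01
#>  conditionCV   1.7005 0.1446     11.76 6.09e-32
#>  conditionMV  -0.1620 0.0931     -1.74 8.17e-02
```

The cluster report shows the generated structure: CV pulls away from UV
well before the noun (2,500 ms), while MV and UV only rise above chance
after it.  In the prediction window the CV term is reliably positive
(z = 11.8) and MV is not distinguishable from UV — the signature of
prediction restricted to strongly associated verbs.  `fit_gca(bins)`
prints the corresponding growth-curve coefficient table.

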