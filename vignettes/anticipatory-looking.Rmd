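---
title: "Modelling anticipatory looking in two-picture preferential-looking tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anticipatory looking in two-picture preferential-looking tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predlook)
```

## The scientific problem

In a two-picture preferential-looking task a listener sees a target and a
distractor picture while hearing a sentence.  If the verb constrains the
upcoming direct object ("The woman *read* the ..."), listeners who predict
will fixate the target *before* the noun is spoken.  `predlook` implements
the full analysis chain for such experiments run with webcam eye-trackers:
noisy (~100 px), irregularly sampled (~60 Hz) gaze with missing runs, on
heterogeneous screens.

The session design is fixed: 28 sentences per participant -- 7 with a
closely related verb (CV), 7 with a moderately related verb (MV), 14 with an
unrelated verb (UV) -- drawn from a 56-sentence inventory so that each
target/distractor image pair appears exactly once per participant, in four
counterbalanced orders.  Each 8,000 ms trial shows a fixation point for
1,000 ms, then the two pictures for 6,000 ms.  All analysis is on *relative*
time (0 = picture onset); the verb arrives at 2,000 ms and the noun at
4,000 ms relative.

## Preprocessing model

Raw samples go through a fixed chain, each step separately testable:

1. **Gaussian smoothing** (`smooth_gaussian`), kernel sigma of 5 samples at
   the native rate, truncated at 4 sigma.  The kernel is renormalized over
   the valid neighbours at every sample, so missing runs neither absorb nor
   leak signal.  The sigma is interpreted in samples; a millisecond
   interpretation would be `sigma_ms / period`, and sigma is a parameter if
   another convention is wanted.
2. **Interpolation and resampling** (`interpolate_resample`) onto a 20 ms
   (50 Hz) grid.  Linear interpolation only; no extrapolation beyond the
   first/last valid sample; missing runs strictly longer than 150 ms
   (measured between the flanking valid samples) are left missing.  The
   boundary is deliberately strict-greater-than: a run of exactly 150 ms is
   still bridged.
3. **AOI coding** (`code_aoi`).  Each picture's area of interest is one
   960 x 1080 half of the 1920 x 1080 reference screen, rescaled to the
   participant's screen width and height independently (`scale_aoi`); the
   stored AOI "location" is the box *center*, so a 480 x 540 center on the
   reference becomes 400 x 600 on a 1600 x 1200 display.  Boxes are
   half-open (left/top edge inside) so adjacent AOIs can tile the screen
   without double-coding.
4. **Binning** (`bin_series`): half-open 100 ms bins over relative
   0--6,000 ms.  Per bin, `F` counts target fixations and `N` counts AOI
   fixations (target + distractor).  **`N` is AOI samples, not all valid
   samples**: a valid sample outside both AOIs reduces `N`.  This makes
   chance exactly 0.5 in the two-AOI display, which the chance-level cluster
   tests rely on; it is the resolution we adopted for an ambiguity in how
   "total fixations in the bin" can be counted.
5. **Exclusion** (`exclude_trials`): a trial is dropped when the AOI-looking
   fraction over 0--6,000 ms is below 25% (strict less-than) of the 300 grid
   points.

Bins with `N = 0` are dropped, never imputed.

## Growth-curve analysis

`fit_gca` models the per-bin empirical log-odds of target fixation,
`log((F + c) / (N - F + c))` with the empirical-logit correction `c = 0.5`
by default (`c = 0` gives the raw log-odds, finite only off the boundary),
over the 4,000--6,000 ms window.  Time is a third-order orthonormal
polynomial basis (`orthogonal_time_basis`, equivalent to Gram--Schmidt on
t, t^2, t^3), so linear/quadratic/cubic terms are uncorrelated.  Condition
and group are dummy coded with UV and TD as references.  The window default
follows the printed analysis window; because the source description is
ambiguous about whether it starts at the verb (2,000 ms relative), the
window is an argument.

The estimation backend is a linear mixed model (`lme4::lmer`, ML) on the
empirical log-odds weighted by `N`.  The original analysis of this design
family used a penalized-quasi-likelihood binomial fit; we use the
aggregated-logit formulation instead because it is deterministic,
well-supported, and standard for fixation time-courses.  Consequences:
coefficients are on the same logit scale and share signs and approximate
magnitudes with a quasi-binomial fit, but standard errors and the (very
large) residual degrees of freedom are backend conventions, not comparable
across software.  p-values use the t distribution at the residual df, with
the normal approximation beyond df 1000.

Random effects follow "maximal that converges": all polynomial slopes by
subject plus a by-item intercept, backed off deterministically
(`random_structure_backoff`: drop cubic, then quadratic, then linear slope,
then intercepts only).  The structure actually used, and the convergence
trail, are reported in the fit's provenance.

## Cluster-mass permutation tests

`permutation_test` operates on subject-level curves (per-subject mean
proportion per 100 ms bin; subjects, not trials, are the exchangeable
unit).  Per bin a paired t (CV or MV against UV) or one-sample t against
chance 0.5 is computed; clusters are maximal contiguous same-sign runs with
|t| above the critical value (`critical_t_for`: two-tailed Student quantile
at n - 1 df, with an override knob for reproducing a published threshold
under another df convention).  The cluster statistic is the summed t
("mass").  The null records the maximum |mass| per iteration after
independent per-subject sign flips -- for the paired test this is exactly a
random swap of condition labels within subject.  p-values use the add-one
estimator (1 + exceedances) / (n_perm + 1), so they are never exactly zero,
and permuted masses tied with the observed mass (to within floating-point
jitter) count as exceedances.  Clustering is two-sided with sign-separated
clusters because reversed effects (more looking in UV) are real outcomes in
this design.  Bins with undefined t (fewer than two complete pairs, or zero
variance) break contiguity.  The default is 100,000 iterations; the
calibration suites use 2,000.

## Prediction-window models

`aggregate_window` sums `F` and `N` per trial over 2,500--4,000 ms relative
(half-open, so the 4,000 ms bin is not shared with the growth-curve
window): after the verb, before the noun.  `fit_window_model` fits an
aggregated binomial mixed model (`lme4::glmer`, logit link) -- `F` of `N`
is likelihood-equivalent to the per-sample binary form up to a constant --
with condition fixed effects (UV reference), random condition slopes by
subject and a by-item intercept, backed off to plain intercepts on
non-convergence.  Continuous covariates are min-max normalized to
[-0.5, 0.5] (`minmax_center`) and enter as a main effect plus
covariate x condition interactions.  `compare_models` refers the deviance
drop to chi-squared with 3 extra df (one main effect + two interaction
dummies); `bic_bayes_factor` uses the BIC approximation
`exp((BIC_ref - BIC_ext) / 2)` with the conventional 0.33 / 3 evidence
bounds.

## The synthetic gaze generator

Raw recordings for this paradigm are typically not shareable, so the
package carries a generative model (`sim_params`, `sample_trial`,
`generate_cohort`) that emulates the *structure* the analysis assumes:

- a logistic target-preference curve
  `p(t) = b + (a - b) / (1 + exp(-(t - c)/s))` with baseline `b = 0.5`
  (chance before disambiguation), condition-specific asymptote and
  crossover, and a per-group horizontal onset shift (default +200 ms for
  the Down-syndrome group, matching the reported anticipation delay);
  the UV crossover is anchored after noun onset (default 4,800 ms).
  A logistic is the minimal monotone curve with the right
  rise-after-cue shape; the defaults (CV: a = 0.80, c = 2,800 ms; MV:
  a = 0.75, c = 3,100 ms; UV: a = 0.75, c = 4,800 ms; s = 250 ms) were
  chosen once to reproduce the qualitative CV > MV > UV pre-noun ordering,
  not any published number;
- ~60 Hz sampling with jittered periods (mean 16.7 ms), 100 px Gaussian
  positional noise, off-AOI looks (probability 0.15, uniform over a 200 px
  frame outside both AOIs), and missing runs with Bernoulli starts
  (0.005 per sample) and geometric lengths (mean 300 ms) -- gaps exist in
  webcam data but only their maximum bridgeable length is documented, so
  the gap process is a modelling choice;
- Gaussian per-subject random effects on the crossover (sd 150 ms) and the
  logit asymptote (sd 0.3), and per-subject screens drawn from common
  display sizes;
- one base seed split per subject and trial by counter, so any subject
  subset regenerates identically.

What the generator does **not** emulate: saccade dynamics, smooth pursuit,
calibration drift, pupilometry, or autocorrelated fixation runs (samples
are conditionally independent given the curve).  One visible consequence:
Gaussian smoothing of conditionally independent samples acts like a local
majority vote, so the *observed* asymptote after preprocessing sits above
the generating one.  Calibration results on synthetic data therefore show
that the machinery is correct and calibrated under the stated structure,
not that real webcam data meet that structure.

## Numerical choices and degenerate inputs

- Half-open conventions everywhere (bins, AOI edges, analysis windows) for
  deterministic tie-breaking.
- Empirical-logit correction `c = 0.5` by default; configurable, `c = 0`
  reproduces the uncorrected formula.
- Zero-variance bins give undefined t and break clusters rather than
  yielding infinities; empty trials (no valid samples) are flagged and
  skipped; constant covariates are an error for min-max scaling.
- Permutation p-values can never be 0; ties with the observed mass count
  as exceedances.
- Mixed-model convergence failures walk a deterministic back-off ladder and
  the chosen structure is recorded; an exhausted ladder is an explicit
  error listing every attempt.

## Problem sizes used by the test and acceptance suites

Simulation-based checks use study-sized cohorts (21 subjects x 28 trials)
with 500 replicates at 2,000 permutations for the cluster-test type-I rate,
100 replicates for prediction-window pattern recovery, and 100 small
cohorts for curve parameter recovery; these sizes give binomial Monte-Carlo
error comfortably inside the asserted bands while keeping a full run in the
tens of minutes on one core.  The window-model replicate fits use the fast
`nAGQ = 0` integration setting; single fits default to the Laplace
approximation.

## Known limitations

- The growth-curve backend is the aggregated weighted-logit approximation,
  not PQL; published coefficient tables from PQL fits are comparable in
  sign and rough magnitude only.
- Association-strength statistics on the packaged norming table are
  item-level; respondent-level statistics (which some published omnibus
  values appear to reflect) cannot be reconstructed from item-level data.
- The plausibility pilot is supported only through the generic correlation
  statistic.
- No fixation parsing (I-DT/I-VT), drift correction, or multi-AOI spatial
  clustering.
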