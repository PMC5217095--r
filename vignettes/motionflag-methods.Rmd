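---
title: "Methods: detecting motion-related bias in structural morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting motion-related bias in structural morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionflag)
```

## The problem and the measurement model

A T1-weighted anatomical scan records no motion trace, yet motion during its
acquisition blurs and ghosts the image, and automated morphometry tends to
read those artifacts as *thinner cortex*. Because the tendency to move is a
stable individual trait within a scan session, head motion estimated from a
participant's same-session fMRI runs is an informative proxy for how much
they likely moved during the anatomical scan. `motionflag` operationalizes
this idea and quantifies its downstream consequences.

### Framewise displacement and its summary hierarchy

Rigid-body realignment of an fMRI run yields six parameters per frame:
three translations (mm) and three rotations (radians). Rotations are
converted to millimetres of displacement on a sphere of radius 50 mm
(`radius`, configurable) — roughly the distance from the cortex to the
centre of the head — and framewise displacement is the L1 norm of the
first difference of the resulting six-vector. FD is therefore defined for
frames 2..T only. A leading structural zero can be requested
(`include_leading_zero = TRUE`) for comparison with tools that emit one, but
it is off by default because a forced zero deflates run means.

Run-level FD-bar (mean, or median via `stat = "median"`) is averaged over
the runs of a task, and task values are averaged into `fd_all_task`. The
two-level average deliberately ignores frame counts so that longer runs and
better-sampled tasks carry no extra weight. Missing runs are dropped from
the averages, never imputed; a participant with no usable runs is an error.

### The flagging rule

The high-mover threshold is the sample mean of `fd_all_task` plus
`k = 1.5` sample standard deviations (n−1 denominator), with a *strict*
inequality, so a value exactly at the threshold is not flagged and a
zero-variance sample flags nobody. The threshold is always recomputed from
exactly the sample supplied. The combined rule flags a participant when
they exceed the FD threshold *or* their composite visual rating — the more
stringent of the two raters on the ordinal scale pass > warn > fail — is
"fail". Each flag records its source (`fd`, `qc`, `both`).

## The statistics battery

**Stability.** Cross-run association of FD-bar uses Spearman's rho (average
ranks for ties) because FD-bar distributions are right-skewed and
leptokurtic and run relationships are heteroscedastic; Pearson is available
behind `method = "pearson"`. Each pair's significance is confirmed by a
permutation test that reorders one run's vector without replacement,
correlates against the intact other, and counts exceedances. We use the
upper tail (positive association is the alternative of interest) — the
direction is a package decision, recorded here — with Bonferroni correction
over k(k−1)/2 pairs. Participants missing a run contribute
pairwise-complete observations.

**Permutation and bootstrap p-values** throughout use the plus-one rule
p = (1 + #{null ≥ observed}) / (1 + n_perm), so no reported p is ever zero
and the p-values are valid at finite n_perm.

**Rating agreement and cohort comparisons.** Cohen's unweighted κ comes
with the Fleiss asymptotic standard error for its CI and the null SE for
the significance test. Rating distributions across age cohorts are compared
by a 2×3 Pearson contingency chi-square of each cohort's pass/warn/fail
counts against the youngest cohort's counts (no continuity correction); a
level absent from both rows is dropped and the degrees of freedom reduced.

**Group differences.** Motion across rating categories is tested by
tie-corrected Kruskal–Wallis plus pairwise rank-sum tests using the
normal-approximation z without continuity correction; the effect size
reported is the approximate rank eta-squared z²/n. Bonferroni correction
uses m = 3 pairwise comparisons.

**Overlap of the two flag sources.** Sensitivity is the share of FD-flagged
participants also rated "fail"; specificity the share of unflagged
participants rated pass or warn. The permutation null redraws pseudo-"fail"
sets of the observed size without replacement from the full sample; both
tails are upper (is the observed value larger than chance produces?).

**ANCOVA.** The thickness model regresses the outcome on age (continuous),
`fd_all_task` (continuous), composite rating (categorical) and gender
(nuisance), first with all interaction terms under Type III sums of squares
and sum-to-zero contrasts. If no interaction reaches p < 0.05 the main
effects are re-estimated from a main-effects-only refit (where Type III and
Type II coincide). Partial η² is SS_term/(SS_term + SS_residual). Gender
(not ICV) is the default nuisance for thickness because head size covaries
with volume and area but generally not thickness; ICV can be supplied as a
covariate for volume-style analyses. When empty factor cells make the
factorial design rank-deficient the pipeline falls back to the main-effects
model with a warning; calling `ancova()` directly errors, naming the
aliased columns. The effect-size-change test compares η²_age from a model
ignoring QC/FD with the full main-effects model and builds its null by
jointly permuting the (FD, QC) rows against fixed (age, gender, outcome).

**Vertex-wise maps.** Full-partial correlations residualize both thickness
and FD on the covariates and correlate the residuals; p-values use t with
n − q − 2 df where q counts covariate design columns. FDR is
Benjamini–Hochberg, applied across the whole map for correlation maps and
within each hemisphere separately for the group t-maps (pooled-variance t
by default, Welch behind `var_equal = FALSE`). Vertices with residual
variance at numerical-noise scale are excluded from the map and the FDR
family, with the count reported.

**Matched resampling.** Each flagged participant's candidate pool is the
`pool_size = 10` retained participants of the same gender nearest in age,
with ties at the pool boundary broken by participant ID so pools are
identical across runs. The bootstrap null for the flagged group's mean
thickness draws one candidate per flagged member per replicate; the default
tail is *lower* because motion bias depresses thickness. The leave-one-out
envelope instead removes one distinct pool member per flagged participant
to form control cohorts of the retained sample's size, recomputes the
vertex-wise map, and forms pointwise 2.5/97.5 percentile bands of the
sorted correlation vector (the CDF).

A caution discovered during development: control cohorts share most of
their participants, so their sorted-r vectors are strongly correlated and
the envelope is narrow; any map-wide random component (see `subject_sd`
below) moves the whole CDF with effective degrees of freedom near one, so
"any position outside the envelope" is anticonservative. The result object
therefore reports both the share of CDF positions outside the envelope and
the directional `mean_shift` of the after-flagging correlations relative to
the control mean; a genuine negative-bias removal shows a positive shift
(toward zero). The pointwise-CDF reading of the "95% confidence interval"
is itself a design decision — the alternative (per-vertex envelopes) is the
same computation applied before sorting.

**Age-effect comparison.** Before/after variance of mean thickness uses
Bartlett's test; the two age–thickness correlations are compared by a
Fisher-z z-test with the independent-samples standard error
sqrt(1/(n1−3) + 1/(n2−3)). The retained sample is a subset of the full
sample, so this SE is an approximation (it overstates the variance of the
difference); the output labels it accordingly. The vertex-wise correlation
distributions are compared by a two-sample KS test, and parcel-level change
is reported as Δz(r) of mean-parcel thickness vs age.

## The synthetic cohort generator

`cohort_config()` defaults define the study conditions the pipeline was
designed around; they were fixed once, by moment matching, and are not
adjusted per analysis.

- **Sample.** 266 adults aged 20–89, at least 30 per decade, ~64% female;
  seven fMRI runs (VV1/VV2: 202 frames; words: 231; scenes1–3: 171;
  rest: 154) in four task families.
- **Motion.** log FD-bar propensity µ = −2.67 + 0.0101·age + N(0, 0.40²);
  each run's target FD-bar is exp(µ + N(0, 0.2236²)). The log-normal family
  is the simplest two-parameter choice reproducing right-skewed, leptokurtic
  FD-bar distributions. The variance split was solved from three moments:
  run-pair correlation ≈ 0.80 = (a² + b²)/(a² + b² + w²), age–motion
  correlation ≈ 0.44 = a/sqrt(a² + b² + w_eff²) with the all-task averaging
  reducing w_eff, and total log-scale SD 0.5 with median FD ≈ 0.12 mm at the
  mean age. Realignment series are six random walks whose increments are
  rescaled so each run's computed mean FD equals its target exactly (well
  within the 5% tolerance the generator promises); random walks (not white
  noise) keep FD — a first difference — well behaved.
- **Ratings.** Latent T1w artifact severity equals the motion propensity
  plus N(0, 0.30²) — the core premise that people who move in one scan move
  in others, made explicit and tunable. Each rater thresholds
  severity + N(0, 0.30²) at (−1.80, −1.00). The rater noise and thresholds
  were calibrated once by simulation sweep to inter-rater κ ≈ 0.48 with a
  ~60/34/6 pass/warn/fail composite mix at n = 2000, before any downstream
  test was run.
- **Thickness.** thickness(v, p) = 2.5 + subject_offset_p + slope_v·age_p +
  0.02·male_p + β·severity_p·[v ∈ bias region] + N(0, 0.15²), with
  slope_v ~ N(−0.005, 0.002²) mm/yr, β = −0.12 mm per severity unit
  confined to 20% of vertices grouped into contiguous parcels (echoing
  regionally patterned bias without claiming anatomical correspondence),
  and subject_offset ~ N(0, 0.085²) — a global anatomical offset shared
  across vertices, without which whole-brain summaries would correlate with
  age at ≈ −0.99 rather than the realistic ≈ −0.76. Default 2,000 vertices
  in two 1,000-vertex "hemispheres" and 148 parcels for desk-scale work;
  all counts configurable.

**What the generator does not emulate:** spatial autocorrelation of
thickness noise beyond the single global offset (real smoothed maps have
rich local correlation), nonlinear or threshold-like artifact severity,
scanner drift or session effects, and any actual image formation. Passing
tests therefore demonstrate that the *statistics* behave as designed under
a data-generating process with the study's first- and second-order
structure — not that the pipeline's operating characteristics transfer
unchanged to real imaging data.

## Numerical and reproducibility choices

- All randomized analyses take a single integer seed; sub-seeds are derived
  deterministically from a stage-name hash, so adding a stage never
  perturbs another stage's stream. Rerunning a pipeline with the same
  config and seed reproduces every report byte for byte (wall-clock timings
  go to a separate log file).
- Sample SD uses the n−1 denominator; the flag inequality is strict.
- Constant-column detection (stability runs, partial-correlation vertices)
  uses residual sums of squares at numerical-noise scale rather than exact
  zero, so exactly-constant vertices are excluded but real low-variance
  signal is kept; constant stability runs are an explicit error rather than
  a silent NaN.
- Matched-pool ties break lexicographically by participant ID.
- The realignment reader requires a declared column dialect (SPM order vs
  MCFLIRT order) because the two cannot be distinguished numerically, and
  identity always comes from the manifest, never from filename parsing.
- The pipeline config is YAML — one archivable file per run — with CLI
  flags overriding config values.
- Realignment parameter granularity (per-run files vs task-concatenated
  estimates) is accepted as supplied via the manifest; the FD hierarchy is
  agnostic to it.
- When flags are recomputed on a retained subsample, thresholds derive from
  that subsample (recompute-on-retained is the default).

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (n = 25–150, 5 runs of 20–35 frames,
20–300 vertices) chosen to exercise every code path quickly. Calibration
checks use the full seven-run session at n = 2000 with 400-vertex maps;
the attenuation-recovery check uses 50 cohorts of n = 300 with 600-vertex
maps, where the median-|r| estimator over the 120 bias-region vertices is
stable enough to read the direction of the effect in every seed.

## Known limitations

- The fMRI-motion proxy presumes within-session stability of motion; the
  pipeline quantifies that stability but cannot rescue a session where the
  anatomical scan is the only acquisition.
- The envelope analysis is anticonservative under map-wide random
  components (above); read `mean_shift` together with `prop_outside`.
- The Fisher-z comparison treats overlapping samples as independent.
- κ's CI is asymptotic; at small n a bootstrap CI (not built in) would be
  preferable.
- The generator's linear severity→thickness link spreads bias across the
  whole severity range, so removing the flagged tail attenuates but does
  not eliminate bias-region coupling — visible in the acceptance
  statistics, where the bias-region |r| drops rather than vanishes after
  flag removal.
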