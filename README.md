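# motionflag

Head motion corrupts structural (T1-weighted) MRI, but unlike fMRI, a T1w
scan carries no intrinsic motion trace: morphometric estimates such as
cortical thickness can be silently biased downward in the very participants —
older adults, children, clinical groups — who move most. **motionflag**
implements a retrospective screening pipeline for this problem: it quantifies
each participant's tendency to move from the realignment parameters of
*same-session fMRI runs*, integrates two-rater visual quality ratings of the
T1w image, flags scans likely to carry motion-related bias, and runs a
resampling-statistics battery that measures how much that bias distorts
morphometry before and after flagging.

The package is aimed at groups working with lifespan or clinical cohorts
(or legacy datasets acquired without prospective motion correction) who need
a defensible, reproducible rule for excluding motion-contaminated anatomy.

## The model and statistics

**Framewise displacement.** For a run with rigid-body realignment parameters
(translations in mm, rotations in radians), rotations are first converted to
arc length on a sphere of radius r = 50 mm, then

FD(t) = Σ_{j=1..6} | p_j(t) − p_j(t−1) | ,  t = 2..T.

Per-run mean FD (FD-bar) is averaged over the runs of each task, and task
values are averaged into the participant's session-level index
FD-bar_all-task, so runs with more frames or tasks with more runs do not
dominate.

**Flagging.** A participant is flagged when

FD-bar_all-task > mean + 1.5 × SD (sample SD, n−1)  — a "high mover" —

or their composite visual rating (the more stringent of two raters on the
ordinal pass > warn > fail scale) is "fail". The two criteria identify
largely distinct subsets, which is why both are needed.

**The statistics battery.**

- cross-run Spearman stability of FD-bar with one-sided permutation nulls
  and Bonferroni correction over the k(k−1)/2 run pairs;
- Cohen's κ (with Fleiss asymptotic CI) for inter-rater agreement, and
  Pearson chi-square comparisons of rating distributions across age cohorts;
- Kruskal–Wallis and pairwise rank-sum tests (normal-approximation z,
  rank η² = z²/n) of motion across rating groups;
- sensitivity/specificity of "fail" ratings for detecting high movers, with
  a resampling null over random pseudo-"fail" sets;
- Type III ANCOVA with partial η² = SS/(SS + SS_res), an interaction screen,
  and a permutation test for the *change* in the age effect size when
  motion/QC covariates enter the model;
- vertex-wise full-partial correlation maps (thickness vs FD-bar_all-task,
  controlling age and gender) with Benjamini–Hochberg FDR;
- age- and gender-matched bootstrap nulls for the flagged group's mean
  thickness (one draw per flagged member from their 10 nearest matched
  controls), leave-one-out control envelopes for the after-flagging
  correlation CDF, and hemisphere-wise FDR-corrected group t-maps;
- before/after-flagging comparison of the age effect: Bartlett's variance
  test, Fisher-z correlation comparison, two-sample Kolmogorov–Smirnov on
  vertex-wise correlation distributions, and per-parcel Δz(r).

Because the cohort that motivated this design is not publicly deposited, the
package ships a calibrated synthetic lifespan-cohort generator
(`generate_cohort()`) with ground truth, reproducing the study conditions:
right-skewed FD distributions, cross-run rank stability ρ ≈ 0.70–0.90,
age–motion correlation ≈ 0.44, rater agreement κ ≈ 0.48, and regionally
confined motion bias on thickness.

## Worked example

```r
library(motionflag)

cohort <- generate_cohort(cohort_config(), seed = 42)   # 266 participants, 7 runs
res <- run_pipeline(cohort, params = pipeline_params(seed = 42),
                    out_dir = "reports")

res$flags
#> <mf_flags> 17/266 flagged (threshold = mean 0.1364 + 1.5 SD 0.0643 = 0.2328 mm)
res$overlap
#> sensitivity = 0.47 (p = 0.0001), specificity = 0.97 (p = 0.0001); union = 25 of 266
res$effect_size_change
#> age eta^2: 0.584 (without QC/FD) -> 0.522 (with); delta = 0.062, perm p = 0.000999
res$boot
#> observed flagged-group mean = 2.1564; null 2.2053 +/- 0.0175; lower-tail p = 0.0027 (10000 draws)
res$age_comparison
#> age~thickness r: -0.763 (n = 266) -> -0.743 (n = 241); Fisher z = 0.53, p = 0.596
#> variance: 0.0194 -> 0.01824 (Bartlett X^2(1) = 0.24, p = 0.627)
#> vertex-wise correlation CDFs: KS D = 0.0670, p = 0.000252
#> parcel delta z(r) >= 0 (attenuation) in 100% of 148 parcels
```

Reading the output: 17 of 266 synthetic participants exceed the high-mover
threshold of 0.233 mm; "fail" ratings catch 47% of them (permutation
p = 1e-4). The flagged group's mean thickness sits 0.049 mm below its
matched-control null (p = 0.003), the apparent age effect on thickness drops
by Δη² = 0.06 once motion and QC enter the model (permutation p = 0.001),
and removing the flagged scans shifts the vertex-wise age-correlation
distribution significantly toward zero (KS D = 0.067) even though the
whole-brain age correlation barely moves (−0.76 → −0.74). That pattern —
large regional bias hiding behind stable global summaries — is exactly what
the pipeline is built to expose.

Every result object supports `tidy()`, `glance()` and `autoplot()`; all
reports are written as TSV/JSON with seeds recorded. A thin command-line
wrapper with `generate`/`fd`/`ratings`/`flag`/`stability`/`bias`/`all`
subcommands is installed at `inst/scripts/motionflag`.

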