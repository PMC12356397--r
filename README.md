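# srbias

Can adding noise to a display make an observer not only *see better* but
also *judge less prejudicedly*?  `srbias` is a simulation and analysis
pipeline for a visual psychophysics paradigm built around that question.
Near-threshold letters — consonants (C, B, H) versus vowels (O, E, U) —
are presented in dynamic Gaussian pixel noise whose standard deviation σ
steps through a geometric ladder (0, 0.25, 0.76, 2.30, 6.96, 21.11, 64
grey levels).  One letter category appears on 80% of trials, which induces
a response bias toward the frequent category.  Stochastic resonance — the
inverted-U improvement of subthreshold detection at intermediate noise —
is then measured jointly on performance and on bias.

The package is aimed at psychophysicists and methodologists who want a
fully synthetic, seed-reproducible test bed for this class of designs:
every stage from pixels to p-values is simulated and testable without
human data.

## What it computes

Responses on the 6-alternative letter task are folded into a
2-alternative category decision.  With the rare category as "signal",
hits H, misses M, false alarms FA and correct rejections CR give

    accuracy = (H + CR) / (H + M + FA + CR)
    HR = H / (H + M)          FAR = FA / (FA + CR)
    d'  = z(HR) - z(FAR)
    c   = -( z(HR) + z(FAR) ) / 2

with extreme rates clipped to 1/(2N).  A positive criterion c means
under-reporting the rare category.  Around these sit:

* **stimuli** — the noise ladder, deterministic Sloan-like letter bitmaps
  (confusion partners C–O, B–E, H–U straddle the category boundary), and
  noisy stimulus frames (`make_noise_ladder()`, `letter_templates()`,
  `compose_trial_frames()`);
* **quest** — a QUEST Bayesian staircase titrating letter luminance to 70%
  correct on a Weibull psychometric function
  `p(x) = δγ + (1−δ)[1 − (1−γ) exp(−10^{β(x−T)})]`
  (`quest_params()`, `run_quest_titration()`, `quest_demo()`);
* **observer** — a synthetic participant: hard transduction threshold θ
  (the stochastic-resonance nonlinearity) → template matching →
  prior-weighted decision with Gaussian late noise and lapses
  (`observer_params()`, `simulate_participant()`);
* **paradigm** — the block ladder with the 80/20 base-rate flip toward
  each participant's own bias, QUEST-rerun and exclusion rules
  (`build_design()`, `assign_frequent_category()`, `exclusion_rule()`);
* **sdt** — tallies and summaries per participant × σ
  (`classify_responses()`, `sdt_summarize()`, `dprime()`, `criterion()`);
* **inference** — repeated-measures ANOVA over noise level, one-tailed
  baseline-referenced post-hocs with Benjamini–Hochberg FDR, JZS Bayes
  factors (one-sample and correlation), and noncentral-t power analysis
  (`rm_anova_oneway()`, `posthoc_vs_baseline()`, `jzs_bf_one_sample()`,
  `power_sample_size()`).

`run_simulate()` and `run_analyze()` tie the stages together around a
canonical CSV trial-log schema; the numbered scripts under `analysis/`
drive the full workflow and write their tables under `results/`.

## Worked example

Simulate a 22-observer cohort through the whole experiment and analyse it
(about a minute on one core):

```r
library(srbias)
sim <- run_simulate(list(seed = 1L))
res <- run_analyze(sim$trials)
writeLines(res$report)
```

```
Participants analyzed: 22 of 22 (excluded: none)
Noise levels (sigma): 0, 0.25, 0.7579, 2.297, 6.964, 21.11, 64
Accuracy RM-ANOVA: F(6,126) = 41.08, p = 2.05e-27
d' RM-ANOVA: F(6,126) = 40.57, p = 3.4e-27
Criterion RM-ANOVA: F(6,126) = 4.63, p = 0.000277
Zero-noise criterion: M = 0.98 +/- 0.30, t(21) = 15.20, p = 4.18e-13, d = 3.24, lnBF10 = 22.87
Bayesian correlation of accuracy change vs criterion change at sigma = 0.25: lnBF10 = -0.71
A priori power: d = 0.6, alpha = 0.05, 1-tailed -> N = 19
```

```r
round(rbind(accuracy  = colMeans(res$matrices$accuracy),
            dprime    = colMeans(res$matrices$dprime),
            criterion = colMeans(res$matrices$criterion)), 3)
```

```
              0  0.25 0.7579 2.297 6.964 21.11    64
accuracy  0.721 0.724  0.772 0.862 0.881 0.877 0.805
dprime    0.165 0.278  0.735 1.795 2.004 1.958 1.099
criterion 0.975 0.947  0.914 0.721 0.754 0.700 0.815
```

Reading the numbers: category accuracy and d′ rise from the zero-noise
baseline to a peak at intermediate noise (σ ≈ 2.3–21) and fall again at
σ = 64 — the inverted-U signature of stochastic resonance.  The zero-noise
criterion is strongly positive (bias toward the frequent category), and it
is relieved at the resonant noise levels; `res$posthoc$criterion` holds
the one-tailed FDR-corrected contrasts with per-level Bayes factors.

The same workflow, with narrative logging and figures, is in the numbered
scripts:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_group_inference.R
Rscript analysis/03_quest_validation.R
Rscript analysis/04_figures.R
```

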