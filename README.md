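# pemod

Reward prediction-error signals, chronic life stress, and fluid
intelligence — a reinforcement-learning and moderation-analysis pipeline,
validated end to end on synthetic cohorts.

## What this package is for

Striatal BOLD activity tracks reward prediction errors (PEs), the
teaching signal of habitual, model-free learning. `pemod` is for
researchers who want to quantify that per-subject "BOLD PE signal" from
reversal-learning behavior and test whether a between-subject moderator —
here, chronic stressful life events (SLES) — changes how the signal
relates to a cognitive outcome such as fluid IQ. The package covers the
full chain:

1. **Task simulation** (`task_config()`, `run_task()`,
   `simulate_agent()`): a probabilistic reversal-learning task with
   20/80, 80/20 and 50/50 reward blocks that reverse unannounced after
   ≥ 10 trials at ≥ 70% correct, or automatically after 16 trials;
   200 trials over two sessions.
2. **Rescorla-Wagner/softmax model** (`sequence_loglik()`): choice
   probabilities `p(a|Q) = exp(Q_a) / Σ exp(Q_a')`, value update
   `Q ← Q + ε (R − Q)` with effective reinforcement `R = β_rew` for
   reward and `R = −β_pun` for punishment, and the trial-wise
   prediction-error trace `PE_t = R_t − Q_{t−1}(a_t)`.
3. **Hierarchical empirical-Bayes fitting** (`em_fit_population()`,
   `map_fit_subject()`): per-subject MAP estimates in transformed space
   `(logit ε, log β_rew, log β_pun)` under a Gaussian population prior
   whose mean and covariance are estimated from the whole cohort by
   expectation-maximization with a Laplace approximation.
4. **PE-modulated fMRI regression** (`build_design()`, `fit_glm()`):
   feedback-onset sticks and mean-centered PE modulators convolved with
   the canonical double-gamma HRF, fitted by OLS per session; the
   PE-modulator beta is the subject's BOLD PE signal.
5. **Moderation statistics** (`moderation_regression()`,
   `subgroup_r2()`): two-step hierarchical regression of fluid IQ on the
   PE beta and SLES (median-split or continuous z-coding), the
   interaction F-change test, and Cook's distance / standardized-residual
   influence flags.
6. **Synthetic cohorts** (`cohort_spec()`, `generate_cohort()`,
   `end_to_end()`): complete study datasets — RL parameters, behavior,
   SLES, fluid IQ, voxel time series — with known ground truth, so every
   stage can be validated by simulation.

See `vignettes/methods.Rmd` for the model details, the design decisions,
and what the synthetic validation does and does not establish.

## Worked example

Generate a 16-subject synthetic cohort with a planted SLES × PE-signal
interaction and run the complete analysis pipeline on it:

```r
library(pemod)
set.seed(2026)
spec <- cohort_spec(n_subjects = 16)
res <- end_to_end(spec, em_max_iter = 8, n_restarts = 3)
print(res$moderation)
```

```
Moderation regression (SLES coding: median_split, n = 16)
  R2 step 1 (main effects): 0.440
  R2 step 2 (+ interaction): 0.636
  F-change = 6.480, p = 0.0257
 step        term beta_std      b      t      p
    1     pe_beta    0.202  0.268  0.776 0.4516
    1   sles_code    0.522  0.649  2.011 0.0656
    2     pe_beta   -1.370 -1.822 -2.093 0.0583
    2   sles_code   -0.708 -0.879 -1.335 0.2066
    2 interaction    2.551  1.600  2.546 0.0257
  influence flags on subject(s): 16 
  max Cook's distance = 1.054
```

Reading this: the main-effects model explains 44% of the variance in
fluid IQ; adding the SLES × PE-beta product raises that to 64%, a
significant F-change (6.48, p = 0.026) — the planted moderation is
detected. One subject exceeds the Cook's-distance threshold and is
flagged (never dropped). The subgroup scatter behind the median split
shows the same story:

```r
unlist(res$subgroups)
#>    r2_low   r2_high
#> 0.1723805 0.4082463
```

Fluid IQ tracks the BOLD PE signal more tightly in the high-SLES
subgroup. Because the cohort is synthetic, the pipeline can also be
scored against ground truth:

```r
unlist(res$recovery)
#> epsilon_rank_cor beta_rew_rank_cor  scale_cor scale_rmse
#>            0.847             0.929      0.968      0.126
```

Rank correlations of 0.85/0.93 between true and recovered learning rates
and reward sensitivities, and GLM betas tracking the true BOLD scales at
r = 0.97.

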