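---
title: "Modeling striatal prediction-error signals and their moderation by life stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling striatal prediction-error signals and their moderation by life stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemod)
```

## The scientific question

Reward prediction errors (PEs) — the difference between the reinforcement
an agent receives and the reinforcement it expected — are the teaching
signal of habitual, model-free learning, and the ventral striatum (VS)
tracks them closely in fMRI. `pemod` implements the computational chain
needed to ask whether chronic life stress changes how strongly this basic
learning signal relates to fluid intelligence: a probabilistic
reversal-learning task, a Rescorla-Wagner (RW) observation model fitted
hierarchically across subjects, a PE-modulated BOLD regression that yields
one "VS BOLD PE signal" per subject, and a two-step moderation regression
of fluid IQ on that signal, stressful life events (SLES), and their
interaction. Because the motivating study's raw data (16 subjects) are not
public, the package ships a synthetic-cohort generator with the same
statistical structure, so every stage of the pipeline is exercised and
validated end to end by simulation.

## The reversal-learning task

Two response options (left/right) pay probabilistic reward under three
block types: 20/80, 80/20 and 50/50 (reward probability for left and
right respectively). A block ends — unannounced — once at least 10 trials
have been played with at least 70% of them correct, or automatically
after 16 trials. Sessions hold 100 trials each; the default protocol is
two sessions. Feedback is displayed for 1 s and trials are separated by a
uniform 1–6.5 s jittered interval.

Two scoring conventions coexist, and they answer different questions:

* **Switching criterion** (`criterion_rule` in `task_config()`): the rule
  that ends blocks must operate in every block, including 50/50 blocks
  where no response is objectively better. The default scores a response
  correct if it chose the higher-reward-probability action, falling back
  to feedback (rewarded = correct) in 50/50 blocks; a pure
  feedback-defined rule is available.
* **Behavioral accuracy** (`percent_correct()`): accuracy is only
  meaningful where an objectively better option exists, so the summary
  statistic counts higher-probability choices in asymmetric blocks and
  excludes 50/50 trials. A feedback-defined variant is provided for
  comparison.

Unstated details were fixed once: block types change to one of the two
*other* types drawn uniformly (the first block is uniform over all
three); the inter-trial jitter is uniform on its range; simulated agents
respond instantly, so response-time bookkeeping is omitted; missed-trial
handling exists only in the events reader (flagged trials are dropped,
since the model likelihood is defined over made choices only).

## The Rescorla-Wagner observation model

Choice probabilities follow a softmax over the running action values,

$$p(a \mid Q_t) = \frac{\exp Q_t(a)}{\sum_{a'} \exp Q_t(a')},$$

and the chosen action's value is updated by a fraction $\varepsilon$ of
the prediction error,

$$Q_t(a_{\text{chosen}}) = Q_{t-1}(a_{\text{chosen}}) +
\varepsilon\,(R_t - Q_{t-1}(a_{\text{chosen}})), \qquad
\text{PE}_t = R_t - Q_{t-1}(a_t),$$

where the effective reinforcement is $R_t = \beta_{\text{rew}}$ after a
reward and $R_t = -\beta_{\text{pun}}$ after a punishment. The
sensitivities double as inverse-temperature: large $\beta$ values make
both the values and the softmax choice more extreme.

Numerical and structural choices:

* Values start at $Q_0 = (0, 0)$; this makes the
  $\beta_{\text{rew}} = \beta_{\text{pun}} = 0$ likelihood exactly
  $n \log 0.5$, a useful exact oracle.
* Values are *not* reset at the session boundary by default (subjects are
  never told about reversals, so learning is one continuous stream); a
  reset variant is config-switchable and covered by tests.
* Only the chosen action's value is updated; there is no decay or
  forgetting of the unchosen option.
* The softmax is computed with max-subtraction; its shift-invariance
  makes this exact.
* Fitting happens in transformed space
  $\theta = (\operatorname{logit} \varepsilon, \log \beta_{\text{rew}},
  \log \beta_{\text{pun}})$, which enforces the domain constraints.
* The sequential likelihood recursion is implemented in C++ (Rcpp): it
  is evaluated tens of thousands of times inside the hierarchical fit.

## Hierarchical empirical-Bayes estimation

Per-subject parameters are maximum a posteriori (MAP) estimates under a
Gaussian population prior $N(\mu, \Sigma)$ in transformed space. The
prior is estimated from all subjects jointly by
expectation-maximization: the E-step computes each subject's MAP vector
$\theta_i$ and its Laplace covariance $H_i^{-1}$ (inverse Hessian of the
negative log-posterior); the M-step sets

$$\mu \leftarrow \tfrac1N \sum_i \theta_i, \qquad
\Sigma \leftarrow \tfrac1N \sum_i \left[(\theta_i - \mu)(\theta_i -
\mu)^\top + H_i^{-1}\right].$$

The $H_i^{-1}$ term keeps the prior variance from collapsing onto the
point estimates. Iteration stops when the largest absolute change in
$\mu$ and $\Sigma$ drops below $10^{-3}$ or after 100 iterations.

Choices that experience forced:

* **Diagonal $\Sigma$ by default.** At cohort sizes in the tens, the
  off-diagonal M-step terms are dominated by Laplace-approximation noise.
  In simulation they acquired a spurious negative covariance between
  $\log \beta_{\text{rew}}$ and the weakly identified
  $\log \beta_{\text{pun}}$, which dragged the reward-sensitivity
  estimates and cut their rank-correlation with the truth from about
  0.86 to 0.55. A full covariance remains available
  (`diagonal_sigma = FALSE`) for larger cohorts.
* **Restarts every iteration.** RL likelihoods are multimodal (a
  $\beta_{\text{rew}} \to 0$ ridge can mimic punishment-driven behavior).
  Each EM iteration refits every subject from the prior mean, fresh
  prior draws, and the previous optimum; warm starts alone left subjects
  stranded in local modes. Restart draws are capped in spread so that a
  deliberately flat prior still produces usable starting points.
* **Broad initialization** ($\mu = 0$, $\Sigma = 6.25 I$) avoids early
  over-shrinkage; convergence tolerance and iteration cap are desk-scale
  defaults.
* The per-subject log-likelihood reported in summaries is the *data*
  term at the MAP (not the posterior), and the cohort summary reports
  quartiles of natural-space values, the conventional format for RL
  cohort tables.

The EM objective (summed per-subject log-posterior at the current prior)
is only guaranteed monotone up to Laplace-approximation error; the test
suite flags decreases beyond 0.5% of the objective's magnitude.

## The BOLD PE signal

Feedback onsets are modeled as stick functions on a microtime grid (16
subdivisions of the TR = 2.3 s), plus a parametrically modulated copy
whose stick heights are the session-mean-centered trial PEs. Both are
convolved with the canonical double-gamma HRF (peak 6 s, undershoot
16 s, ratio 1/6, 32 s support) and down-sampled to the 310-volume
session grid. Mean-centering the modulator per session keeps it
orthogonal in expectation to the unmodulated onset regressor. The HRF is
normalized to unit peak, so a regression coefficient reads as BOLD
amplitude per unit centered PE at the response peak — this fixes the
units of the synthetic "signal scale" and makes planted scales directly
recoverable.

The per-subject GLM is ordinary least squares per session, sessions
combined by averaging betas (standard errors pooled). The PE-modulator
coefficient is the subject's "VS BOLD PE signal". The forward model for
testing adds stationary AR(1) Gaussian noise (marginal SD 1, lag-1
correlation 0.3) to a scaled copy of the PE regressor; OLS betas remain
unbiased under that noise, while t-statistics are naive with respect to
autocorrelation and are labeled as such. The whole voxelwise SPM
apparatus (smoothing, small-volume correction, the literature-based VS
volume of interest) is deliberately replaced by this one-voxel
abstraction: the group-level statistics consume exactly one scalar per
subject.

## Moderation statistics

"Stepwise" here means explicit two-step hierarchical entry, not
automated variable selection: step 1 regresses fluid IQ on the PE beta
and the SLES term; step 2 adds their product. The interaction's
contribution is the F-change statistic

$$F_{\text{change}} = \frac{(R^2_{\text{full}} - R^2_{\text{base}})/q}
{(1 - R^2_{\text{full}})/(n - k - 1)},$$

which the tests verify to $10^{-10}$ against the nested-model partial F.
SLES enters either as a median-split 1/2 code (ties at the median join
the low group; switchable) or as a z-transformed continuous score; in
both codings the PE beta is left uncentered in the product, matching the
construction the analysis mirrors, with a centered option for users who
prefer interpretable main effects. Influence diagnostics (Cook's
distance with threshold 1, standardized residuals with threshold 3) are
reported for every point; nothing is ever dropped silently. Age is
available as an optional covariate in both steps.

## The synthetic cohort

The generator emulates the joint structure the analysis assumes:

* **RL parameters**: $\theta_i \sim N(\mu, \Sigma)$ with $\mu$ chosen so
  the natural-space medians sit at the cohort quartile-table medians
  ($\varepsilon = 0.62$, $\beta_{\text{rew}} = 2.73$,
  $\beta_{\text{pun}} = 0.84$) and diagonal $\Sigma = (1.44, 0.49,
  0.19)$ matched to the reported interquartile ranges via the normal
  IQR-to-SD ratio.
* **SLES**: normal(16.31, 4.59) rounded and truncated to the 0–42
  checklist range — only these moments and the range are known.
* **BOLD scale**: $s_i = 1 + 0.4\,z(\text{SLES}_i) + N(0, 0.2)$, a
  positive link mirroring the positive SLES–VS association the analysis
  probes; set the slope to 0 for null cohorts.
* **Fluid IQ**: $0.60 + 0.5\,s_i + 0\cdot z_i + 0.8\,s_i z_i +
  N(0, 0.25)$. The intercept matches the reported cohort mean; the zero
  direct SLES effect mirrors the reported null correlation; ages are
  uniform on 20–60 years (only used as an optional covariate).

The interaction coefficient and residual SD were calibrated **once**
(`scripts/calibrate_cohort.R`) so that at the study's $n = 16$ the
continuous-coding interaction test has power near 0.9 (0.9385 pinned at
4000 replicates; the median-split variant, attenuated by dichotomizing a
continuous moderator, pins at 0.6390) and the median-split subgroup
pattern shows the qualitative signature of interest — fluid IQ tracking
the PE beta much more tightly in the high-SLES subgroup (mean $R^2$
about 0.71 versus 0.32) — and then frozen. These are calibration
choices, not estimates from any real cohort: the motivating study's
standardized effect sizes are not identifiable from its report.

What the generator does *not* emulate: realistic fMRI artifacts (motion,
drift beyond AR(1)), the neuropsychological battery behind the fluid-IQ
factor score, age structure beyond a uniform draw, and measurement error
in SLES. Passing tests therefore demonstrate that the pipeline is
correct and well calibrated *under its own assumptions*, not that those
assumptions hold in real data.

## Problem sizes used in validation

The test suite and acceptance script run at sizes chosen to make
Monte-Carlo error small relative to the tolerances they check:
1,000 agents for the posterior-predictive behavioral summary; 50
subjects × 200 trials for hierarchical parameter recovery (rank
correlations with the generating values: learning rate ≈ 0.93, reward
sensitivity ≈ 0.86); 100 seeds for the planted-scale monotonicity check
and 1,000 for the null t-calibration of the GLM; 2,000 replicates for
the type-I error and 1,000 for the power of the interaction test. A
dense 600-point one-dimensional grid and a 25³-point three-dimensional
grid serve as brute-force oracles for the MAP optimizer; the flat-prior
variant of the 3-D comparison checks only that the optimizer beats every
grid point, because the unpenalized optimum can escape any finite grid
box along the $\beta_{\text{rew}} \to 0$ likelihood ridge.

## Known limitations

* The punishment sensitivity is weakly identified at 200 trials; its
  estimates lean on the prior, and its hyperparameters are the least
  accurate part of the EM solution. This is a property of the design
  (punishments are frequent but carry little choice-discriminating
  information at these parameter values), not of the optimizer.
* The one-voxel abstraction cannot reproduce spatial statistics
  (cluster inference, small-volume correction); per-subject betas are
  its only output.
* The naive OLS t-statistics understate autocorrelation; group-level
  inferences in the package rest on the betas, not on these t values.
* With $n = 16$ the moderation test's power depends strongly on SLES
  coding; the median-split variant pays a substantial attenuation cost,
  which is itself visible in the pinned calibration values.
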