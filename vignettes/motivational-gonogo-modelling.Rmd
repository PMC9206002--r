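---
title: "Modelling motivational bias in the Go/NoGo task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling motivational bias in the Go/NoGo task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgng)
```

## The task and what the package models

In the motivational Go/NoGo task a cue appears on every trial and the
participant either presses a button (Go) or withholds (NoGo). Cue valence
(Win or Avoid) is signalled by the cue's edge colour; the required action
(Go or NoGo) has to be learned from probabilistic feedback. Crossing the
two factors gives four cue conditions: Go-to-Win and NoGo-to-Avoid are
*bias-congruent* (the action the valence prompts coincides with the action
required), Go-to-Avoid and NoGo-to-Win are *bias-incongruent*. Feedback is
probabilistic: a correct response earns the desired outcome (reward for
Win cues, nothing for Avoid cues) on 80% of trials, an incorrect response
on only 20%. Win cues never punish; Avoid cues never reward.

A session, as generated by `generate_schedule()`, has two blocks of 80
trials with each cue shown 20 times per block. Inter-trial intervals are
jittered over 2200–3400 ms and cue-feedback intervals over 1400–2600 ms,
both in 200 ms steps. A practice phase (`generate_practice_schedule()`)
has 4 presentations per cue in each of two rounds — deterministic feedback
first, probabilistic second, 32 trials in total — and is never fitted.

Two numerical conventions are fixed here rather than by the task
definition:

* **Reward signal coding.** Outcomes enter the learning rule as
  r ∈ {+1, 0, −1} for reward/neutral/punishment. This is the minimal
  symmetric coding compatible with a single multiplicative feedback
  sensitivity; `outcome_reward_signal()` accepts an alternative coding
  vector should an asymmetric scheme be wanted.
* **Jitter balancing.** With 40 presentations per cue and 7 jitter steps
  exact balance is impossible. Counts per step value differ by at most
  one, the remainder steps being assigned by a seeded draw; the temporal
  order is randomised within cue. This preserves the design intent
  (equal exposure per step and cue) up to the unavoidable remainder.

Cue duration (1300 ms) and feedback duration (750 ms) are carried as
schedule attributes only; the package does not model reaction times.

## Model family

All models are Rescorla–Wagner learners over action values
$Q(a, s)$ for $a \in \{\text{Go}, \text{NoGo}\}$ and the four cues $s$:

$$Q_t(a_t, s_t) = Q_{t-1}(a_t, s_t) +
  \varepsilon\,\bigl(\rho\, r_t - Q_{t-1}(a_t, s_t)\bigr)$$

with learning rate $\varepsilon \in (0,1)$ and feedback sensitivity
$\rho > 0$. Action weights add a Go bias $b$ and a motivational bias
$\pi$ acting through cue valence $V$ (+0.5 Win, −0.5 Avoid):

$$w_t(\text{Go}, s) = Q_t(\text{Go}, s) + b + V(s)\,\pi, \qquad
  w_t(\text{NoGo}, s) = Q_t(\text{NoGo}, s),$$

and a two-action softmax converts weights to choice probabilities. M1
contains $(\rho, \varepsilon)$; M2 adds $b$; M3 adds $\pi$; M4 duplicates
the M3 set per drug condition so that every parameter may differ between
the placebo and drug sessions.

Modelling conventions, chosen where the task definition is silent:

* $Q$ starts at 0 for every action–cue pair. The valence prior is carried
  entirely by $V\pi$, so a neutral value prior is the consistent choice.
* $Q$ values reset between sessions and are never shared: each test day
  uses a distinct cue set, so each session is an independent learning
  episode. (The two blocks within a session are fitted concatenated —
  they continue the same cue set.)
* Only the chosen action's value is updated (instrumental credit
  assignment).
* There is no lapse/irreducible-noise parameter; the model space is the
  four models above. A lapse variant is a known extension but out of
  scope here.
* Missing responses contribute neither likelihood nor update; the
  simulator never produces them, but the data reader tolerates the
  `"na"` code.

The likelihood replay is implemented in compiled code for speed; the test
suite checks it trial-by-trial against an independent pure-R replay, a
symbolic two-trial hand computation, and the nesting identities
(M2 with $b=0$ equals M1, M3 with $\pi=0$ equals M2, M4 with equal sets
equals M3, all to machine precision).

## Fitting

`fit_subject()` maximises the log posterior per subject in an
unconstrained space: $x_\rho = \log \rho$,
$x_\varepsilon = \mathrm{logit}\,\varepsilon$, $b$ and $\pi$ unchanged.
The logistic back-transform is clipped to $(10^{-12}, 1-10^{-12})$ so
extreme optimizer excursions cannot produce degenerate learning rates.
Priors are weakly informative normals — $x_\rho, x_\varepsilon \sim
N(0, 1.5^2)$ and $b, \pi \sim N(0, 2^2)$ — and the optimiser is BFGS with
numeric gradients, relative tolerance $10^{-10}$, from 10 seeded restarts
drawn from the prior (plus, inside `fit_cohort()`, the optimum of the
nested simpler model, which guarantees the best likelihood is monotone
over the nesting chain; M4 is seeded with the duplicated M3 optimum).

The log model evidence is the Laplace approximation at the MAP optimum,
$$\log p(y) \approx \log p(y, \hat\theta) + \tfrac{d}{2}\log 2\pi
  - \tfrac12 \log |H|,$$
with $H$ the finite-difference Hessian of the negative log posterior.
If $H$ is not positive definite the function falls back to $-\mathrm{BIC}/2$
and warns; in practice this occurs only for pathological datasets.

**Empirical-Bayes refinement.** `fit_cohort(empirical_bayes = TRUE)`
re-estimates the group prior (mean and SD of the unconstrained MAP
estimates of the largest model, SDs floored at 0.25) and refits, for two
outer iterations. This is a light-weight version of the hierarchical
expectation-maximisation fitting that is standard in this literature. It
matters for model selection: under the flat default priors the Laplace
complexity penalty for $b$ and $\pi$ (about 2.5 nats per parameter at
320 trials) nearly cancels the likelihood gain for subjects whose drawn
$\pi$ is small, which leaves group-level evidence differences fragile.
With the refined group prior the evidence reflects the population-typical
parameter scale, and selection of the generating model becomes decisive.
The package therefore uses the empirical-Bayes evidences for its
model-selection analyses; single-subject estimation is unaffected.

The drug contrast on fitted parameters is a paired two-sided Wilcoxon
signed-rank test per parameter (drug vs placebo estimates from M4), a
distribution-free paired test of the same null as the study-level
regression contrast, which — like all mixed-effects covariate modelling —
is outside this package's scope.

## Random-effects model selection

`run_bms()` implements the standard variational scheme for a Dirichlet
population distribution over model frequencies:

1. responsibilities $u_{nk} \propto \exp\{L_{nk} + \psi(\alpha_k) -
   \psi(\textstyle\sum_j \alpha_j)\}$,
2. $\alpha_k = \alpha_0 + \sum_n u_{nk}$,

iterated until the change in $\alpha$ is below $10^{-6}$, with
$\alpha_0 = 1$ (uniform prior). Exceedance probabilities come from
$10^6$ seeded Dirichlet draws (gamma representation); the Monte-Carlo
estimator is validated against the closed-form Beta tail
$P(\theta > 1/2 \mid \mathrm{Beta}(3,1)) = 0.875$ in the tests. The Bayes
omnibus risk compares the free energy of the fitted random-effects model,

$$F_1 = \mathbb{E}_q[\log p] + \mathcal{H}[q(r)] + \mathcal{H}[q(m)],$$

computed from the variational solution, with the exact null evidence
$F_0 = \sum_n \bigl(\mathrm{logsumexp}_k L_{nk} - \log K\bigr)$ for
frequencies fixed at $1/K$, giving $\mathrm{BOR} = 1/(1 + e^{F_1 - F_0})$
and $\mathrm{PXP} = (1-\mathrm{BOR})\,\mathrm{XP} + \mathrm{BOR}/K$.
Two presets mirror the usual analysis sequence: `base` compares M1–M3;
`full` adds the drug-split M4.

## Synthetic cohorts and what they do (not) emulate

`cohort_spec()` defines the study conditions used for validation: 35
subjects, two sessions of 160 trials, population parameters
$\rho \sim N(3, 1)$ (clipped to $[0.1, 20]$),
$\varepsilon \sim N(0.25, 0.1)$ (clipped to $(0.01, 0.99)$),
$b \sim N(0.2, 0.3)$, $\pi \sim N(0.7, 0.4)$, and a drug effect that
shifts $\pi$ by −0.4 in the drug session with subject-level noise of
SD 0.2 (half the mean shift — large enough for realistic heterogeneity,
small enough that the population effect keeps its sign for most
subjects). These values are stand-ins chosen to produce a Win−Avoid
Go-rate gap of roughly 15–25 percentage points, the magnitude typical of
this task; they are not estimates from any particular dataset. The other
parameters are shared across sessions in the generator, while the fitted
M4 frees all eight — so recovery also checks that spurious drug effects
do not appear in $\rho$, $\varepsilon$, $b$.

The generator emulates choice behaviour only. Real data additionally
contain reaction times, missing responses, session-order and test-site
effects, and slow non-stationarities (fatigue, strategy shifts) — none of
which are simulated. Passing recovery on synthetic cohorts therefore
shows the estimation and selection machinery is sound at the study's
size and noise level, not that the model is the true generative process
of any empirical dataset.

`recovery_test()` refits the generating model (M4 for drug-effect
questions, so $\pi$ is estimated per session), reports per-parameter
true-vs-recovered Pearson correlations, the paired Wilcoxon test of
recovered $\pi_{\mathrm{drug}}$ vs $\pi_{\mathrm{placebo}}$, and whether
the recovered mean shift has the generating sign.
`replicate_recovery()` repeats this over replicate cohorts (20 by
default) for power and type-I summaries.

## Pipeline and reproducibility

`run_pipeline()` chains cohort generation, fitting of M1–M4, both model
comparisons, the drug contrast and the recovery report, writing CSV
tables, JSON reports and a manifest. Every stage seed derives
deterministically from the master seed as
`(master * 48271 + weighted character sum of the stage name) mod (2^31 − 1)`
(`stage_seed()`), so runs are reproducible end to end and stages can be
re-run in isolation; identical configurations give byte-identical numeric
outputs.

## Problem sizes and numerical choices

The validation suite runs single-subject oracles at 2–320 trials,
cohort-level checks at 8–12 subjects, and the study-scale checks
(model selection and drug-effect recovery) at the full 35 subjects with
20 replicate cohorts for the power and null-calibration summaries —
sizes chosen to match the study design where the claim depends on it and
to stay small where it does not. Further numerical details: softmax
computed with max-subtraction; per-trial probabilities floored at
$10^{-300}$ inside the likelihood (relevant only for absurd parameter
proposals during optimisation); Monte-Carlo XP uses $10^5$–$10^6$ draws
depending on the precision the consumer needs.

## Known limitations

* Subject-level MAP + Laplace is a pragmatic approximation; full
  hierarchical MCMC would propagate estimation uncertainty into the
  group level.
* The evidence approximation, and hence PXP, depends on the prior scale;
  the empirical-Bayes refinement mitigates but does not remove this.
* No lapse parameter, no Pavlovian value learning, no reaction-time
  modelling; the model space is exactly M1–M4.
* The Wilcoxon drug contrast ignores covariates (test site, session
  order) that a mixed-effects analysis of real data would include.
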