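---
title: "Methods: the two-step protection task and its hybrid-learner pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-step protection task and its hybrid-learner pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protectRL)
```

## The task

protectRL simulates and analyses a two-step sequential decision task in
which the second-stage outcome is framed as *protection* (shields that
reduce an impending loss), *reward* (sacks that are later exchanged for
coins), *direct reward* (coins), or *punishment* (flames).  Every trial
begins with a stakes cue (x1 or x5), then one of two first-stage states,
each showing two dwellings.  Transitions are deterministic: within a
state each dwelling always leads to the same one of two creatures, and
the map is crossed between states so that the two first-stage states are
implicitly equivalent — what is learned about a creature from one state
is equally informative in the other.  Creatures deliver 0–9 outcome
units that drift across trials as independent Gaussian random walks
(step SD 2) with reflecting bounds at 0 and 9, initialized low (0–4) for
one creature and high (5–9) for the other.  The final result multiplies
the outcome by the stakes and applies it to the amplified maximum at
stake: with 2 shields against a 9-flame threat, a low-stakes trial ends
with 9 − 2 = 7 flames and a high-stakes trial with 45 − 10 = 35.

Key tunable constants (all in `task_config()`): trial counts per session
(120 with 20 practice for the short preset, 225 with 25 practice for the
long presets; practice trials are flagged and excluded from every
analysis), stakes values (1, 5), the probability of a high-stakes trial
(0.5 by default — the source design says only that stakes were random,
so the rate is configurable), walk step SD (2 points/trial), walk bounds
(0–9 points), and the maximum threat per unit stakes (9).

Two reading notes on the boundary behaviour.  "Reflecting bounds" is
implemented as iterated mirror folding (`v > 9` becomes `18 − v`,
applied repeatedly), which preserves the symmetry of the Gaussian step
distribution at the boundary.  Probe schedules (a certainty probe on 25%
of analyzable trials and an outcome-estimate probe on a disjoint 25%)
use exact-count random placement rather than i.i.d. coin flips so the
per-subject proportions are exact and testable.

## The hybrid learner

Behaviour is generated (and fit) by a hybrid of two controllers over the
four first-stage dwelling stimuli and the two creatures:

* **Model-free**: SARSA(λ)-style caches `Q_MF(state, dwelling)`.  After a
  choice, the first-stage cache moves toward the visited creature's
  current value with learning rate α (`δ1`); after the outcome, the
  creature value moves toward the delivered reward (`δ2`) and a fraction
  λ of that second-stage error also updates the first-stage cache.
* **Model-based**: plans through the known deterministic map; the value
  of a dwelling is simply the learned value of the creature it leads to,
  so second-stage learning generalizes across both first-stage states.

Decision values mix the two with weight ω (`ω·Q_MB + (1−ω)·Q_MF`) and
enter a softmax with inverse temperature β plus a perseveration bonus π
for the option whose response key (left/right) repeats the previous
response.  Keys, not dwellings, carry the stickiness because dwelling
positions are counterbalanced across trials.  Learning operates on the
0–9 unit scale, not the stakes-amplified result — stakes can moderate
parameters (Models 2 and 4) only if the base reward scale is
stakes-free.  In the punishment framing outcomes are valence-aligned
internally (`9 − flames`) so that "more is better" for every variant.
All caches start at 4.5, the midpoint of the payoff range and an
unbiased prior between the low- and high-initialized creatures.

The exact update equations are a reconstruction: the source describes
the parameters and cites the two-step literature rather than printing
equations, and the SARSA(λ) hybrid above is the established formulation
for the deterministic-transition variant.  A consequence of the
"four first-stage stimuli" reading is that each (state, dwelling) pair
carries its own cache; an alternative state-by-position reading exists
but is not pursued.

## Hierarchical inference

Models M1–M4 differ only in parameter tying: M1 shares one ω and one α
across everything, M2 splits them by stakes, M3 by task variant, M4 by
variant × stakes; λ, π and β are always shared.  Subject-level
parameters use the non-centered parameterization
`θ_subject = μ_group + σ_group · ε_subject` with standard normal priors
on μ and ε and a half-normal(0, 1) prior on σ, and reach their natural
scales through the logistic sigmoid (ω, α, λ, π in [0, 1]; β scaled to
[0, 20]).  Bounding π to [0, 1] follows the source's blanket transform
statement literally, although unbounded stickiness is common elsewhere;
this is a deliberate reading, not an oversight.

Sampling is by adaptive Metropolis-within-Gibbs on the latent space:
each subject's offsets are updated coordinate-wise (subjects are
conditionally independent given the group level, so acceptance is
vectorized across subjects), then each parameter's (μ, σ) pair jointly,
with proposal scales adapted toward standard acceptance targets during
warmup only (so the post-warmup chain is a valid fixed kernel).  The
original analysis used Stan's NUTS; no HMC backend is available in this
environment, and the estimation contract here is defined by recovery
behaviour, not by the sampler brand.  Both presets keep the published
chain geometry: `"paper"` = 4 chains × 4000 iterations, `"desk"` =
2 × 1000, each with the first half as warmup (the warmup split is not
stated in the source; half is the convention).  Split-R̂ is reported for
all group parameters and a warning is raised above 1.1 — nonconvergence
is surfaced, never ignored.  Point estimates are posterior means of the
natural-scale subject parameters; group summaries report the mean and SD
of those subject means (the scale on which cohort parameter summaries
are conventionally reported) together with the latent μ and σ.

WAIC is computed from the per-trial pointwise log-likelihood over
posterior draws: `lppd` via a stable log-sum-exp, the effective
parameter penalty as the sample (n−1) variance of the pointwise log
densities (the common estimator in the WAIC literature), and
`WAIC = −2(lppd − p_waic)`.  Observations are trials, matching the
likelihood granularity.  Because the relative-difference convention for
comparing WAIC scores is ambiguous, `rank_models()` reports both the raw
ΔWAIC and the delta as a percentage of the best score, labeled.

## Model-agnostic analyses

`code_stay()` codes "stay" on creatures, not dwellings: revisiting the
same second-stage creature counts as a stay even when the first-stage
state differs, which is exactly what lets the regression separate the
two controllers.  The previous trial's outcome enters valence-aligned
and centered at 4.5; `same_state` and `stakes` carry ±0.5 effect codes
so the outcome main effect is the average slope across same- and
different-state trials (the model-based component) and the
outcome × state interaction is the same-state excess (the model-free
component).  The mixed logistic model uses a subject random intercept by
default (random slopes optional), Laplace-fit via lme4, and reports the
Wald table, the random-intercept variance τ00, and the latent-scale
conditional R².  The stakes code uses the *current* trial's stakes — the
incentive in force at the decision being modeled.  Trials following a
missed trial have no defined predecessor and are dropped, as is each
session's first analyzable trial.

Corrected reward rate divides the mean internal outcome earned by the
mean internal outcome available across both creatures' walks over
analyzable trials; an indiscriminate chooser scores ≈ 1.  Exclusions
follow the preregistered rules strictly: drop above 20% missed trials
(exactly 20% is kept) or below 50% comprehension when a score is given.

Metacognitive and predictive bias are the per-subject slopes of
certainty and outcome-estimate ratings on realized outcomes, extracted
as fixed + random slopes from a linear mixed model (per-subject OLS as
the explicit fallback on nonconvergence, and ratings treated as
continuous 0–9).  `relate_bias_to_params()` regresses those slopes on
the fitted ω and α per variant.

## The synthetic cohort generator — what it emulates and what it does not

`cohort_scenario()` presets mirror the three studies' structure: 200
subjects, both variants per subject with counterbalanced order, 100 or
200 analyzable trials, and group ω/α means and SDs at the published
cohort values (e.g. study 1: ω .72(.14) protection vs .14(.22) reward).
Subjects are drawn on the latent scale with latent moments chosen by
moment matching (quadrature + Nelder–Mead), so the generated cohort is
exactly the population the hierarchical model assumes and recovery tests
are fair; infeasible mean/SD combinations for a bounded parameter fail
fast with the offending entry named.  Two stand-ins are explicitly
synthetic: the shared λ .50(.20), π .20(.15), β 5(2) group values (the
published ones live in a supplementary spreadsheet not reproduced here;
these are mid-range values for this task family), and the probe-rating
generator.  The published group SDs are dispersions of point estimates,
not population SDs; the presets treat them as population SDs, a known
approximation.

The rating generator produces outcome estimates as
`round(clip(intercept + slope · latent payoff of the visited creature + noise))`
and certainty as an affine function of the latent payoff gap between the
creatures.  The latent walk payoff — not the agent's learned value — is
the signal on purpose: the learned value is an error-laden proxy, and
regressing ratings on realized outcomes would attenuate a slope planted
on it by roughly 40%, making the generator's slope parameter
unrecoverable by the very analysis it exists to validate.  With the
latent payoff, a planted mean slope of 0.6 round-trips through
`bias_slopes()` to within well under ±0.1.

A green synthetic-cohort test therefore establishes that the pipeline's
estimators recover the parameters of the stated generative world; it
does not establish anything about human data — reaction times, comprehension
checks, questionnaire responses, sequential effects beyond the model,
and any misspecification of the learner are all outside the generator.

## Numerical choices, degenerate inputs, limitations

Softmax probabilities use a max-subtracted log-sum-exp and saturate
gracefully (never NaN) when β times the value gap exceeds floating-point
range.  Missed trials contribute zero log-likelihood and freeze the
agent state, including the previous response.  β = 0 data are exactly
uninformative (every profile is flat); recovery reports flag such runs
rather than printing meaningless correlations.  A zero-subject cohort
yields a prior-only model, used to check the sampler against the known
prior.

Two empirical caveats surfaced by the package's own tests, at the
stated world's parameters (σ = 2 walks): first, a pure planner tracks
the currently better creature at high rates only when walks drift
slowly (the unvisited creature's value goes stale, so the "greedy
planner" property is a low-noise property); second, the payoff walks'
autocorrelation leaks a small cross-state outcome association
(~0.1 log-odds/unit, an order of magnitude below the same-state slope)
into the stay regression even for a pure model-free agent, so the
"different-state slope is zero" null is a statement about magnitudes,
not about z statistics, which grow without bound in cohort size.
Finally, subject-level λ is weakly identified at 100–200 trials —
group-level recovery is fine, but per-subject λ correlations are low;
this matches the general experience with eligibility traces in this
task family.
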